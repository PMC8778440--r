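#' InteractionModel: effective protein-protein pair interaction
#'
#' Monodisperse effective-particle description of the protein-protein
#' interaction: a hard core of radius R (the population-averaged state
#' radius) plus two Yukawa tails - a screened-Coulomb (DLVO) repulsion
#' set by the average net charge Z and the Debye length, and a generic
#' attraction of contact depth J (in units of k_B T) and range d.
#'
#' @slot R average protein radius [Angstrom]
#' @slot Z average net charge [elementary charges]
#' @slot J contact attraction depth [k_B T]
#' @slot d attraction range [Angstrom]
#' @slot kappaD reciprocal Debye length [1/Angstrom]
#' @slot eps relative dielectric constant
#' @slot T temperature [K]
#' @slot nPart particle number density [1/cm^3]
#' @slot eta hard-sphere volume fraction
#' @export
setClass("InteractionModel",
         representation(R = "numeric", Z = "numeric", J = "numeric",
                        d = "numeric", kappaD = "numeric", eps = "numeric",
                        T = "numeric", nPart = "numeric", eta = "numeric"),
         validity = function(object) {
           if (object@R <= 0) return("radius must be positive")
           if (object@d <= 0) return("attraction range must be positive")
           if (object@eta < 0 || object@eta >= 0.5)
             return("volume fraction must lie in [0, 0.5)")
           TRUE
         })

#' Construct an InteractionModel
#'
#' @param R average protein radius [Angstrom]
#' @param Z average net charge
#' @param J attraction depth at contact [k_B T]
#' @param d attraction range [Angstrom]
#' @param T temperature [K]
#' @param nPart particle number density [1/cm^3]
#' @param kappaD reciprocal Debye length [1/Angstrom]
#' @param eps relative dielectric constant (default: pure water at T)
#' @return an [InteractionModel-class]
#' @export
interactionModel <- function(R, Z, J, d, T, nPart, kappaD,
                             eps = waterDielectric(T)) {
  eta <- nPart * (pi / 6) * (2 * R * 1e-8)^3
  new("InteractionModel", R = R, Z = Z, J = J, d = d, kappaD = kappaD,
      eps = eps, T = T, nPart = nPart, eta = eta)
}

setMethod("show", "InteractionModel", function(object) {
  cat(sprintf(
    "InteractionModel: R=%.1f A, Z=%.2f, J=%.2f kT, d=%.1f A, eta=%.4f, kappaD=%.4f 1/A\n",
    object@R, object@Z, object@J, object@d, object@eta, object@kappaD))
})

#' Population-averaged radius, charge and particle density
#'
#' Number-weighted averages over the state mixture:
#' \eqn{R = \langle\alpha^{-1}\rangle^{-1}\sum_j x_j\alpha_j^{-1}R_j}
#' (same for Z), with \eqn{\langle\alpha^{-1}\rangle = \sum_j x_j/\alpha_j};
#' the particle number density is the monomer number density times
#' \eqn{\langle\alpha^{-1}\rangle}.
#'
#' @param x state fractions
#' @param alpha aggregation numbers
#' @param R state radii [Angstrom]
#' @param Z state charges
#' @param n monomer number density [1/cm^3] (optional)
#' @return list with R, Z, invAlphaMean and (if n given) nPart [1/cm^3]
#' @export
averageRadiusCharge <- function(x, alpha, R, Z, n = NULL) {
  stopifnot(abs(sum(x) - 1) < 1e-8)
  iam <- sum(x / alpha)
  out <- list(R = sum(x / alpha * R) / iam, Z = sum(x / alpha * Z) / iam,
              invAlphaMean = iam)
  if (!is.null(n)) out$nPart <- n * iam
  out
}

# reduced Yukawa tail coefficients: list(B1 [m], B2 [1/m]) per tail,
# for u(r)/kBT = B1 exp(-B2 (r - 2R))/r with r in metres
.yukawaTails <- function(model) {
  Rm <- model@R * 1e-10
  kap <- model@kappaD * 1e10
  lB <- .pc$q_e^2 / (4 * pi * .pc$eps0 * model@eps * .pc$k_B * model@T)
  tails <- list()
  if (model@Z != 0)
    tails$coulomb <- list(B1 = model@Z^2 * lB / (1 + kap * Rm)^2, B2 = kap)
  if (model@J != 0)
    tails$attraction <- list(B1 = -2 * model@J * Rm, B2 = 1 / (model@d * 1e-10))
  tails
}

#' Hard-sphere double-Yukawa pair potential
#'
#' \eqn{u(r) = u_{HS}(r) + B_{1C} e^{-\kappa_D (r-2R)}/r + B_{1A}
#' e^{-(r-2R)/d}/r}: infinite inside the contact distance 2R, the sum of
#' a screened-Coulomb repulsion and a generic attraction outside. The
#' attraction depth at contact is exactly -J.
#'
#' @param r centre-to-centre distance(s) [Angstrom]
#' @param model an [InteractionModel-class]
#' @return potential in units of k_B T (Inf inside the core)
#' @examples
#' m <- interactionModel(R = 17, Z = 5, J = 2, d = 10, T = 298.15,
#'                       nPart = 1e17, kappaD = 0.03)
#' hsdyPotential(c(30, 34, 40, 60), m)
#' @export
hsdyPotential <- function(r, model) {
  stopifnot(is(model, "InteractionModel"), all(r > 0))
  tails <- .yukawaTails(model)
  rm <- r * 1e-10
  sigma <- 2 * model@R * 1e-10
  u <- numeric(length(r))
  for (tl in tails)
    u <- u + tl$B1 * exp(-tl$B2 * (rm - sigma)) / rm
  u[rm < sigma] <- Inf
  u
}

#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic Wertheim-Thiele solution for monodisperse hard spheres of
#' diameter 2R at volume fraction eta. Satisfies the compressibility
#' limit \eqn{S_0(0) = (1-\eta)^4/(1+2\eta)^2}.
#'
#' @param q scattering vector grid [1/Angstrom]
#' @param R sphere radius [Angstrom]
#' @param eta volume fraction in [0, 0.5)
#' @return S0(q)
#' @examples
#' pyStructureFactor(c(1e-6, 0.05, 0.1), R = 17, eta = 0.1)
#' @export
pyStructureFactor <- function(q, R, eta) {
  if (eta < 0 || eta >= 0.5) stop("eta must lie in [0, 0.5)")
  if (eta == 0) return(rep(1, length(q)))
  sigma <- 2 * R
  A <- q * sigma
  al <- (1 + 2 * eta)^2 / (1 - eta)^4
  be <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  ga <- eta * al / 2
  G <- function(A) {
    al / A^2 * (sin(A) - A * cos(A)) +
      be / A^3 * (2 * A * sin(A) + (2 - A^2) * cos(A) - 2) +
      ga / A^5 * (-A^4 * cos(A) + 4 * ((3 * A^2 - 6) * cos(A) +
                                         (A^3 - 6 * A) * sin(A) + 6))
  }
  S <- numeric(length(A))
  small <- A < 1e-3
  S[small] <- (1 - eta)^4 / (1 + 2 * eta)^2
  if (any(!small)) {
    Ab <- A[!small]
    S[!small] <- 1 / (1 + 24 * eta * G(Ab) / Ab)
  }
  S
}

# 3-D Fourier transform of a truncated Yukawa tail (r > sigma), in m^3
# per unit of the reduced amplitude B1 [m]; q in 1/m
.yukawaFT <- function(q, B1, B2, sigma) {
  4 * pi * B1 / q * (B2 * sin(sigma * q) + q * cos(sigma * q)) / (B2^2 + q^2)
}

#' RPA-perturbed structure factor
#'
#' Random-phase-approximation correction of the Percus-Yevick
#' hard-sphere structure factor by the two Yukawa tails, treated
#' perturbatively outside the hard core:
#' \eqn{1/S(q) = 1/S_0(q) + n\,\tilde u(q)/(k_B T)} with the analytic
#' Fourier transform of each tail truncated at the contact distance.
#'
#' @param q scattering vector grid [1/Angstrom]
#' @param S0 hard-sphere structure factor on the same grid (computed if
#'   missing)
#' @param model an [InteractionModel-class]
#' @return S(q)
#' @export
rpaStructureFactor <- function(q, model,
                               S0 = pyStructureFactor(q, model@R, model@eta)) {
  stopifnot(is(model, "InteractionModel"), length(S0) == length(q))
  tails <- .yukawaTails(model)
  if (length(tails) == 0L) return(S0)
  qm <- q * 1e10
  sigma <- 2 * model@R * 1e-10
  ut <- numeric(length(q))
  for (tl in tails) ut <- ut + .yukawaFT(qm, tl$B1, tl$B2, sigma)
  n_m3 <- model@nPart * 1e6
  invS <- 1 / S0 + n_m3 * ut
  if (any(invS <= 0))
    stop("RPA instability: S(q) non-positive; weaken the attraction or lower the density")
  1 / invS
}

#' Measured structure factor under the decoupling approximation
#'
#' \eqn{S_M(q) = 1 + \beta(q) [S(q) - 1]}.
#'
#' @param S average structure factor
#' @param beta coupling function in [0, 1]
#' @return S_M(q)
#' @export
measuredStructureFactor <- function(S, beta) {
  stopifnot(length(S) == length(beta))
  if (any(beta < 0 | beta > 1)) stop("beta must lie in [0, 1]")
  1 + beta * (S - 1)
}
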