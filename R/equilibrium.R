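#' EquilibriumSolution: solved state distribution and shell occupancies
#'
#' Result of [solveDistribution()]: the molar fractions x_j of nominal
#' monomers in each state, the first-shell water occupancies phi_j, the
#' bulk-solvent composition, the nominal monomer molarity, the mean molar
#' volume and the elementary/effective equilibrium constants, all at the
#' sample temperature.
#'
#' @slot x named state fractions (sum to 1)
#' @slot phi named first-shell water occupancies in [0,1]
#' @slot xGb cosolvent molar fraction of the bulk solvent
#' @slot XWb,XGb bulk water / cosolvent molar fractions of the system
#' @slot CP nominal monomer molar concentration [mol/L]
#' @slot meanNu mean molar volume [L/mol]
#' @slot KW1 named elementary transition constants K_W1j at T
#' @slot Kex named exchange constants K_exj at T
#' @slot K1 named effective constants K_1j (composition dependent)
#' @slot dG1 named effective Gibbs energies -RT ln K_1j [J/mol]
#' @slot I total ionic strength [mol/L]
#' @slot kappaD reciprocal Debye length [1/Angstrom]
#' @slot T temperature [K]
#' @slot nuWb,nuGb bulk water / cosolvent molar volumes at T [L/mol]
#' @slot converged logical
#' @slot iterations outer iteration count
#' @export
setClass("EquilibriumSolution",
         representation(x = "numeric", phi = "numeric", xGb = "numeric",
                        XWb = "numeric", XGb = "numeric", CP = "numeric",
                        meanNu = "numeric", KW1 = "numeric", Kex = "numeric",
                        K1 = "numeric", dG1 = "numeric", I = "numeric",
                        kappaD = "numeric", T = "numeric", nuWb = "numeric",
                        nuGb = "numeric", converged = "logical",
                        iterations = "numeric"),
         validity = function(object) {
           if (abs(sum(object@x) - 1) > 1e-8) return("state fractions must sum to 1")
           if (any(object@phi < 0 | object@phi > 1 + 1e-12))
             return("phi out of [0,1]")
           TRUE
         })

setMethod("show", "EquilibriumSolution", function(object) {
  cat(sprintf("EquilibriumSolution at T=%.2f K (%s, %d iterations)\n",
              object@T, if (object@converged) "converged" else "NOT converged",
              as.integer(object@iterations)))
  cat("  x:   ", paste(sprintf("%s=%.4f", names(object@x), object@x),
                       collapse = "  "), "\n")
  cat("  phi: ", paste(sprintf("%s=%.5f", names(object@phi), object@phi),
                       collapse = "  "), "\n")
  cat(sprintf("  xGb=%.4e  CP=%.4e M  I=%.4e M\n",
              object@xGb, object@CP, object@I))
})

#' @describeIn solveDistribution accessor, state fractions
#' @param object an EquilibriumSolution
#' @export
stateFractions <- function(object) object@x
#' @describeIn solveDistribution accessor, first-shell water occupancies
#' @export
shellOccupancies <- function(object) object@phi

#' First-shell water occupancy from the exchange constant
#'
#' Closed-form inversion of the Schellman exchange isotherm: given the
#' water-cosolvent exchange constant K_ex of a state and the cosolvent
#' fraction of the bulk solvent x_Gb, the fraction of first-shell sites
#' occupied by water is
#' \deqn{\phi = \frac{K_{ex}(1 - x_{Gb})}{x_{Gb} + K_{ex}(1 - x_{Gb})}.}
#' K_ex > 1 means water is preferred at the surface.
#'
#' @param Kex exchange constant (> 0)
#' @param xGb bulk cosolvent molar fraction of the solvent, in [0, 1)
#' @return occupancy phi in [0, 1]
#' @examples
#' phiFromExchange(2, 0.2)  # 0.888...
#' @export
phiFromExchange <- function(Kex, xGb) {
  stopifnot(all(Kex > 0))
  if (any(xGb < 0) || any(xGb > 1)) stop("xGb must lie in [0, 1]")
  if (any(xGb == 1)) {
    warning("xGb = 1: returning the phi = 0 limit")
  }
  Kex * (1 - xGb) / (xGb + Kex * (1 - xGb))
}

#' Effective transition constant in a binary solvent
#'
#' Builds the composition-dependent effective constant for the 1 -> j
#' transformation from the elementary constant in water K_W1j, the shell
#' occupancies and the bulk water fraction:
#' \deqn{K_{1j} = K_{W1j}\,\phi_1^{m_1}\,
#'       X_{Wb}^{\alpha_j^{-1} m_j - m_1} / \phi_j^{\alpha_j^{-1} m_j}.}
#' Computed in log space (the exponents are of order of the hydration
#' site counts, several hundred).
#'
#' @param KW1j elementary constant (> 0)
#' @param phi1,phij first-shell water occupancies of states 1 and j, in (0,1]
#' @param XWb bulk water molar fraction, in (0,1]
#' @param m1,mj first-shell site counts
#' @param alphaj aggregation number of state j
#' @return the effective constant K_1j
#' @export
effectiveConstant <- function(KW1j, phi1, phij, XWb, m1, mj, alphaj) {
  stopifnot(KW1j > 0, XWb > 0, XWb <= 1)
  if (phi1 <= 0 || phij <= 0)
    stop("zero shell occupancy: fully cosolvent-covered shells unsupported")
  exp(log(KW1j) + m1 * log(phi1) + (mj / alphaj - m1) * log(XWb) -
        (mj / alphaj) * log(phij))
}

#' Bulk-solvent composition under protein binding
#'
#' Mass-balance bookkeeping: given the nominal composition (X_P, x_G) and
#' the current state distribution and shell occupancies, returns the
#' cosolvent fraction of the bulk solvent and the bulk water/cosolvent
#' molar fractions of the whole system.
#'
#' @param XP nominal protein monomer molar fraction
#' @param xG nominal cosolvent fraction of the solvent
#' @param x state fractions (sum to 1)
#' @param phi first-shell water occupancies
#' @param m first-shell site counts per state
#' @param alpha aggregation numbers per state
#' @return list with xGb, XWb, XGb
#' @export
bulkComposition <- function(XP, xG, x, phi, m, alpha) {
  stopifnot(abs(sum(x) - 1) < 1e-8, all(phi >= 0), all(phi <= 1))
  sPhi   <- sum(m * x / alpha * phi)
  sGphi  <- sum(m * x / alpha * (1 - phi))
  sAll   <- sum(m * x / alpha)
  XWb <- (1 - XP) * (1 - xG) - XP * sPhi
  XGb <- (1 - XP) * xG - XP * sGphi
  den <- 1 - XP * (1 + sAll)
  if (XWb <= 0 || den <= 0)
    stop("infeasible composition: protein shell demand exceeds the solvent")
  xGb <- ((1 - XP) * xG - XP * sGphi) / den
  list(xGb = max(xGb, 0), XWb = XWb, XGb = max(XGb, 0))
}

#' Mean molar volume and nominal monomer molarity
#'
#' Volume bookkeeping over protein, bulk solvent and hydration sites
#' (first-shell water compressed by the factor d_j; site cosolvent volume
#' taken equal to bulk). Returns the mean molar volume of the mixture and
#' the nominal monomer molar concentration C_P = X_P / <nu>.
#'
#' @param XP,xG nominal composition
#' @param x,phi state fractions and occupancies
#' @param m,alpha,d per-state site counts, aggregation numbers and
#'   hydration-water relative densities
#' @param nuP protein molar volume at T [L/mol]
#' @param nuWb,nuGb bulk water/cosolvent molar volumes at T [L/mol]
#' @return list with meanNu [L/mol] and CP [mol/L]
#' @export
meanMolarVolume <- function(XP, xG, x, phi, m, alpha, d, nuP, nuWb, nuGb) {
  nuWs <- nuWb / d
  site <- sum(m * x / alpha * ((nuWs - nuWb) * phi))  # nuGs == nuGb
  meanNu <- nuP * XP + (nuWb * (1 - xG) + nuGb * xG) * (1 - XP) + XP * site
  list(meanNu = meanNu, CP = XP / meanNu)
}

# mass-action state fractions from effective constants (log-space).
# logK1: named log K_1j per state (state 1 has logK = 0); alpha: aggregation
# numbers; CP: nominal monomer molarity [M]. Solves for the monomer
# concentration C1 such that sum_j alpha_j (K_1j C1)^(alpha_j) = CP.
.massActionFractions <- function(logK1, alpha, CP) {
  if (CP <= 0) {
    x <- numeric(length(alpha)); x[1] <- 1
    return(x)
  }
  f <- function(t) {
    y <- alpha * (logK1 + t)
    y[y > 700] <- 700
    sum(alpha * exp(y)) - CP
  }
  hi <- log(CP)
  if (f(hi) <= 0) {
    root <- hi            # all mass monomeric (single-state limit)
  } else {
    lo <- hi - 5
    it <- 0L
    while (f(lo) > 0 && it < 400L) { lo <- lo - 5; it <- it + 1L }
    if (f(lo) > 0) stop("mass-action bracketing failed")
    root <- stats::uniroot(f, c(lo, hi), tol = 1e-12, maxiter = 2000L)$root
  }
  y <- alpha * (logK1 + root)
  y[y > 700] <- 700
  Cj <- exp(y)
  x <- alpha * Cj / CP
  x / sum(x)  # remove the residual root-finder error
}

#' Map printed oligomerisation constants to effective 1 -> j constants
#'
#' The stepwise association constants of the insulin scheme
#' (2 monomers -> dimer, 2 dimers -> tetramer, dimer + tetramer -> hexamer)
#' are related to the effective monomer-based constants by
#' Kbar_12 = K_12^2, Kbar_24 = (K_14/K_12)^4 and
#' Kbar_46 = K_16^6/(K_14^4 K_12^2). This helper inverts those relations.
#'
#' @param Kbar12,Kbar24,Kbar46 stepwise constants [1/M]
#' @return named vector with the effective constants K12, K14, K16
#'   (dimensionless in the 1 M standard state)
#' @examples
#' insulinEffectiveConstants(2.22e5, 40, 220)
#' @export
insulinEffectiveConstants <- function(Kbar12, Kbar24, Kbar46) {
  stopifnot(Kbar12 > 0, Kbar24 > 0, Kbar46 > 0)
  K12 <- sqrt(Kbar12)
  K14 <- K12 * Kbar24^(1 / 4)
  K16 <- (Kbar46 * K14^4 * K12^2)^(1 / 6)
  c(K12 = K12, K14 = K14, K16 = K16)
}

#' Solve the coupled state-distribution / shell-occupancy system
#'
#' Finds the 2*Ns unknowns (x_j, phi_j) satisfying simultaneously the
#' normalisation of state fractions, the Schellman exchange isotherm for
#' every state and the mass-action law with the effective constants K_1j,
#' with the bulk composition, mean molar volume, counterion ionic
#' strength and Debye-Hueckel terms recomputed self-consistently. A
#' damped fixed-point iteration is used: the closed-form phi update and a
#' one-dimensional root solve for the monomer concentration per sweep.
#'
#' @param states list of [ProteinState-class]; the first must be the
#'   monomeric reference state (alpha = 1)
#' @param transitions named list of [ThermoTriplet-class], one per
#'   non-reference state id: the non-electrostatic 1 -> j parameters
#' @param exchanges named list of [ThermoTriplet-class], one per state id:
#'   water-cosolvent exchange parameters (may be NULL when the sample
#'   contains no cosolvent)
#' @param sample a [SampleComposition-class]
#' @param env an [IonicEnvironment-class]
#' @param control list: damping (default 0.5), tol (relative tolerance,
#'   default 1e-10), maxit (default 500)
#' @return an [EquilibriumSolution-class]
#' @examples
#' st <- list(proteinState("1", 1, 404, 465, 17, 0),
#'            proteinState("2", 2, 753, 827, 26.7, 0))
#' tr <- list("2" = thermoTriplet(-28.5))   # strong dimerisation
#' sc <- sampleComposition(c0 = 2, M1 = 17000, T = 298.15)
#' sol <- solveDistribution(st, tr, NULL, sc,
#'                          ionicEnvironment(electrostatics = FALSE))
#' stateFractions(sol)
#' @export
solveDistribution <- function(states, transitions, exchanges = NULL, sample,
                              env = ionicEnvironment(),
                              control = list()) {
  ctl <- modifyList(list(damping = 0.5, tol = 1e-10, maxit = 500L), control)
  ns <- length(states)
  ids <- vapply(states, function(s) s@id, character(1))
  alpha <- vapply(states, function(s) s@alpha, numeric(1))
  m  <- vapply(states, function(s) s@m,  numeric(1))
  d  <- vapply(states, function(s) s@d,  numeric(1))
  R  <- vapply(states, function(s) s@R,  numeric(1))
  Z  <- vapply(states, function(s) s@Z,  numeric(1))
  if (alpha[1] != 1) stop("the first state must be the monomeric reference")
  if (ns > 1) {
    missing_tr <- setdiff(ids[-1], names(transitions))
    if (length(missing_tr))
      stop("missing transition parameters for state(s): ",
           paste(missing_tr, collapse = ", "))
  }
  T  <- sample@T
  XP <- sample@XP
  xG <- sample@xG
  if (xG > 0) {
    missing_ex <- setdiff(ids, names(exchanges))
    if (length(missing_ex))
      stop("missing exchange parameters for state(s): ",
           paste(missing_ex, collapse = ", "))
  }
  RT <- .pc$R_gas * T
  nuWb <- waterMolarVolume(T)
  nuGb <- if (is.null(sample@cosolvent)) nuWb * 10 else
    expandedMolarVolume(sample@cosolvent@nuGb0, sample@cosolvent@alphaG, T)
  nuP <- expandedMolarVolume(sample@nuP0, sample@alphaP, T)
  eps <- waterDielectric(T)

  # exchange constants at T (independent of composition)
  Kex <- rep(Inf, ns)
  if (!is.null(exchanges)) {
    Kex <- vapply(ids, function(id)
      if (id %in% names(exchanges))
        exp(-gibbsAtTemperature(exchanges[[id]], T) / RT) else Inf,
      numeric(1))
  }
  names(Kex) <- ids
  # non-electrostatic part of the elementary transition energies at T
  dGnel <- c(0, vapply(ids[-1], function(id)
    gibbsAtTemperature(transitions[[id]], T), numeric(1)))

  x <- numeric(ns); x[1] <- 1
  phi <- rep(1, ns)
  lam <- ctl$damping
  converged <- FALSE
  iter <- 0L
  logK1 <- numeric(ns)
  bc <- NULL; mv <- NULL; Itot <- 0; kapD <- 0; KW1 <- rep(1, ns)
  for (iter in seq_len(ctl$maxit)) {
    bc <- bulkComposition(XP, xG, x, phi, m, alpha)
    mv <- meanMolarVolume(XP, xG, x, phi, m, alpha, d, nuP, nuWb, nuGb)
    CP <- mv$CP
    # ionic strength: buffer + ionic cosolvent microions + counterions
    IS <- env@IS
    if (!is.null(sample@cosolvent) && sample@cosolvent@ionic)
      IS <- IS + bc$XGb / mv$meanNu   # 1:1 electrolyte at the bulk molarity
    Itot <- IS
    if (env@electrostatics) Itot <- IS + counterionIonicStrength(CP, x, alpha, Z)
    kapD <- if (Itot > 0) debyeKappa(Itot, eps, T) else 0
    # elementary constants with the electrostatic term
    if (env@electrostatics) {
      Gel <- electrostaticStateEnergy(Z, R, kapD, env@a, eps)
      dGel <- Gel / alpha - Gel[1]
    } else dGel <- numeric(ns)
    KW1 <- exp(-(dGnel + dGel) / RT)
    # closed-form occupancy update
    phiNew <- if (xG > 0) phiFromExchange(pmin(Kex, 1e300), bc$xGb) else rep(1, ns)
    # effective constants (log space) and mass action
    XWbFrac <- bc$XWb / (1 - XP)  # water molar fraction of the solvent+shell pool
    logK1 <- log(KW1) + m[1] * log(phiNew[1]) +
      (m / alpha - m[1]) * log(bc$XWb) - (m / alpha) * log(phiNew)
    logK1[1] <- 0
    xNew <- .massActionFractions(logK1, alpha, CP)
    xNew[alpha > 1 & xNew < 1e-15] <- 0
    xNew <- xNew / sum(xNew)
    delta <- max(abs(xNew - x), abs(phiNew - phi))
    x <- (1 - lam) * x + lam * xNew
    phi <- (1 - lam) * phi + lam * phiNew
    if (delta < ctl$tol) { x <- xNew; phi <- phiNew; converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("equilibrium solver did not converge in %d iterations (last residual %.3e)",
                 ctl$maxit, delta))
  bc <- bulkComposition(XP, xG, x, phi, m, alpha)
  mv <- meanMolarVolume(XP, xG, x, phi, m, alpha, d, nuP, nuWb, nuGb)
  K1 <- exp(logK1)
  names(x) <- names(phi) <- names(K1) <- ids
  new("EquilibriumSolution", x = x, phi = pmin(phi, 1), xGb = bc$xGb,
      XWb = bc$XWb, XGb = bc$XGb, CP = mv$CP, meanNu = mv$meanNu,
      KW1 = stats::setNames(KW1, ids), Kex = Kex, K1 = K1,
      dG1 = stats::setNames(-RT * logK1, ids), I = Itot, kappaD = kapD,
      T = T, nuWb = nuWb, nuGb = nuGb, converged = converged,
      iterations = iter)
}
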