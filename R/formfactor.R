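# atomic displaced solvent volumes [A^3] (Fraser-MacRae-Suzuki set)
.displacedVolume <- c(H = 5.15, C = 16.44, N = 2.49, O = 9.13, S = 19.86,
                      P = 5.73, FE = 7.99, ZN = 9.85, MG = 9.85, CA = 9.85)

.j0 <- function(x) ifelse(x < 1e-8, 1 - x^2 / 6, sin(x) / x)

#' FormFactorBasis: SLD-independent scattering sums of one state
#'
#' Precomputed Debye machinery for one structure plus its hydration
#' shells: scatterers are grouped into classes (one per element, plus one
#' for the shell dummy spheres), and for every class pair the pairwise
#' distance histogram (weighted by occupancy) is reduced, on a fixed q
#' grid, to the partial sum \eqn{S_{ab}(q) = \sum_k n_k j_0(q d_k)} with
#' per-bin mean distances. The orientationally averaged intensity for any
#' bulk/local-domain SLD pair is then a cheap quadratic form in the
#' q-dependent class scattering lengths, which is what makes global
#' fitting (where SLDs change with the solvation state at every step)
#' affordable.
#'
#' @slot q q grid [1/Angstrom]
#' @slot classLabel class labels (element symbols and "SITE")
#' @slot classNe electrons per scatterer (0 for sites)
#' @slot classV displaced/occupied volume per scatterer [Angstrom^3]
#' @slot classType "atom" or "site"
#' @slot classWeight total occupancy weight per class
#' @slot pairA,pairB class indices of each stored pair (A <= B)
#' @slot pairMult 1 for A == B, 2 for A < B
#' @slot Spair matrix (nq x npairs) of partial Debye sums
#' @slot Tsingle matrix (nq x nclass) of single sums
#'   \eqn{\sum_i j_0(q r_i)} about the electron-weighted centroid
#' @slot alpha aggregation number of the state
#' @export
setClass("FormFactorBasis",
         representation(q = "numeric", classLabel = "character",
                        classNe = "numeric", classV = "numeric",
                        classType = "character", classWeight = "numeric",
                        pairA = "integer", pairB = "integer",
                        pairMult = "numeric", Spair = "matrix",
                        Tsingle = "matrix", alpha = "numeric"))

setMethod("show", "FormFactorBasis", function(object) {
  cat(sprintf(
    "FormFactorBasis: %d classes (%s), %d q points, alpha=%d\n",
    length(object@classLabel), paste(object@classLabel, collapse = ","),
    length(object@q), as.integer(object@alpha)))
})

#' FormFactorTable: state form factor on a q grid
#'
#' Orientationally averaged squared amplitude P_j(q) and averaged
#' amplitude P1_j(q) of one protein state under the per-monomer
#' normalisation \eqn{P_j = \langle|\Delta A_j|^2\rangle/\alpha_j^2},
#' \eqn{P_j^{(1)} = \langle\Delta A_j\rangle/\alpha_j^2}, so that
#' \eqn{n\sum_j x_j \alpha_j P_j(q)} is the physical mixture intensity.
#'
#' @slot q q grid [1/Angstrom]
#' @slot P squared-amplitude average [cm^2]
#' @slot P1 amplitude average [cm]
#' @slot alpha aggregation number
#' @export
setClass("FormFactorTable",
         representation(q = "numeric", P = "numeric", P1 = "numeric",
                        alpha = "numeric"),
         validity = function(object) {
           if (length(object@P) != length(object@q) ||
               length(object@P1) != length(object@q))
             return("grid length mismatch")
           TRUE
         })

setMethod("show", "FormFactorTable", function(object) {
  cat(sprintf("FormFactorTable: %d q points, alpha=%d, P(0)=%.4e cm^2\n",
              length(object@q), as.integer(object@alpha), object@P[1]))
})

#' Default q grid
#'
#' 120 log-spaced points in the working band of the model
#' (0.01-0.35 1/Angstrom, where the q-independent atomic scattering
#' length approximation is justified).
#'
#' @param n number of points (default 120)
#' @param qmin,qmax band limits [1/Angstrom]
#' @return numeric q grid
#' @export
defaultQGrid <- function(n = 120, qmin = 0.01, qmax = 0.35) {
  exp(seq(log(qmin), log(qmax), length.out = n))
}

# weighted pair-distance partial sums between two point groups
.pairPartialSum <- function(q, ca, wa, cb, wb, same, binWidth, chunk = 1024L) {
  # accumulate weighted counts and weighted distance sums per bin
  maxd <- sqrt(sum((pmax(apply(ca, 2, max), apply(cb, 2, max)) -
                      pmin(apply(ca, 2, min), apply(cb, 2, min)))^2)) + binWidth
  nb <- as.integer(ceiling(maxd / binWidth)) + 1L
  wsum <- numeric(nb); dsum <- numeric(nb)
  nA <- nrow(ca)
  for (s in seq(1L, nA, by = chunk)) {
    e <- min(s + chunk - 1L, nA)
    blk <- ca[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(cb^2), "+") - 2 * tcrossprod(blk, cb)
    d2[d2 < 0] <- 0
    d <- sqrt(as.vector(d2))
    w <- as.vector(outer(wa[s:e], wb))
    bin <- pmin(as.integer(d / binWidth) + 1L, nb)
    rs <- rowsum(cbind(w, w * d), bin)
    idx <- as.integer(rownames(rs))
    wsum[idx] <- wsum[idx] + rs[, 1]
    dsum[idx] <- dsum[idx] + rs[, 2]
  }
  keep <- wsum > 0
  dbar <- dsum[keep] / wsum[keep]
  # S(q) = sum_k n_k j0(q dbar_k)
  outer(q, dbar, function(qq, dd) .j0(qq * dd)) %*% wsum[keep]
}

#' Build the SLD-independent form-factor basis of a state
#'
#' @param structure an [AtomicStructure-class]
#' @param shells a [HydrationShellModel-class] built for this structure
#' @param q q grid [1/Angstrom], default [defaultQGrid()]
#' @param alpha aggregation number of the state (default 1)
#' @param binWidth pair-distance histogram bin width [Angstrom]
#' @return a [FormFactorBasis-class]
#' @export
formFactorBasis <- function(structure, shells, q = defaultQGrid(),
                            alpha = 1, binWidth = 0.25) {
  stopifnot(is(structure, "AtomicStructure"), is(shells, "HydrationShellModel"))
  if (nrow(shells@sites) < 1L) stop("shell model carries no sites")
  el <- toupper(elements(structure))
  occ <- structure@occupancy
  labels <- sort(unique(el))
  coordsL <- lapply(labels, function(L) coords(structure)[el == L, , drop = FALSE])
  weightL <- lapply(labels, function(L) occ[el == L])
  Ne <- electronCount(labels)
  V <- .displacedVolume[labels]
  V[is.na(V)] <- .displacedVolume[["C"]]
  # the shell sites form one extra class
  labels <- c(labels, "SITE")
  coordsL <- c(coordsL, list(shells@sites))
  weightL <- c(weightL, list(rep(1, nrow(shells@sites))))
  Ne <- c(Ne, 0)
  V <- c(V, shells@siteVolume)
  type <- c(rep("atom", length(labels) - 1L), "site")
  ncl <- length(labels)
  # centroid for the amplitude average: electron-weighted atom positions
  wAtom <- occ * electronCount(el)
  ctr <- colSums(coords(structure) * wAtom) / sum(wAtom)
  pairs <- which(upper.tri(matrix(0, ncl, ncl), diag = TRUE), arr.ind = TRUE)
  Spair <- matrix(0, length(q), nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1]; b <- pairs[p, 2]
    Spair[, p] <- .pairPartialSum(q, coordsL[[a]], weightL[[a]],
                                  coordsL[[b]], weightL[[b]],
                                  same = (a == b), binWidth = binWidth)
  }
  Tsingle <- matrix(0, length(q), ncl)
  for (a in seq_len(ncl)) {
    r <- sqrt(rowSums(sweep(coordsL[[a]], 2, ctr)^2))
    Tsingle[, a] <- outer(q, r, function(qq, rr) .j0(qq * rr)) %*% weightL[[a]]
  }
  new("FormFactorBasis", q = q, classLabel = labels, classNe = Ne,
      classV = unname(V), classType = type,
      classWeight = vapply(weightL, sum, numeric(1)),
      pairA = as.integer(pairs[, 1]), pairB = as.integer(pairs[, 2]),
      pairMult = ifelse(pairs[, 1] == pairs[, 2], 1, 2),
      Spair = Spair, Tsingle = Tsingle, alpha = alpha)
}

# q-dependent class scattering lengths [cm] for given SLDs [cm^-2]
.classWeights <- function(basis, rho0, rhoLd) {
  q <- basis@q
  w <- matrix(0, length(q), length(basis@classLabel))
  for (a in seq_along(basis@classLabel)) {
    V <- basis@classV[a]
    gauss <- exp(-q^2 * V^(2 / 3) / (4 * pi))
    if (basis@classType[a] == "atom") {
      w[, a] <- .pc$r_e * basis@classNe[a] - rho0 * (V * 1e-24) * gauss
    } else {
      w[, a] <- (rhoLd - rho0) * (V * 1e-24) * gauss
    }
  }
  w
}

#' Evaluate a state form factor for given solvent SLDs
#'
#' Contracts a [FormFactorBasis-class] with the q-dependent class
#' scattering lengths implied by the bulk SLD rho0 and the local-domain
#' SLD rho_ld: atoms carry \eqn{r_e N_e} minus a Gaussian excluded-volume
#' term at rho0, shell sites carry \eqn{(\rho_{ld}-\rho_0) v_{site}}
#' times a Gaussian sphere factor.
#'
#' @param basis a [FormFactorBasis-class]
#' @param rho0 bulk solvent SLD [cm^-2]
#' @param rhoLd local-domain SLD [cm^-2]
#' @return a [FormFactorTable-class]
#' @export
evaluateFormFactor <- function(basis, rho0, rhoLd) {
  stopifnot(is(basis, "FormFactorBasis"))
  w <- .classWeights(basis, rho0, rhoLd)
  P <- numeric(length(basis@q))
  for (p in seq_along(basis@pairA)) {
    P <- P + basis@pairMult[p] *
      w[, basis@pairA[p]] * w[, basis@pairB[p]] * basis@Spair[, p]
  }
  P1 <- rowSums(w * basis@Tsingle)
  new("FormFactorTable", q = basis@q, P = P / basis@alpha^2,
      P1 = P1 / basis@alpha^2, alpha = basis@alpha)
}

#' One-step state form factor
#'
#' Convenience wrapper: builds the basis for a structure plus shells and
#' evaluates it at the given SLDs. For repeated evaluation at changing
#' SLDs build the basis once with [formFactorBasis()] and call
#' [evaluateFormFactor()].
#'
#' @inheritParams formFactorBasis
#' @inheritParams evaluateFormFactor
#' @return a [FormFactorTable-class]
#' @export
stateFormFactor <- function(structure, shells, rho0, rhoLd,
                            q = defaultQGrid(), alpha = 1) {
  evaluateFormFactor(formFactorBasis(structure, shells, q, alpha), rho0, rhoLd)
}

#' Ensemble-averaged form factor
#'
#' Unweighted mean of member form factors (used for the unfolded-state
#' conformational ensemble).
#'
#' @param tables list of [FormFactorTable-class] on a common q grid
#' @return a [FormFactorTable-class]
#' @export
ensembleFormFactor <- function(tables) {
  stopifnot(length(tables) >= 1)
  q <- tables[[1]]@q
  alpha <- tables[[1]]@alpha
  for (tb in tables) {
    if (!isTRUE(all.equal(tb@q, q)))
      stop("inconsistent q grids across ensemble members")
    if (tb@alpha != alpha) stop("inconsistent aggregation numbers")
  }
  P <- Reduce(`+`, lapply(tables, function(tb) tb@P)) / length(tables)
  P1 <- Reduce(`+`, lapply(tables, function(tb) tb@P1)) / length(tables)
  new("FormFactorTable", q = q, P = P, P1 = P1, alpha = alpha)
}

#' Effective form factor and coupling function of a state mixture
#'
#' \eqn{P(q) = \sum_j x_j \alpha_j P_j(q)},
#' \eqn{P^{(1)}(q) = \sum_j x_j \alpha_j P^{(1)}_j(q)} and the
#' decoupling-approximation coupling function
#' \eqn{\beta(q) = |P^{(1)}(q)|^2 / P(q)}, clipped to [0, 1].
#'
#' @param tables list of [FormFactorTable-class], one per state, on a
#'   common q grid
#' @param x state fractions (summing to 1), same order
#' @return list with q, P [cm^2], P1 [cm], beta
#' @export
effectiveFormFactor <- function(tables, x) {
  stopifnot(length(tables) == length(x), abs(sum(x) - 1) < 1e-8)
  q <- tables[[1]]@q
  P <- numeric(length(q)); P1 <- numeric(length(q))
  for (j in seq_along(tables)) {
    stopifnot(isTRUE(all.equal(tables[[j]]@q, q)))
    P <- P + x[j] * tables[[j]]@alpha * tables[[j]]@P
    P1 <- P1 + x[j] * tables[[j]]@alpha * tables[[j]]@P1
  }
  beta <- pmin(pmax(P1^2 / P, 0), 1)
  list(q = q, P = P, P1 = P1, beta = beta)
}
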