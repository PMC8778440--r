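#' ScatteringCurve: one SAXS curve with its curve parameters
#'
#' Absolute-scale macroscopic differential scattering cross section
#' dSigma/dOmega(q) with experimental standard deviations and the four
#' curve labels of the global-fit design: protein concentration at the
#' reference temperature, temperature, cosolvent type and cosolvent
#' concentration at the reference temperature.
#'
#' @slot q scattering vector [1/Angstrom], strictly increasing
#' @slot I intensity dSigma/dOmega [1/cm]
#' @slot sigma standard deviations [1/cm], positive
#' @slot c0 protein concentration at 298.15 K [g/L]
#' @slot T temperature [K]
#' @slot G cosolvent id ("" for none)
#' @slot CG0 cosolvent molarity at 298.15 K [mol/L]
#' @export
setClass("ScatteringCurve",
         representation(q = "numeric", I = "numeric", sigma = "numeric",
                        c0 = "numeric", T = "numeric", G = "character",
                        CG0 = "numeric"),
         validity = function(object) {
           n <- length(object@q)
           if (length(object@I) != n || length(object@sigma) != n)
             return("q, I, sigma length mismatch")
           if (n >= 2 && any(diff(object@q) <= 0))
             return("q must be strictly increasing")
           if (any(object@sigma <= 0)) return("sigma must be positive")
           TRUE
         })

#' Construct a ScatteringCurve
#' @param q,I,sigma the three curve columns
#' @param c0 protein concentration [g/L]
#' @param T temperature [K]
#' @param G cosolvent id, "" if none
#' @param CG0 cosolvent concentration [mol/L]
#' @return a [ScatteringCurve-class]
#' @export
scatteringCurve <- function(q, I, sigma, c0, T, G = "", CG0 = 0) {
  new("ScatteringCurve", q = q, I = I, sigma = sigma, c0 = c0, T = T,
      G = G, CG0 = CG0)
}

setMethod("show", "ScatteringCurve", function(object) {
  cat(sprintf(
    "ScatteringCurve: %d points, q in [%.3f, %.3f] 1/A | c0=%g g/L, T=%.2f K, G='%s', CG0=%g M\n",
    length(object@q), min(object@q), max(object@q), object@c0, object@T,
    object@G, object@CG0))
})

#' SAXSSystem: everything needed to predict a curve
#'
#' Bundles the protein states (with their form-factor bases), the
#' transition and exchange thermodynamics, the cosolvent, the ionic
#' environment and the shared q grid. This is the object the forward
#' model [modelIntensity()] and the global fit operate on.
#'
#' @slot states list of [ProteinState-class]
#' @slot transitions named list of [ThermoTriplet-class] (1 -> j)
#' @slot exchanges named list of [ThermoTriplet-class] (per state)
#' @slot cosolv a [Cosolvent-class] or NULL
#' @slot env an [IonicEnvironment-class]
#' @slot M1 monomer molecular weight [g/mol]
#' @slot pH solution pH
#' @slot nuP0 protein molar volume at 298.15 K [L/mol]
#' @slot alphaP protein expansivity [1/K]
#' @slot q shared q grid [1/Angstrom]
#' @slot bases named list (per state id) of lists of
#'   [FormFactorBasis-class] (one entry per ensemble member)
#' @export
setClass("SAXSSystem",
         representation(states = "list", transitions = "list",
                        exchanges = "list", cosolv = "ANY", env = "ANY",
                        M1 = "numeric", pH = "numeric", nuP0 = "numeric",
                        alphaP = "numeric", q = "numeric", bases = "list"))

setMethod("show", "SAXSSystem", function(object) {
  ids <- vapply(object@states, function(s) s@id, character(1))
  cat(sprintf("SAXSSystem: %d states (%s), M1=%g g/mol, pH=%.1f, %d q points%s\n",
              length(ids), paste(ids, collapse = ","), object@M1, object@pH,
              length(object@q),
              if (is.null(object@cosolv)) "" else
                paste0(", cosolvent ", object@cosolv@id)))
})

#' Assemble a SAXSSystem
#'
#' Builds hydration shells and form-factor bases for every state that
#' carries a structure (an ensemble is averaged member by member).
#'
#' @param states list of [ProteinState-class]; every state needs a
#'   structure (or ensemble) for the scattering part
#' @param transitions named list of [ThermoTriplet-class] per
#'   non-reference state id
#' @param exchanges named list of [ThermoTriplet-class] per state id
#'   (empty list when no cosolvent is used)
#' @param M1 monomer molecular weight [g/mol]
#' @param pH solution pH
#' @param cosolv a [Cosolvent-class] or NULL
#' @param env an [IonicEnvironment-class]
#' @param q q grid [1/Angstrom]
#' @param nuP0 protein molar volume [L/mol], default from 0.73 cm^3/g
#' @param alphaP protein expansivity [1/K]
#' @param verbose print progress while building bases
#' @return a [SAXSSystem-class]
#' @export
saxsSystem <- function(states, transitions, exchanges = list(), M1, pH = 7,
                       cosolv = NULL, env = ionicEnvironment(),
                       q = defaultQGrid(), nuP0 = 0.73 * M1 / 1000,
                       alphaP = 0, verbose = FALSE) {
  bases <- list()
  for (s in states) {
    if (is.null(s@structure)) stop("state ", s@id, " carries no structure")
    members <- if (is(s@structure, "AtomicStructure")) list(s@structure)
               else s@structure
    bl <- lapply(members, function(str) {
      if (verbose) message("building basis for state ", s@id)
      sh <- buildShells(str)
      formFactorBasis(str, sh, q = q, alpha = s@alpha)
    })
    bases[[s@id]] <- bl
  }
  new("SAXSSystem", states = states, transitions = transitions,
      exchanges = exchanges, cosolv = cosolv, env = env, M1 = M1, pH = pH,
      nuP0 = nuP0, alphaP = alphaP, q = q, bases = bases)
}

#' Forward model: absolute SAXS intensity of one sample
#'
#' Full chain for one curve: solve the state/solvation equilibrium at
#' the curve's composition and temperature, derive bulk and local-domain
#' SLDs, evaluate state form factors and the coupling function, build
#' the PY+RPA structure factor from the population-averaged interaction
#' model, and assemble \eqn{d\Sigma/d\Omega(q) = n P(q) S_M(q)} with the
#' monomer number density thermally corrected through the mean molar
#' volume.
#'
#' @param system a [SAXSSystem-class]
#' @param c0 protein concentration at 298.15 K [g/L]
#' @param T temperature [K]
#' @param CG0 cosolvent molarity at 298.15 K [mol/L]
#' @param J attraction depth [k_B T] (per-curve parameter)
#' @param d attraction range [Angstrom] (per-curve parameter)
#' @param interactions logical; FALSE forces S_M = 1
#' @return list with q, I [1/cm], P, beta, S, SM, n [1/cm^3], and the
#'   [EquilibriumSolution-class] as `solution`
#' @export
modelIntensity <- function(system, c0, T, CG0 = 0, J = 0, d = 10,
                           interactions = TRUE) {
  stopifnot(is(system, "SAXSSystem"))
  sample <- sampleComposition(c0 = c0, M1 = system@M1, T = T, CG0 = CG0,
                              pH = system@pH, cosolv = system@cosolv,
                              nuP0 = system@nuP0, alphaP = system@alphaP)
  sol <- solveDistribution(system@states, system@transitions,
                           system@exchanges, sample, system@env)
  bW <- .pc$b_W
  bG <- if (is.null(system@cosolv)) 0 else scatteringLength(system@cosolv)
  rho0 <- sldBulk(sol@xGb, sol@nuWb, sol@nuGb, bW, bG)
  ids <- vapply(system@states, function(s) s@id, character(1))
  tables <- vector("list", length(ids))
  for (j in seq_along(system@states)) {
    s <- system@states[[j]]
    dom <- localDomain(s@m, s@m2, sol@phi[[s@id]], sol@xGb,
                       nuWs = sol@nuWb / s@d, nuGs = sol@nuGb,
                       nuWb = sol@nuWb, nuGb = sol@nuGb)
    rhoLd <- sldLocal(dom, bW, bG)
    memb <- lapply(system@bases[[s@id]], evaluateFormFactor,
                   rho0 = rho0, rhoLd = rhoLd)
    tables[[j]] <- if (length(memb) == 1L) memb[[1]] else
      ensembleFormFactor(memb)
  }
  eff <- effectiveFormFactor(tables, as.numeric(sol@x))
  n <- sol@CP * .pc$N_A / 1000          # monomers per cm^3 at T
  if (interactions) {
    alpha <- vapply(system@states, function(s) s@alpha, numeric(1))
    Rj <- vapply(system@states, function(s) s@R, numeric(1))
    Zj <- vapply(system@states, function(s) s@Z, numeric(1))
    avg <- averageRadiusCharge(as.numeric(sol@x), alpha, Rj, Zj, n = n)
    im <- interactionModel(R = avg$R, Z = if (system@env@electrostatics)
      avg$Z else 0, J = J, d = d, T = T, nPart = avg$nPart,
      kappaD = sol@kappaD, eps = waterDielectric(T))
    S <- rpaStructureFactor(system@q, im)
    SM <- measuredStructureFactor(S, eff$beta)
  } else {
    S <- SM <- rep(1, length(system@q))
  }
  list(q = system@q, I = n * eff$P * SM, P = eff$P, beta = eff$beta,
       S = S, SM = SM, n = n, solution = sol)
}

#' Average reduced chi-square of a curve batch
#'
#' Mean over curves of the per-curve mean squared standardized
#' residuals (each curve first averaged over its own q points, then the
#' curve values averaged - the order matters for unequal point counts).
#'
#' @param curves list of [ScatteringCurve-class]
#' @param models list of theoretical intensity vectors on matching grids
#' @return the average reduced chi-square
#' @export
chiSquare <- function(curves, models) {
  stopifnot(length(curves) == length(models), length(curves) >= 1)
  perCurve <- vapply(seq_along(curves), function(k) {
    cv <- curves[[k]]
    Ik <- if (is.list(models[[k]])) models[[k]]$I else models[[k]]
    if (length(Ik) != length(cv@q)) stop("grid mismatch for curve ", k)
    mean(((cv@I - Ik) / cv@sigma)^2)
  }, numeric(1))
  mean(perCurve)
}

#' Regularization penalty over per-curve parameters
#'
#' For each per-curve fitting parameter (columns of X: the attraction
#' depth J and range d) and each curve k, finds for every curve label p
#' the neighbour curve k' identical in the other three labels and
#' nearest in p (ties resolved towards the smaller value) and adds
#' \eqn{(1 - X_{i,k'}/X_{i,k})^2}. Curves without a neighbour in a label
#' contribute nothing for that label.
#'
#' @param X numeric matrix, curves x per-curve parameters (J, d); all
#'   entries non-zero
#' @param meta data.frame with columns c0, T, G, CG0 (one row per curve)
#' @return the penalty L
#' @export
regularizationPenalty <- function(X, meta) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == nrow(meta))
  if (any(X == 0)) stop("per-curve parameters must be non-zero (ratios used)")
  labs <- c("c0", "T", "G", "CG0")
  stopifnot(all(labs %in% names(meta)))
  # numeric encoding for the categorical cosolvent label
  meta2 <- meta[labs]
  meta2$G <- as.numeric(factor(meta$G))
  L <- 0
  for (k in seq_len(nrow(X))) {
    for (p in seq_along(labs)) {
      others <- setdiff(seq_along(labs), p)
      same <- rep(TRUE, nrow(X))
      for (o in others) same <- same & meta2[[o]] == meta2[[o]][k]
      cand <- which(same & meta2[[p]] != meta2[[p]][k])
      if (!length(cand)) next
      dist <- abs(meta2[[p]][cand] - meta2[[p]][k])
      best <- cand[order(dist, meta2[[p]][cand])][1]
      L <- L + sum((1 - X[best, ] / X[k, ])^2)
    }
  }
  L
}
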