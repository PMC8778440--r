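#' Generate a toy pseudo-atomic structure
#'
#' Deterministic test structures for the scattering machinery: a
#' uniformly filled sphere, a dumbbell of two spheres, or a seeded
#' self-avoiding random-walk coil. Spheres and dumbbells are filled on a
#' cubic grid (uniform density, no sampling noise); the coil uses a
#' fixed-step self-avoiding walk.
#'
#' @param kind "sphere", "dumbbell" or "coil"
#' @param size sphere radius [Angstrom] (per lobe for the dumbbell);
#'   ignored for the coil
#' @param nAtoms approximate number of pseudo-atoms (>= 10); exact for
#'   the coil
#' @param seed integer seed (used by the coil walk)
#' @param element element symbol assigned to every pseudo-atom
#' @param separation centre-to-centre lobe distance for the dumbbell
#'   [Angstrom], default 8/3 of the lobe radius
#' @param step coil bond length [Angstrom], default 3.8
#' @return an [AtomicStructure-class]
#' @examples
#' sph <- makeToyStructure("sphere", size = 20, nAtoms = 400)
#' sqrt(mean(rowSums(scale(coords(sph), scale = FALSE)^2)))  # about sqrt(3/5)*20
#' @export
makeToyStructure <- function(kind = c("sphere", "dumbbell", "coil"),
                             size = 15, nAtoms = 300, seed = 1,
                             element = "O", separation = 8 / 3 * size,
                             step = 3.8) {
  kind <- match.arg(kind)
  if (nAtoms < 10) stop("nAtoms must be at least 10")
  fillSphere <- function(R, n) {
    s <- (4 / 3 * pi * R^3 / n)^(1 / 3)
    g <- seq(-R, R, by = s)
    pts <- as.matrix(expand.grid(x = g, y = g, z = g))
    pts[rowSums(pts^2) <= R^2, , drop = FALSE]
  }
  xyz <- switch(kind,
    sphere = fillSphere(size, nAtoms),
    dumbbell = {
      lobe <- fillSphere(size, round(nAtoms / 2))
      rbind(sweep(lobe, 2, c(-separation / 2, 0, 0)),
            sweep(lobe, 2, c(+separation / 2, 0, 0)))
    },
    coil = .withSeed(seed, {
      pos <- matrix(0, nAtoms, 3)
      i <- 2L; tries <- 0L
      while (i <= nAtoms && tries < 20000L) {
        u <- stats::rnorm(3)
        cand <- pos[i - 1L, ] + step * u / sqrt(sum(u^2))
        prev <- pos[seq_len(i - 2L), , drop = FALSE]
        ok <- i <= 2L || min(rowSums(sweep(prev, 2, cand)^2)) > (0.9 * step)^2
        tries <- tries + 1L
        if (ok) { pos[i, ] <- cand; i <- i + 1L }
      }
      if (i <= nAtoms) stop("self-avoiding walk failed to place all beads")
      pos
    }))
  if (nrow(xyz) < 10) stop("infeasible packing: fewer than 10 atoms placed")
  atomicStructure(xyz, rep(element, nrow(xyz)))
}

#' SyntheticScenario: design of a simulated SAXS batch
#'
#' The generator's defaults encode the study conditions this package
#' targets: dilute protein (grams per litre), modified-sugar-like
#' cosolvent below 0.25 M, temperatures between 25 and 60 C, and
#' synchrotron-like noise (a 2 percent relative component plus a small
#' constant floor).
#'
#' @slot system a [SAXSSystem-class] holding the true thermodynamics
#' @slot design data.frame with columns c0, T, CG0 (one row per curve)
#' @slot J,d true per-curve interaction parameters (recycled)
#' @slot noiseRel relative noise fraction
#' @slot noiseFloor constant noise floor [1/cm]
#' @slot noiseCount counting-like coefficient (sigma term prop. sqrt(I))
#' @slot seed integer seed
#' @export
setClass("SyntheticScenario",
         representation(system = "ANY", design = "data.frame", J = "numeric",
                        d = "numeric", noiseRel = "numeric",
                        noiseFloor = "numeric", noiseCount = "numeric",
                        seed = "numeric"),
         validity = function(object) {
           if (!all(c("c0", "T", "CG0") %in% names(object@design)))
             return("design needs columns c0, T, CG0")
           if (object@noiseRel < 0) return("negative relative noise")
           TRUE
         })

#' Construct a SyntheticScenario
#' @param system a [SAXSSystem-class]
#' @param design data.frame with columns c0 [g/L], T [K], CG0 [M]
#' @param J,d per-curve interaction truth (recycled over curves)
#' @param noiseRel relative noise fraction (default 0.02)
#' @param noiseFloor constant noise floor [1/cm] (default 1e-5)
#' @param noiseCount counting-like coefficient (default 0)
#' @param seed integer seed (default 1)
#' @return a [SyntheticScenario-class]
#' @export
syntheticScenario <- function(system, design, J = 1, d = 10,
                              noiseRel = 0.02, noiseFloor = 1e-5,
                              noiseCount = 0, seed = 1) {
  new("SyntheticScenario", system = system, design = design, J = J, d = d,
      noiseRel = noiseRel, noiseFloor = noiseFloor, noiseCount = noiseCount,
      seed = seed)
}

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf(
    "SyntheticScenario: %d curves, noise %.1f%% + %.1e 1/cm, seed %d\n",
    nrow(object@design), 100 * object@noiseRel, object@noiseFloor,
    as.integer(object@seed)))
})

#' Default monomer-dimer recovery scenario
#'
#' The canonical parameter-recovery setup: a monomer-dimer protein
#' (myoglobin-like hydration site counts, radii and charges) with one
#' neutral cosolvent, a 12-curve design crossing two protein
#' concentrations (2 and 10 g/L), three temperatures (25, 45, 60 C) and
#' two cosolvent levels (0 and 0.15 M), 2 percent relative noise. The
#' true thermodynamics put the monomer-dimer midpoint inside the
#' temperature window so both transition and exchange parameters are
#' identifiable.
#'
#' @param seed integer seed
#' @param nq q points per curve (default 100)
#' @return a [SyntheticScenario-class]
#' @export
defaultRecoveryScenario <- function(seed = 1, nq = 100) {
  mono <- makeToyStructure("sphere", size = 14, nAtoms = 260)
  dimer <- makeToyStructure("dumbbell", size = 14, nAtoms = 520,
                            separation = 30)
  states <- list(
    proteinState("1", alpha = 1, m = 404, m2 = 465, R = 17.0, Z = 5,
                 d = 1.07, structure = mono),
    proteinState("2", alpha = 2, m = 753, m2 = 827, R = 26.7, Z = 10,
                 d = 1.07, structure = dimer))
  transitions <- list("2" = thermoTriplet(dG0 = -11, dS0 = 300, dCp = 0))
  exchanges <- list("1" = thermoTriplet(dG0 = 1.5, dS0 = 0, dCp = 0),
                    "2" = thermoTriplet(dG0 = -2, dS0 = 0, dCp = 0))
  cs <- cosolvent("G1", nuGb0 = 0.2, Ne = 180, alphaG = 5e-4, ionic = FALSE)
  sys <- saxsSystem(states, transitions, exchanges, M1 = 17000, pH = 5,
                    cosolv = cs, env = ionicEnvironment(IS = 0.01),
                    q = defaultQGrid(nq))
  design <- expand.grid(c0 = c(2, 10), T = 273.15 + c(25, 45, 60),
                        CG0 = c(0, 0.15))
  syntheticScenario(sys, design, J = 1.2, d = 12, noiseRel = 0.02,
                    noiseFloor = 1e-5, seed = seed)
}

#' Simulate a SAXS batch from a scenario
#'
#' Evaluates the forward model at every design point and adds Gaussian
#' noise with \eqn{\sigma(q) = floor + rel \cdot I + count \sqrt{I}}.
#' Byte-identical output for a fixed seed.
#'
#' @param scenario a [SyntheticScenario-class]
#' @param noise logical: add noise (FALSE returns exact model curves,
#'   with the same sigma column)
#' @return list with `curves` (list of [ScatteringCurve-class]),
#'   `manifest` (the design data.frame plus cosolvent id) and `truth`
#'   (list: transitions, exchanges, J, d)
#' @export
simulateBatch <- function(scenario, noise = TRUE) {
  stopifnot(is(scenario, "SyntheticScenario"))
  sys <- scenario@system
  des <- scenario@design
  nC <- nrow(des)
  J <- rep_len(scenario@J, nC)
  d <- rep_len(scenario@d, nC)
  Gid <- if (is.null(sys@cosolv)) "" else sys@cosolv@id
  curves <- .withSeed(scenario@seed, {
    lapply(seq_len(nC), function(k) {
      mod <- modelIntensity(sys, c0 = des$c0[k], T = des$T[k],
                            CG0 = des$CG0[k], J = J[k], d = d[k])
      sig <- scenario@noiseFloor + scenario@noiseRel * abs(mod$I) +
        scenario@noiseCount * sqrt(abs(mod$I))
      Iobs <- if (noise) mod$I + stats::rnorm(length(mod$I), 0, sig) else mod$I
      scatteringCurve(q = mod$q, I = Iobs, sigma = sig, c0 = des$c0[k],
                      T = des$T[k], G = if (des$CG0[k] > 0) Gid else "",
                      CG0 = des$CG0[k])
    })
  })
  manifest <- cbind(des, G = ifelse(des$CG0 > 0, Gid, ""),
                    stringsAsFactors = FALSE)
  list(curves = curves, manifest = manifest,
       truth = list(transitions = sys@transitions, exchanges = sys@exchanges,
                    J = J, d = d))
}

#' Seeded parameter-recovery experiment
#'
#' Simulates a batch from the scenario, perturbs the declared free
#' parameters, refits them with [globalFit()] and reports truth versus
#' estimate, bias, and the chi-square at the true parameters (which
#' should sit at the noise floor of 1).
#'
#' @param scenario a [SyntheticScenario-class]
#' @param free free-parameter table (rows from [freeParameter()]);
#'   default frees the transition dG0/dS0 and both exchange dG0
#' @param gamma regularization constant
#' @param seed fit-stage seed (the data seed lives in the scenario)
#' @param control passed to [globalFit()]
#' @return list with truth, estimate, se, bias, chi2AtTruth and the
#'   [SAXSFit-class] object
#' @export
recoveryExperiment <- function(scenario, free = NULL, gamma = 1e-7,
                               seed = 1, control = list()) {
  if (is.null(free))
    free <- rbind(
      freeParameter("transition", "2", "dG0", -25, 5),
      freeParameter("transition", "2", "dS0", 0, 600),
      freeParameter("exchange", "1", "dG0", -12, 12),
      freeParameter("exchange", "2", "dG0", -12, 12))
  sim <- simulateBatch(scenario)
  sys <- scenario@system
  truthOf <- function(row) {
    lst <- if (row["block"] == "transition") sys@transitions else sys@exchanges
    tt <- lst[[row[["id"]]]]
    switch(row[["param"]], dG0 = tt@dG0 / 1000, dS0 = tt@dS0, dCp = tt@dCp)
  }
  truth <- apply(free, 1, truthOf)
  ctl <- modifyList(list(J = scenario@J[1], d = scenario@d[1]), control)
  fit <- globalFit(sim$curves, sys, free, gamma = gamma, seed = seed,
                   perCurve = FALSE, control = ctl)
  # chi-square with every parameter at truth
  modelsTruth <- lapply(seq_along(sim$curves), function(k)
    modelIntensity(sys, c0 = scenario@design$c0[k], T = scenario@design$T[k],
                   CG0 = scenario@design$CG0[k],
                   J = rep_len(scenario@J, length(sim$curves))[k],
                   d = rep_len(scenario@d, length(sim$curves))[k]))
  chi2Truth <- chiSquare(sim$curves, modelsTruth)
  est <- fit@par
  list(truth = stats::setNames(truth, names(est)), estimate = est,
       se = fit@parSE, bias = est - truth, chi2AtTruth = chi2Truth,
       fit = fit, curves = sim$curves)
}
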