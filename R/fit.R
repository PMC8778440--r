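# run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# compact seeded differential evolution (rand/1/bin) under box bounds
.deOptimise <- function(fn, lower, upper, seed = 1, popSize = NULL,
                        maxGen = 60, F = 0.8, CR = 0.9) {
  np <- length(lower)
  if (is.null(popSize)) popSize <- max(16L, 6L * np)
  .withSeed(seed, {
    pop <- matrix(stats::runif(popSize * np, lower, upper), popSize, np,
                  byrow = TRUE)
    cost <- apply(pop, 1, fn)
    nev <- popSize
    for (g in seq_len(maxGen)) {
      for (i in seq_len(popSize)) {
        idx <- sample(setdiff(seq_len(popSize), i), 3)
        trial <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
        cross <- stats::runif(np) < CR
        cross[sample(np, 1)] <- TRUE
        trial <- ifelse(cross, trial, pop[i, ])
        trial <- pmin(pmax(trial, lower), upper)
        ct <- fn(trial); nev <- nev + 1L
        if (ct <= cost[i]) { pop[i, ] <- trial; cost[i] <- ct }
      }
    }
    best <- which.min(cost)
    list(par = pop[best, ], value = cost[best], evaluations = nev)
  })
}

#' Declare a free global fit parameter
#'
#' @param block one of "transition", "exchange" (thermodynamic triplets),
#'   "state" (per-state structural parameter) or "env"
#' @param id state id the parameter belongs to ("" for env)
#' @param param for triplets one of "dG0" [kJ/mol], "dS0", "dCp"
#'   [J/mol/K]; for states one of "d", "R", "Z"; for env "IS" [mol/L]
#' @param lower,upper box bounds (in the interface units above)
#' @return one-row data.frame to be rbind-ed into a free-parameter table
#' @examples
#' rbind(freeParameter("transition", "2", "dG0", -40, 0),
#'       freeParameter("exchange", "1", "dG0", -15, 15))
#' @export
freeParameter <- function(block, id, param, lower, upper) {
  stopifnot(block %in% c("transition", "exchange", "state", "env"),
            lower < upper)
  data.frame(block = block, id = id, param = param, lower = lower,
             upper = upper, stringsAsFactors = FALSE)
}

# return a copy of the system with the global parameters set to theta
.applyParams <- function(system, free, theta) {
  for (r in seq_len(nrow(free))) {
    b <- free$block[r]; id <- free$id[r]; pm <- free$param[r]; v <- theta[r]
    if (b %in% c("transition", "exchange")) {
      slotName <- if (b == "transition") "transitions" else "exchanges"
      tt <- slot(system, slotName)[[id]]
      if (is.null(tt)) tt <- thermoTriplet(0, 0, 0)
      if (pm == "dG0") tt@dG0 <- v * 1000
      else if (pm == "dS0") tt@dS0 <- v
      else if (pm == "dCp") tt@dCp <- v
      else stop("unknown triplet parameter: ", pm)
      tmp <- slot(system, slotName); tmp[[id]] <- tt
      slot(system, slotName) <- tmp
    } else if (b == "state") {
      j <- which(vapply(system@states, function(s) s@id, character(1)) == id)
      if (!length(j)) stop("unknown state id: ", id)
      slot(system@states[[j]], pm) <- v
    } else if (b == "env") {
      if (pm != "IS") stop("unknown env parameter: ", pm)
      system@env@IS <- v
    }
  }
  system
}

#' SAXSFit: result of the regularized global fit
#'
#' @slot par named vector of fitted global parameters (interface units)
#' @slot parSE covariance-based standard errors (NA when not computed)
#' @slot perCurve matrix (curves x 2) of fitted (J, d); zero rows when
#'   the per-curve stage was not free
#' @slot chi2 average reduced chi-square
#' @slot L regularization penalty
#' @slot H merit function, exactly chi2 + gamma * L
#' @slot gamma regularization constant
#' @slot free the free-parameter table
#' @slot meta per-curve labels (c0, T, G, CG0)
#' @slot evaluations objective evaluation count
#' @export
setClass("SAXSFit",
         representation(par = "numeric", parSE = "numeric",
                        perCurve = "matrix", chi2 = "numeric", L = "numeric",
                        H = "numeric", gamma = "numeric", free = "data.frame",
                        meta = "data.frame", evaluations = "numeric"))

setMethod("show", "SAXSFit", function(object) {
  cat(sprintf("SAXSFit: H=%.4f = chi2 %.4f + gamma*L %.4g (gamma=%.1e)\n",
              object@H, object@chi2, object@gamma * object@L, object@gamma))
  for (i in seq_along(object@par)) {
    se <- object@parSE[i]
    cat(sprintf("  %-28s %12.5g%s\n", names(object@par)[i], object@par[i],
                if (is.finite(se)) sprintf(" +/- %.3g", se) else ""))
  }
  if (nrow(object@perCurve))
    cat(sprintf("  per-curve J in [%.2f, %.2f] kT, d in [%.1f, %.1f] A\n",
                min(object@perCurve[, 1]), max(object@perCurve[, 1]),
                min(object@perCurve[, 2]), max(object@perCurve[, 2])))
})

#' @describeIn globalFit accessor, fitted global parameters
#' @param object a SAXSFit
#' @export
fittedParameters <- function(object) object@par
#' @describeIn globalFit accessor, the merit decomposition
#' @export
meritFunction <- function(object) c(H = object@H, chi2 = object@chi2,
                                    L = object@L, gamma = object@gamma)

#' Regularized global fit of a SAXS curve batch
#'
#' Minimizes the merit function \eqn{H = \chi^2 + \gamma L} over the
#' declared global thermodynamic/structural parameters and (optionally)
#' the per-curve interaction parameters (J, d), where \eqn{\chi^2} is the
#' average reduced chi-square over the batch and L the neighbour-ratio
#' regularization of the per-curve parameters. A seeded
#' differential-evolution global stage is followed by a Nelder-Mead
#' polish; the contract is the minimized H, not the optimisation path.
#'
#' @param curves list of [ScatteringCurve-class] sharing the system q grid
#' @param system a [SAXSSystem-class]
#' @param free free-parameter table built from [freeParameter()] rows
#' @param gamma regularization constant (default 1e-7)
#' @param seed integer seed for the stochastic stage
#' @param perCurve logical: fit (J, d) per curve; otherwise they are
#'   fixed at control$J, control$d
#' @param control list: popSize, maxGen, localMaxit (default 300),
#'   J (default 0), d (default 10), Jbounds (default c(0.05, 15)),
#'   dbounds (default c(2, 40)), uncertainties (default TRUE: covariance
#'   SEs for the global parameters from the numerical Hessian of the
#'   summed squared residuals)
#' @return a [SAXSFit-class]
#' @export
globalFit <- function(curves, system, free, gamma = 1e-7, seed = 1,
                      perCurve = FALSE, control = list()) {
  ctl <- modifyList(list(popSize = NULL, maxGen = 30, localMaxit = 1000,
                         J = 0, d = 10, Jbounds = c(0.05, 15),
                         dbounds = c(2, 40), uncertainties = TRUE), control)
  stopifnot(length(curves) >= 1, nrow(free) >= 1)
  meta <- do.call(rbind, lapply(curves, function(cv)
    data.frame(c0 = cv@c0, T = cv@T, G = cv@G, CG0 = cv@CG0,
               stringsAsFactors = FALSE)))
  if (any(free$block == "exchange") && all(meta$CG0 == 0))
    warning("exchange parameters are free but no curve contains cosolvent: ",
            paste(free$id[free$block == "exchange"], collapse = ", "),
            " unconstrained")
  nG <- nrow(free)
  nC <- length(curves)
  lower <- free$lower; upper <- free$upper
  if (perCurve) {
    lower <- c(lower, rep(c(ctl$Jbounds[1], ctl$dbounds[1]), each = nC))
    upper <- c(upper, rep(c(ctl$Jbounds[2], ctl$dbounds[2]), each = nC))
  }
  nEval <- 0L
  scale <- (upper - lower)
  objective <- function(thetaRaw) {
    nEval <<- nEval + 1L
    theta <- pmin(pmax(thetaRaw, lower), upper)
    # smooth quadratic penalty outside the box keeps simplex methods
    # from collapsing on a flat clamped plateau
    outOfBox <- sum(((thetaRaw - theta) / scale)^2)
    sys2 <- .applyParams(system, free, theta[seq_len(nG)])
    Jk <- if (perCurve) theta[nG + seq_len(nC)] else rep(ctl$J, nC)
    dk <- if (perCurve) theta[nG + nC + seq_len(nC)] else rep(ctl$d, nC)
    chi2 <- tryCatch(withCallingHandlers({
      models <- lapply(seq_len(nC), function(k)
        modelIntensity(sys2, c0 = meta$c0[k], T = meta$T[k],
                       CG0 = meta$CG0[k], J = Jk[k], d = dk[k]))
      chiSquare(curves, models)
    }, warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NA_real_)
    if (!is.finite(chi2)) return(1e8)
    L <- if (perCurve) regularizationPenalty(cbind(Jk, dk), meta) else 0
    chi2 + gamma * L + 100 * outOfBox
  }
  de <- .deOptimise(objective, lower, upper, seed = seed,
                    popSize = ctl$popSize, maxGen = ctl$maxGen)
  ps <- (upper - lower) / 20
  polish <- function(start) {
    nm <- if (length(start) == 1L)
      stats::optim(start, objective, method = "Brent", lower = lower,
                   upper = upper)
    else
      stats::optim(start, objective, method = "Nelder-Mead",
                   control = list(maxit = ctl$localMaxit,
                                  reltol = 1e-12, parscale = ps))
    bf <- tryCatch(
      stats::optim(nm$par, objective, method = "BFGS",
                   control = list(maxit = 50, reltol = 1e-12,
                                  parscale = ps)),
      error = function(e) nm)
    if (bf$value <= nm$value) bf else nm
  }
  # polish from the DE best and from the box midpoint, keep the better
  cand <- list(polish(de$par), polish((lower + upper) / 2))
  pol <- cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]
  best <- pmin(pmax(pol$par, lower), upper)
  # final decomposition at the optimum
  sys2 <- .applyParams(system, free, best[seq_len(nG)])
  Jk <- if (perCurve) best[nG + seq_len(nC)] else rep(ctl$J, nC)
  dk <- if (perCurve) best[nG + nC + seq_len(nC)] else rep(ctl$d, nC)
  models <- lapply(seq_len(nC), function(k)
    modelIntensity(sys2, c0 = meta$c0[k], T = meta$T[k], CG0 = meta$CG0[k],
                   J = Jk[k], d = dk[k]))
  chi2 <- chiSquare(curves, models)
  L <- if (perCurve) regularizationPenalty(cbind(Jk, dk), meta) else 0
  parNames <- paste(free$block, free$id, free$param, sep = ".")
  parSE <- rep(NA_real_, nG)
  if (isTRUE(ctl$uncertainties)) {
    parSE <- tryCatch(
      .covarianceSE(best[seq_len(nG)], free, system, curves, meta, Jk, dk),
      error = function(e) rep(NA_real_, nG))
  }
  new("SAXSFit", par = stats::setNames(best[seq_len(nG)], parNames),
      parSE = stats::setNames(parSE, parNames),
      perCurve = if (perCurve) cbind(J = Jk, d = dk) else
        matrix(numeric(0), 0, 2, dimnames = list(NULL, c("J", "d"))),
      chi2 = chi2, L = L, H = chi2 + gamma * L, gamma = gamma, free = free,
      meta = meta, evaluations = nEval)
}

# covariance-based standard errors from the numerical Hessian of the
# summed squared standardized residuals (per-curve parameters frozen)
.covarianceSE <- function(thetaG, free, system, curves, meta, Jk, dk) {
  ssr <- function(th) {
    sys2 <- .applyParams(system, free, th)
    s <- 0
    for (k in seq_along(curves)) {
      mod <- modelIntensity(sys2, c0 = meta$c0[k], T = meta$T[k],
                            CG0 = meta$CG0[k], J = Jk[k], d = dk[k])
      s <- s + sum(((curves[[k]]@I - mod$I) / curves[[k]]@sigma)^2)
    }
    s
  }
  p <- length(thetaG)
  h <- pmax(abs(thetaG) * 1e-3, 1e-4)
  H <- matrix(0, p, p)
  f0 <- ssr(thetaG)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- ej <- numeric(p); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      H[i, i] <- (ssr(thetaG + ei) - 2 * f0 + ssr(thetaG - ei)) / h[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (ssr(thetaG + ei + ej) - ssr(thetaG + ei - ej) -
           ssr(thetaG - ei + ej) + ssr(thetaG - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  cov <- 2 * solve(H)
  se <- sqrt(pmax(diag(cov), 0))
  se
}

#' State-population phase diagram over temperature and cosolvent
#'
#' Solves the equilibrium on a temperature x cosolvent-concentration
#' grid (no scattering step needed) and extracts, per state and per
#' cosolvent column, the temperature at which its population crosses
#' one half - the boundary between dominant-state regions.
#'
#' @param system a [SAXSSystem-class]
#' @param Tgrid temperatures [K]
#' @param CGgrid cosolvent molarities at 298.15 K [mol/L]
#' @param c0 protein concentration [g/L]
#' @return list with `table` (long data.frame: T, CG0, state, x, phi) and
#'   `contours` (data.frame: state, CG0, T at x = 0.5; one row per
#'   crossing)
#' @export
phaseDiagram <- function(system, Tgrid, CGgrid, c0) {
  stopifnot(is(system, "SAXSSystem"))
  ids <- vapply(system@states, function(s) s@id, character(1))
  rows <- list()
  for (CG in CGgrid) for (T in Tgrid) {
    sample <- sampleComposition(c0 = c0, M1 = system@M1, T = T, CG0 = CG,
                                pH = system@pH, cosolv = system@cosolv,
                                nuP0 = system@nuP0, alphaP = system@alphaP)
    sol <- solveDistribution(system@states, system@transitions,
                             system@exchanges, sample, system@env)
    rows[[length(rows) + 1L]] <- data.frame(
      T = T, CG0 = CG, state = ids, x = as.numeric(sol@x),
      phi = as.numeric(sol@phi), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  cont <- list()
  for (id in ids) for (CG in CGgrid) {
    sub <- tab[tab$state == id & tab$CG0 == CG, ]
    sub <- sub[order(sub$T), ]
    dx <- sub$x - 0.5
    cr <- which(dx[-1] * dx[-length(dx)] < 0)
    for (i in cr) {
      frac <- dx[i] / (dx[i] - dx[i + 1])
      cont[[length(cont) + 1L]] <- data.frame(
        state = id, CG0 = CG, T = sub$T[i] + frac * (sub$T[i + 1] - sub$T[i]),
        stringsAsFactors = FALSE)
    }
  }
  contours <- if (length(cont)) do.call(rbind, cont) else
    data.frame(state = character(0), CG0 = numeric(0), T = numeric(0))
  list(table = tab, contours = contours)
}
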