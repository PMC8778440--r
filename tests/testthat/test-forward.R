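# a small single-state system shared across forward-model tests
fxSystem1 <- local({
  mono <- makeToyStructure("sphere", size = 12, nAtoms = 200)
  st <- list(proteinState("1", 1, 400, 450, 14, 0, d = 1.07,
                          structure = mono))
  saxsSystem(st, list(), list(), M1 = 17000, pH = 7,
             env = ionicEnvironment(electrostatics = FALSE),
             q = defaultQGrid(40))
})

test_that("number density follows c NA / M1 and doubles with concentration", {
  mod <- modelIntensity(fxSystem1, c0 = 2, T = 298.15, interactions = FALSE)
  expect_equal(mod$n, 2 * pc$N_A / 17000 / 1000, tolerance = 2e-3)
  mod2 <- modelIntensity(fxSystem1, c0 = 4, T = 298.15,
                         interactions = FALSE)
  expect_equal(mod2$I / mod$I, rep(2, 40), tolerance = 2e-3)
  # thermal expansion dilutes the sample at higher T
  modT <- modelIntensity(fxSystem1, c0 = 2, T = 333.15,
                         interactions = FALSE)
  expect_lt(modT$n, mod$n)
  expect_equal(modT$n / mod$n, waterMolarVolume(298.15) /
                 waterMolarVolume(333.15), tolerance = 1e-3)
})

test_that("intensity chain composes n, P and S_M", {
  mod <- modelIntensity(fxSystem1, c0 = 2, T = 298.15, J = 1.5, d = 12)
  expect_equal(mod$I, mod$n * mod$P * mod$SM, tolerance = 1e-12)
  expect_true(all(mod$SM > 0))
  # with interactions off the measured structure factor is identity
  mod0 <- modelIntensity(fxSystem1, c0 = 2, T = 298.15,
                         interactions = FALSE)
  expect_equal(mod0$SM, rep(1, 40))
  expect_equal(mod0$I, mod0$n * mod0$P, tolerance = 1e-12)
})

test_that("average reduced chi-square averages curves after points", {
  q <- defaultQGrid(25)
  cv <- function(I, s) scatteringCurve(q, I, rep(s, 25), 2, 298.15)
  I0 <- exp(-q * 3)
  expect_identical(chiSquare(list(cv(I0, 0.1)), list(I0)), 0)
  expect_equal(chiSquare(list(cv(I0 + 0.1, 0.1)), list(I0)), 1)
  # per-curve values 0.5 and 1.5 average to 1 whatever the point counts
  c1 <- scatteringCurve(q, I0 + sqrt(0.5) * 0.1, rep(0.1, 25), 2, 298.15)
  q2 <- defaultQGrid(50); I2 <- exp(-q2 * 3)
  c2 <- scatteringCurve(q2, I2 + sqrt(1.5) * 0.2, rep(0.2, 50), 2, 308.15)
  expect_equal(chiSquare(list(c1, c2), list(I0, I2)), 1, tolerance = 1e-12)
})

test_that("regularization pairs curves that differ in exactly one label", {
  meta <- data.frame(c0 = c(2, 2), T = c(298.15, 308.15), G = c("", ""),
                     CG0 = c(0, 0))
  X <- cbind(J = c(1.0, 1.1), d = c(10, 10))
  L <- regularizationPenalty(X, meta)
  expect_equal(L, (1 - 1.1 / 1.0)^2 + (1 - 1.0 / 1.1)^2, tolerance = 1e-12)
  # identical per-curve parameters give zero penalty
  X0 <- cbind(J = c(1, 1), d = c(10, 10))
  expect_identical(regularizationPenalty(X0, meta), 0)
  # an isolated curve (different in two labels) contributes nothing
  meta2 <- data.frame(c0 = c(2, 10), T = c(298.15, 308.15), G = c("", ""),
                      CG0 = c(0, 0))
  expect_identical(regularizationPenalty(X, meta2), 0)
  # nearest neighbour in the varied label wins
  meta3 <- data.frame(c0 = 2, T = c(298, 308, 318), G = "", CG0 = 0)
  X3 <- cbind(J = c(1, 1, 2), d = c(10, 10, 10))
  # curve 1 pairs with 2 (same J), curve 3 pairs with 2: terms from 1<->2
  # vanish, 3 contributes (1 - 1/2)^2 and 2 contributes 0 against 1
  expect_equal(regularizationPenalty(X3, meta3), (1 - 1 / 2)^2,
               tolerance = 1e-12)
  expect_error(regularizationPenalty(cbind(c(0, 1), c(1, 1)), meta),
               "non-zero")
})

test_that("merit decomposition is exact and per-curve parameters respond to gamma", {
  # tiny two-curve monomer-dimer batch, per-curve (J, d) free
  scen <- getScenario()
  sys <- scen@system
  des <- data.frame(c0 = c(10, 10), T = c(318.15, 328.15), CG0 = c(0, 0))
  sub <- syntheticScenario(sys, des, J = 1.2, d = 12, noiseRel = 0.02,
                           seed = 5)
  sim <- simulateBatch(sub)
  free <- freeParameter("transition", "2", "dG0", -14, -8)
  fit <- globalFit(sim$curves, sys, free, gamma = 1e-7, seed = 2,
                   perCurve = TRUE,
                   control = list(popSize = 12, maxGen = 8,
                                  localMaxit = 400, uncertainties = FALSE))
  expect_identical(fit@H, fit@chi2 + fit@gamma * fit@L)
  expect_true(all(fit@perCurve[, "J"] >= 0.05 & fit@perCurve[, "J"] <= 15))
  expect_lt(abs(fit@par[[1]] - (-11)), 1)
  expect_lt(fit@chi2, 3)
  # a dominating penalty forces the per-curve parameters together
  fitBig <- globalFit(sim$curves, sys, free, gamma = 1e3, seed = 2,
                      perCurve = TRUE,
                      control = list(popSize = 12, maxGen = 8,
                                     localMaxit = 400,
                                     uncertainties = FALSE))
  expect_lt(abs(fitBig@perCurve[1, "J"] / fitBig@perCurve[2, "J"] - 1), 0.05)
  expect_lt(abs(fitBig@perCurve[1, "d"] / fitBig@perCurve[2, "d"] - 1), 0.05)
  expect_lt(fitBig@L, fit@L + 1e-9)
})

test_that("unconstrained exchange parameters are flagged", {
  scen <- getScenario()
  des <- data.frame(c0 = 2, T = 298.15, CG0 = 0)
  sim <- simulateBatch(syntheticScenario(scen@system, des, J = 1, d = 10,
                                         seed = 3))
  free <- freeParameter("exchange", "1", "dG0", -5, 5)
  expect_warning(
    globalFit(sim$curves, scen@system, free, seed = 1,
              control = list(popSize = 6, maxGen = 1, localMaxit = 5,
                             uncertainties = FALSE, J = 1, d = 10)),
    "unconstrained")
})

test_that("phase diagram grids conserve mass and cross at the midpoint once", {
  scen <- getScenario()
  sys <- scen@system
  Tg <- seq(298.15, 338.15, length.out = 9)
  pd <- phaseDiagram(sys, Tg, c(0, 0.15), c0 = 2)
  sums <- tapply(pd$table$x, list(pd$table$T, pd$table$CG0), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-8)
  # the no-cosolvent column reproduces a direct one-dimensional scan
  direct <- vapply(Tg, function(T) {
    sc <- sampleComposition(c0 = 2, M1 = sys@M1, T = T, pH = sys@pH,
                            nuP0 = sys@nuP0)
    unname(stateFractions(solveDistribution(sys@states, sys@transitions,
                                            sys@exchanges, sc, sys@env))[2])
  }, numeric(1))
  col0 <- pd$table[pd$table$CG0 == 0 & pd$table$state == "2", ]
  expect_equal(col0$x[order(col0$T)], direct, tolerance = 1e-10)
  # monotone dimer growth in T gives exactly one 0.5 crossing per column
  cross <- pd$contours[pd$contours$state == "2", ]
  expect_equal(nrow(cross[cross$CG0 == 0, ]), 1)
  expect_true(all(cross$T >= min(Tg) & cross$T <= max(Tg)))
})
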