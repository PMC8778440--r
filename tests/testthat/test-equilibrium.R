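test_that("exchange isotherm inversion is exact", {
  expect_identical(phiFromExchange(3, 0), 1)
  expect_equal(phiFromExchange(1, 0.5), 0.5)
  phi <- phiFromExchange(2, 0.2)
  expect_equal(phi, 1.6 / 1.8, tolerance = 1e-15)
  # substituting back into the isotherm recovers Kex = 2
  expect_equal(phi / (1 - phi) * 0.2 / 0.8, 2, tolerance = 1e-12)
  expect_warning(phiFromExchange(2, 1), "phi = 0")
  expect_error(phiFromExchange(2, 1.2), "0, 1")
})

test_that("effective constant carries the hydration-site exponents", {
  expect_equal(effectiveConstant(3, 1, 1, 1, 404, 753, 2), 3,
               tolerance = 1e-14)
  expect_equal(effectiveConstant(1, 1, 1, 0.99, 404, 753, 2),
               0.99^(753 / 2 - 404), tolerance = 1e-12)
  k1 <- effectiveConstant(1, 0.98, 0.99, 0.999, 404, 753, 2)
  k2 <- effectiveConstant(1, 0.99, 0.99, 0.999, 404, 753, 2)
  expect_gt(k2, k1)
  expect_error(effectiveConstant(1, 0, 1, 1, 404, 753, 2), "occupancy")
})

test_that("bulk composition limits and internal consistency hold", {
  st <- fxStatesMD()
  m <- c(400, 800); al <- c(1, 2)
  b0 <- bulkComposition(0, 0.005, c(1, 0), c(1, 1), m, al)
  expect_equal(b0$xGb, 0.005)
  bG <- bulkComposition(1e-4, 0, c(0.3, 0.7), c(0.9, 0.95), m, al)
  expect_equal(bG$xGb, 0)
  expect_equal(bG$XGb, 0)
  # xGb must equal XGb / (XGb + XWb)
  b <- bulkComposition(1e-4, 0.005, c(0.4, 0.6), c(0.97, 0.99), m, al)
  expect_equal(b$xGb, b$XGb / (b$XGb + b$XWb), tolerance = 1e-12)
  expect_error(bulkComposition(0.5, 0.005, c(1, 0), c(1, 1), m, al),
               "infeasible")
})

test_that("mean molar volume mixes components and site corrections", {
  mv <- meanMolarVolume(0, 0, 1, 1, 400, 1, 1.07, 12, 0.018, 0.2)
  expect_equal(mv$meanNu, 0.018)
  mv2 <- meanMolarVolume(0, 0.01, 1, 1, 400, 1, 1.07, 12, 0.018, 0.2)
  expect_equal(mv2$meanNu, 0.99 * 0.018 + 0.01 * 0.2, tolerance = 1e-12)
  # d = 1 removes the site correction entirely
  mv3 <- meanMolarVolume(1e-5, 0, c(0.5, 0.5), c(0.9, 0.9), c(400, 800),
                         c(1, 2), c(1, 1), 12, 0.018, 0.2)
  expect_equal(mv3$meanNu,
               12 * 1e-5 + 0.018 * (1 - 1e-5), tolerance = 1e-12)
})

test_that("single-state system is trivial and occupancies decouple", {
  st <- list(proteinState("1", 1, 400, 450, 17, 0, d = 1.07))
  cs <- cosolvent("G", nuGb0 = 0.2, Ne = 180)
  sc <- sampleComposition(c0 = 2, M1 = 17000, T = 298.15, CG0 = 0.1,
                          pH = 7, cosolv = cs)
  ex <- list("1" = thermoTriplet(dG0 = 2))
  sol <- solveDistribution(st, list(), ex, sc, noElec)
  expect_equal(unname(stateFractions(sol)), 1)
  expect_equal(unname(shellOccupancies(sol)),
               phiFromExchange(exp(-2000 / (RGAS * 298.15)), sol@xGb),
               tolerance = 1e-9)
})

test_that("monomer-dimer populations match the closed-form quadratic", {
  # balanced hydration counts isolate the mass action: stepwise constant
  # Kbar = Cdim/Cmono^2 = 1e5 1/M, effective K12 = sqrt(Kbar)
  st <- fxStatesMD()
  tr <- list("2" = tripletFromK(sqrt(1e5)))
  sc <- sampleComposition(c0 = 1e-4 * 17000, M1 = 17000, T = 298.15)
  sol <- solveDistribution(st, tr, NULL, sc, noElec)
  CP <- sol@CP
  C1 <- (-1 + sqrt(1 + 8e5 * CP)) / (4e5)
  expect_equal(unname(stateFractions(sol)),
               c(C1 / CP, 1 - C1 / CP), tolerance = 1e-8)
  # mass balances of the solution object close to 1e-10
  expect_equal(sum(stateFractions(sol)), 1, tolerance = 1e-12)
  b <- bulkComposition(sc@XP, sc@xG, as.numeric(sol@x), as.numeric(sol@phi),
                       c(400, 800), c(1, 2))
  expect_equal(b$XWb, sol@XWb, tolerance = 1e-10)
  expect_equal(b$XGb, sol@XGb, tolerance = 1e-10)
})

test_that("solver matches the independent polynomial oracle on multi-state systems", {
  # three systems of 2-4 states without cosolvent/electrostatics
  cases <- list(
    list(alpha = c(1, 2), K = c(1, 320)),
    list(alpha = c(1, 2, 4), K = c(1, 470, 1200)),
    list(alpha = c(1, 2, 4, 6), K = c(1, 470, 1185, 2141)))
  for (cs in cases) {
    m1 <- 200
    st <- lapply(seq_along(cs$alpha), function(j)
      proteinState(as.character(j), cs$alpha[j], m1 * cs$alpha[j],
                   m1 * cs$alpha[j], 10 + 5 * j, 0))
    tr <- lapply(cs$K[-1], tripletFromK)
    names(tr) <- vapply(st[-1], function(s) s@id, character(1))
    sc <- sampleComposition(c0 = 3e-4 * 5800, M1 = 5800, T = 298.15)
    sol <- solveDistribution(st, tr, NULL, sc, noElec)
    xo <- oracleMassAction(cs$K, cs$alpha, sol@CP)
    expect_equal(unname(stateFractions(sol)), xo, tolerance = 1e-8)
  }
})

test_that("insulin oligomerisation constants map correctly and solve to the oracle", {
  K <- insulinEffectiveConstants(2.22e5, 40, 220)
  # the printed stepwise relations are reproduced by the mapping
  expect_equal(unname(K["K12"]^2), 2.22e5, tolerance = 1e-12)
  expect_equal(unname((K["K14"] / K["K12"])^4), 40, tolerance = 1e-12)
  expect_equal(unname(K["K16"]^6 / (K["K14"]^4 * K["K12"]^2)), 220,
               tolerance = 1e-12)
  al <- c(1, 2, 4, 6)
  Keff <- c(1, K)
  m1 <- 199
  st <- lapply(seq_along(al), function(j)
    proteinState(c("1", "2", "4", "6")[j], al[j], m1 * al[j], m1 * al[j],
                 c(9.6, 13.2, 23.3, 27.0)[j], 0))
  tr <- lapply(Keff[-1], tripletFromK)
  names(tr) <- c("2", "4", "6")
  sc <- sampleComposition(c0 = 3e-4 * 5800, M1 = 5800, T = 298.15)
  sol <- solveDistribution(st, tr, NULL, sc, noElec)
  xo <- oracleMassAction(unname(Keff), al, sol@CP)
  expect_equal(unname(stateFractions(sol)), xo, tolerance = 1e-8)
  # direct stepwise mass-action check: Cdim/Cmono^2 = Kbar12 etc.
  C <- sol@CP * stateFractions(sol) / al
  expect_equal(unname(C[2] / C[1]^2), 2.22e5, tolerance = 1e-6)
  expect_equal(unname(C[3] / C[2]^2), 40, tolerance = 1e-6)
  expect_equal(unname(C[4] / (C[2] * C[3])), 220, tolerance = 1e-6)
})

test_that("elementary constants are composition-independent, effective ones are not", {
  st <- fxStatesMD()
  tr <- list("2" = thermoTriplet(-10, 100, 0))
  ex <- list("1" = thermoTriplet(1.5), "2" = thermoTriplet(-2))
  cs <- cosolvent("G", nuGb0 = 0.2, Ne = 180)
  KW <- c(); Kex <- c(); K1 <- c()
  for (c0 in c(2, 10)) for (CG in c(0.05, 0.2)) {
    sc <- sampleComposition(c0 = c0, M1 = 17000, T = 310, CG0 = CG,
                            cosolv = cs)
    sol <- solveDistribution(st, tr, ex, sc, noElec)
    KW <- c(KW, sol@KW1[["2"]])
    Kex <- c(Kex, sol@Kex[["2"]])
    K1 <- c(K1, sol@K1[["2"]])
  }
  expect_lt(diff(range(KW)) / KW[1], 1e-12)
  expect_lt(diff(range(Kex)) / Kex[1], 1e-12)
  expect_gt(diff(range(K1)) / K1[1], 1e-4)   # composition moves K_1j
})

test_that("dilute limit decouples occupancies and state fractions respond to Kex", {
  st <- fxStatesMD()
  tr <- list("2" = thermoTriplet(-10))
  cs <- cosolvent("G", nuGb0 = 0.2, Ne = 180)
  ex <- list("1" = thermoTriplet(2), "2" = thermoTriplet(-1))
  sc <- sampleComposition(c0 = 1e-4, M1 = 17000, T = 298.15, CG0 = 0.1,
                          cosolv = cs)   # vanishing protein
  sol <- solveDistribution(st, tr, ex, sc, noElec)
  for (id in c("1", "2"))
    expect_equal(sol@phi[[id]], phiFromExchange(sol@Kex[[id]], sc@xG),
                 tolerance = 1e-6)
  # raising dGex2 lowers Kex2: the dimer shell binds more cosolvent,
  # phi2 drops and the effective K12 (prop. to phi2^(-m2/2)) grows, so
  # the dimer population rises monotonically
  xs <- vapply(c(-4, -2, 0, 2, 4), function(dgex) {
    ex2 <- list("1" = thermoTriplet(2), "2" = thermoTriplet(dgex))
    sc2 <- sampleComposition(c0 = 5, M1 = 17000, T = 298.15, CG0 = 0.2,
                             cosolv = cs)
    unname(stateFractions(solveDistribution(st, tr, ex2, sc2, noElec))[2])
  }, numeric(1))
  expect_true(all(diff(xs) > 0))
})

test_that("solver reports convergence and errors on hopeless inputs", {
  st <- fxStatesMD()
  tr <- list("2" = tripletFromK(sqrt(1e5)))
  sc <- sampleComposition(c0 = 2, M1 = 17000, T = 298.15)
  sol <- solveDistribution(st, tr, NULL, sc, noElec)
  expect_true(sol@converged)
  expect_error(
    solveDistribution(st, tr, NULL, sc, noElec, control = list(maxit = 1)),
    "did not converge")
  expect_error(solveDistribution(st, list(), NULL, sc, noElec),
               "missing transition")
})
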