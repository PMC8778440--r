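test_that("population averages weight states by number, not mass", {
  avg <- averageRadiusCharge(c(0.5, 0.5), c(1, 2), c(17, 26.7), c(5, 10),
                             n = 1e17)
  expect_equal(avg$invAlphaMean, 0.75)
  expect_equal(avg$R, (0.5 * 17 + 0.25 * 26.7) / 0.75, tolerance = 1e-12)
  expect_equal(avg$Z, (0.5 * 5 + 0.25 * 10) / 0.75, tolerance = 1e-12)
  expect_equal(avg$nPart, 7.5e16)
  single <- averageRadiusCharge(1, 1, 17, 5)
  expect_equal(single$R, 17); expect_equal(single$Z, 5)
})

test_that("HSDY potential has a hard core, DLVO tail and exact contact depth", {
  m <- interactionModel(R = 17, Z = 5, J = 2, d = 10, T = 298.15,
                        nPart = 5e16, kappaD = 0.033)
  expect_identical(hsdyPotential(30, m), Inf)
  m0 <- interactionModel(R = 17, Z = 0, J = 0, d = 10, T = 298.15,
                         nPart = 5e16, kappaD = 0.033)
  expect_identical(hsdyPotential(c(40, 60), m0), c(0, 0))
  # attraction-only at contact: u(2R) = -J
  mA <- interactionModel(R = 17, Z = 0, J = 2.5, d = 10, T = 298.15,
                         nPart = 5e16, kappaD = 0.033)
  expect_equal(hsdyPotential(34, mA), -2.5, tolerance = 1e-12)
  # repulsion decays with the Debye constant
  mR <- interactionModel(R = 17, Z = 8, J = 0, d = 10, T = 298.15,
                         nPart = 5e16, kappaD = 0.05)
  u <- hsdyPotential(c(40, 50), mR)
  expect_equal(log(u[1] * 40 / (u[2] * 50)) / 10, 0.05, tolerance = 1e-10)
})

test_that("Percus-Yevick structure factor hits the compressibility limit", {
  expect_equal(pyStructureFactor(c(0.01, 0.1, 0.3), 17, 0), rep(1, 3))
  expect_equal(pyStructureFactor(1e-9, 17, 0.1),
               (1 - 0.1)^4 / (1 + 2 * 0.1)^2, tolerance = 1e-10)
  expect_equal(pyStructureFactor(1e-9, 30, 0.25),
               (1 - 0.25)^4 / (1 + 2 * 0.25)^2, tolerance = 1e-10)
  expect_equal(pyStructureFactor(50, 17, 0.3), 1, tolerance = 1e-3)
  expect_error(pyStructureFactor(0.1, 17, 0.6), "eta")
})

test_that("closed-form Yukawa transform matches numeric Fourier integration", {
  sigma <- 34
  for (B2 in c(0.01, 0.1, 0.3, 1)) {
    q <- c(0.01, 0.05, 0.12, 0.35)
    closed <- (4 * pi / q) * (B2 * sin(sigma * q) + q * cos(sigma * q)) /
      (B2^2 + q^2)
    # composite-Simpson radial integration on a fine grid (the integrand
    # oscillates over hundreds of periods for long-ranged tails)
    numericFT <- vapply(q, function(qq) {
      up <- sigma + 45 / B2
      n <- 2L * ceiling((up - sigma) / 0.02)
      r <- seq(sigma, up, length.out = n + 1L)
      # u(r) = e^{-B2 (r - sigma)}/r: the 1/r cancels one radial factor
      f <- 4 * pi * exp(-B2 * (r - sigma)) * sin(qq * r) / qq
      w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
      sum(w * f) * (r[2] - r[1]) / 3
    }, numeric(1))
    expect_lt(max(abs(closed / numericFT - 1)), 1e-3)
  }
})

test_that("RPA reduces to hard spheres and curves the right way at low q", {
  q <- defaultQGrid(40)
  m0 <- interactionModel(R = 17, Z = 0, J = 0, d = 10, T = 298.15,
                         nPart = 5e16, kappaD = 0.03)
  S0 <- pyStructureFactor(q, 17, m0@eta)
  expect_equal(rpaStructureFactor(q, m0), S0)
  # continuity: vanishing J and Z approach the hard-sphere limit
  mEps <- interactionModel(R = 17, Z = 1e-5, J = 1e-6, d = 10, T = 298.15,
                           nPart = 5e16, kappaD = 0.03)
  expect_lt(max(abs(rpaStructureFactor(q, mEps) - S0)), 1e-6)
  # attraction raises, repulsion lowers, the forward structure factor
  mA <- interactionModel(R = 17, Z = 0, J = 2, d = 10, T = 298.15,
                         nPart = 5e16, kappaD = 0.03)
  mZ <- interactionModel(R = 17, Z = 8, J = 0, d = 10, T = 298.15,
                         nPart = 5e16, kappaD = 0.03)
  expect_gt(rpaStructureFactor(q, mA)[1], S0[1])
  expect_lt(rpaStructureFactor(q, mZ)[1], S0[1])
  # low-density expansion: 1/S - 1/S0 is linear in the density
  m1 <- interactionModel(R = 17, Z = 0, J = 1, d = 10, T = 298.15,
                         nPart = 1e15, kappaD = 0.03)
  m2 <- interactionModel(R = 17, Z = 0, J = 1, d = 10, T = 298.15,
                         nPart = 2e15, kappaD = 0.03)
  d1 <- 1 / rpaStructureFactor(q, m1) - 1 / pyStructureFactor(q, 17, m1@eta)
  d2 <- 1 / rpaStructureFactor(q, m2) - 1 / pyStructureFactor(q, 17, m2@eta)
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
  # large q: all structure factors approach 1
  expect_equal(rpaStructureFactor(30, mA,
                                  S0 = pyStructureFactor(30, 17, mA@eta)),
               1, tolerance = 1e-3)
  # overwhelming attraction is reported as an RPA instability
  mBad <- interactionModel(R = 17, Z = 0, J = 50, d = 30, T = 298.15,
                           nPart = 5e17, kappaD = 0.03)
  expect_error(rpaStructureFactor(q, mBad), "instability")
})

test_that("measured structure factor couples S and beta as stated", {
  S <- c(1.4, 1.0, 0.8)
  expect_equal(measuredStructureFactor(S, rep(1, 3)), S)
  expect_equal(measuredStructureFactor(rep(1, 3), c(0.2, 0.5, 0.9)),
               rep(1, 3))
  expect_equal(measuredStructureFactor(1.4, 0.5), 1.2)
  expect_error(measuredStructureFactor(1.4, 1.5), "beta")
})
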