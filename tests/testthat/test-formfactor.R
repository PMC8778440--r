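test_that("forward limit equals the squared total excess scattering length", {
  q <- c(1e-5, defaultQGrid(20))
  rho0 <- sldBulk(0, 0.018, 0.2, pc$b_W, 0)
  rhoLd <- 1.03 * rho0
  tb <- stateFormFactor(fxSphere20, fxShells20, rho0, rhoLd, q = q)
  # independent forward-value bookkeeping
  nAt <- nAtoms(fxSphere20)
  bAtoms <- nAt * (pc$r_e * 8 - rho0 * 9.13e-24)
  vSite <- fxShells20@siteVolume * 1e-24
  bSites <- nrow(fxShells20@sites) * (rhoLd - rho0) * vSite
  expect_equal(tb@P[1], (bAtoms + bSites)^2, tolerance = 1e-3)
  expect_true(all(tb@P > 0))
  expect_true(all(tb@P1[1]^2 <= tb@P[1] * (1 + 1e-12)))
})

test_that("uniform sphere reproduces the analytic form factor", {
  q <- c(1e-5, defaultQGrid(60))
  tb <- stateFormFactor(fxSphere20, fxShells20, rho0 = 0, rhoLd = 0, q = q)
  Pn <- tb@P[-1] / tb@P[1]
  qq <- q[-1]
  # the staircased grid body is a slightly smaller effective sphere; use
  # its own radius of gyration to set the analytic radius
  Reff <- sqrt(5 / 3 * mean(rowSums(scale(coords(fxSphere20),
                                          scale = FALSE)^2)))
  an <- sphereFF(qq, Reff)
  sel <- qq * 20 < 6
  expect_lt(max(abs(Pn[sel] - an[sel])), 0.02)
  # relative agreement away from the form-factor zero
  big <- sel & an > 0.05
  expect_lt(max(abs(Pn[big] / an[big] - 1)), 0.02)
})

test_that("two distant identical spheres show the Debye interference factor", {
  L <- 70
  db <- makeToyStructure("dumbbell", size = 10, nAtoms = 300, separation = L)
  mono <- makeToyStructure("sphere", size = 10, nAtoms = 150)
  shDb <- buildShells(db); shM <- buildShells(mono)
  q <- defaultQGrid(40)
  Pdb <- stateFormFactor(db, shDb, 0, 0, q = q, alpha = 1)@P
  Pm <- stateFormFactor(mono, shM, 0, 0, q = q, alpha = 1)@P
  A2 <- stateFormFactor(mono, shM, 0, 0, q = q, alpha = 1)@P1^2
  pred <- 2 * Pm + 2 * A2 * ifelse(q * L < 1e-8, 1, sin(q * L) / (q * L))
  expect_lt(max(abs(Pdb / pred - 1)), 0.03)
})

test_that("ensemble averaging is the arithmetic mean on a common grid", {
  q <- defaultQGrid(15)
  sh <- buildShells(makeToyStructure("sphere", size = 10, nAtoms = 150))
  t1 <- stateFormFactor(makeToyStructure("sphere", size = 10, nAtoms = 150),
                        sh, 9e10, 9.5e10, q = q)
  expect_equal(ensembleFormFactor(list(t1, t1))@P, t1@P)
  t2 <- new("FormFactorTable", q = q, P = 2 * t1@P, P1 = 2 * t1@P1,
            alpha = t1@alpha)
  em <- ensembleFormFactor(list(t1, t2))
  expect_equal(em@P, 1.5 * t1@P)
  expect_equal(em@P1, 1.5 * t1@P1)
  t3 <- new("FormFactorTable", q = q * 1.01, P = t1@P, P1 = t1@P1,
            alpha = t1@alpha)
  expect_error(ensembleFormFactor(list(t1, t3)), "q grids")
})

test_that("coil ensembles lack the compact-state Kratky peak", {
  set.seed(3)
  q <- defaultQGrid(50)
  members <- lapply(1:5, function(s) {
    coil <- makeToyStructure("coil", nAtoms = 60, seed = s)
    stateFormFactor(coil, buildShells(coil, nOffsets = 1), 0, 0, q = q)
  })
  em <- ensembleFormFactor(members)
  kratkyCoil <- q^2 * em@P / em@P[1]
  # compact sphere: clear interior maximum in the Kratky representation
  tbS <- stateFormFactor(fxSphere20, fxShells20, 0, 0, q = q)
  kratkySphere <- q^2 * tbS@P / tbS@P[1]
  iMaxS <- which.max(kratkySphere)
  expect_lt(iMaxS, length(q) - 5)          # interior peak then decay
  expect_lt(kratkySphere[length(q)], 0.5 * max(kratkySphere))
  # coil: monotone rise, no decaying peak
  iMaxC <- which.max(kratkyCoil)
  expect_gt(kratkyCoil[length(q)], 0.9 * max(kratkyCoil))
  expect_gte(iMaxC, length(q) - 6)
})

test_that("effective form factor obeys the mixture sums and beta bounds", {
  q <- defaultQGrid(30)
  rho0 <- sldBulk(0, 0.018, 0.2, pc$b_W, 0)
  mono <- makeToyStructure("sphere", size = 12, nAtoms = 200)
  dimS <- makeToyStructure("dumbbell", size = 12, nAtoms = 400,
                           separation = 26)
  tbM <- stateFormFactor(mono, buildShells(mono), rho0, 1.05 * rho0, q = q,
                         alpha = 1)
  tbD <- stateFormFactor(dimS, buildShells(dimS), rho0, 1.05 * rho0, q = q,
                         alpha = 2)
  eff <- effectiveFormFactor(list(tbM, tbD), c(0.5, 0.5))
  expect_equal(eff$P, 0.5 * tbM@P + 0.5 * 2 * tbD@P, tolerance = 1e-12)
  expect_true(all(eff$beta >= 0 & eff$beta <= 1))
  # a single monomeric near-spherical state has beta(0) = 1
  effM <- effectiveFormFactor(list(tbM), 1)
  expect_equal(effM$beta[1], 1, tolerance = 1e-3)
})

test_that("mixture intensity equals an independent Debye computation at S = 1", {
  # small structures so the naive double sum stays cheap; vacuum weights
  q <- defaultQGrid(25)
  mono <- makeToyStructure("sphere", size = 9, nAtoms = 80)
  dimS <- makeToyStructure("dumbbell", size = 9, nAtoms = 160,
                           separation = 20)
  shM <- buildShells(mono, nOffsets = 1)
  shD <- buildShells(dimS, nOffsets = 1)
  tbM <- stateFormFactor(mono, shM, 0, 0, q = q, alpha = 1)
  tbD <- stateFormFactor(dimS, shD, 0, 0, q = q, alpha = 2)
  x <- c(0.3, 0.7)
  eff <- effectiveFormFactor(list(tbM, tbD), x)
  n <- 1e16                          # monomer number density, 1/cm^3
  Ipkg <- n * eff$P                  # the package's n P(q) at S_M = 1
  b <- pc$r_e * 8                    # vacuum oxygen scattering length
  F2m <- oracleDebye(coords(mono), rep(b, nAtoms(mono)), q)
  F2d <- oracleDebye(coords(dimS), rep(b, nAtoms(dimS)), q)
  Idir <- (n * x[1] / 1) * F2m + (n * x[2] / 2) * F2d
  expect_lt(max(abs(Ipkg / Idir - 1)), 0.005)
})

test_that("Guinier analysis of a compact state recovers the contrast-weighted Rg", {
  q <- seq(0.012, 0.045, length.out = 25)    # q*Rg < 1 for Rg ~ 16 A
  rho0 <- sldBulk(0, 0.018, 0.2, pc$b_W, 0)
  tb <- stateFormFactor(fxSphere20, fxShells20, rho0, 1.06 * rho0, q = q)
  fitRg <- sqrt(-3 * coef(lm(log(tb@P) ~ I(q^2)))[[2]])
  # direct contrast-weighted radius of gyration of atoms + shell sites
  w <- c(rep(pc$r_e * 8 - rho0 * 9.13e-24, nAtoms(fxSphere20)),
         rep(0.06 * rho0 * fxShells20@siteVolume * 1e-24,
             nrow(fxShells20@sites)))
  allxyz <- rbind(coords(fxSphere20), fxShells20@sites)
  ctr <- colSums(allxyz * w) / sum(w)
  rg2 <- sum(w * rowSums(sweep(allxyz, 2, ctr)^2)) / sum(w)
  expect_lt(abs(fitRg / sqrt(rg2) - 1), 0.03)
})
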