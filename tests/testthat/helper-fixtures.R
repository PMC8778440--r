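# shared fixtures, built once per test run

pc <- physicalConstants()
RGAS <- pc$R_gas

# independent mass-action oracle: polynomial root in the monomer
# concentration, CP = sum_j alpha_j (K1j C1)^(alpha_j), via polyroot
oracleMassAction <- function(K1, alpha, CP) {
  deg <- max(alpha)
  coef <- numeric(deg + 1L)
  for (j in seq_along(alpha))
    coef[alpha[j] + 1L] <- coef[alpha[j] + 1L] + alpha[j] * K1[j]^alpha[j]
  coef[1] <- -CP
  r <- polyroot(coef)
  r <- Re(r[abs(Im(r)) < 1e-9 * (1 + abs(Re(r))) & Re(r) > 0])
  C1 <- min(r)
  x <- alpha * (K1 * C1)^alpha / CP
  x / sum(x)
}

# Monte-Carlo volume of a spherical shell band around an ideal sphere
oracleShellVolumeMC <- function(Rcore, dlo, dhi, n = 4e5, seed = 42) {
  set.seed(seed)
  Rmax <- Rcore + dhi
  pts <- matrix(runif(3 * n, -Rmax, Rmax), ncol = 3)
  r <- sqrt(rowSums(pts^2))
  frac <- mean(r > Rcore + dlo & r <= Rcore + dhi)
  frac * (2 * Rmax)^3
}

# naive independent Debye double sum (vacuum weights) for small structures
oracleDebye <- function(xyz, b, q) {
  d <- as.matrix(dist(xyz))
  vapply(q, function(qq) {
    s <- qq * d
    j0 <- ifelse(s < 1e-10, 1, sin(s) / s)
    as.numeric(t(b) %*% j0 %*% b)
  }, numeric(1))
}

# analytic homogeneous-sphere form factor (normalised to 1 at q = 0)
sphereFF <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# small toy structures reused across files
fxSphere20 <- makeToyStructure("sphere", size = 20, nAtoms = 500)
fxShells20 <- buildShells(fxSphere20)

# balanced-hydration monomer/dimer states: m2 = 2 m1 and phi = 1 make the
# effective constants equal the elementary ones, isolating mass action
fxStatesMD <- function(m1 = 400) list(
  proteinState("1", alpha = 1, m = m1, m2 = m1, R = 17.0, Z = 0, d = 1.07),
  proteinState("2", alpha = 2, m = 2 * m1, m2 = 2 * m1, R = 26.7, Z = 0,
               d = 1.07))

# transitions from target effective constants (at 298.15 K)
tripletFromK <- function(K, T = 298.15) thermoTriplet(-RGAS * T * log(K) / 1000)

noElec <- ionicEnvironment(electrostatics = FALSE)

# the default recovery scenario is expensive to build; share one instance
scenarioCache <- new.env()
getScenario <- function() {
  if (is.null(scenarioCache$scen))
    scenarioCache$scen <- defaultRecoveryScenario(seed = 1)
  scenarioCache$scen
}

# minimal fixed-width PDB writer for io fixtures
writeMiniPDB <- function(path, atoms) {
  # atoms: data.frame with name, resid, chain, x, y, z, occ, elem, alt
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, a$name, a$alt, a$resid, a$chain, i, a$x, a$y, a$z, a$occ,
            20.0, a$elem)
  }, character(1))
  writeLines(c(lines, "END"), path)
}
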