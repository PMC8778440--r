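#' @import methods
NULL

#' ThermoTriplet: reference thermodynamics of an elementary process
#'
#' Holds the three parameters that define the temperature dependence of a
#' Gibbs free energy change under classical thermodynamics with a
#' temperature-independent heat capacity change:
#' \deqn{\Delta G(T) = \Delta G^\circ + (\Delta C_p - \Delta S^\circ)(T - T^\circ)
#'       - \Delta C_p\, T \ln(T/T^\circ)}
#' with reference temperature \eqn{T^\circ = 298.15} K. Used both for the
#' non-electrostatic part of state transitions (monomer to oligomer or
#' unfolded) and for the water-cosolvent surface exchange processes.
#'
#' @slot dG0 reference Gibbs free energy change at T_ref [J/mol]
#' @slot dS0 reference entropy change at T_ref [J/mol/K]
#' @slot dCp heat capacity change, temperature independent [J/mol/K]
#' @export
setClass("ThermoTriplet",
         representation(dG0 = "numeric", dS0 = "numeric", dCp = "numeric"),
         prototype(dG0 = 0, dS0 = 0, dCp = 0),
         validity = function(object) {
           if (length(object@dG0) != 1L || length(object@dS0) != 1L ||
               length(object@dCp) != 1L)
             return("dG0, dS0, dCp must be scalars")
           if (!all(is.finite(c(object@dG0, object@dS0, object@dCp))))
             return("thermodynamic parameters must be finite")
           TRUE
         })

#' Construct a ThermoTriplet
#'
#' @param dG0 reference Gibbs free energy change [kJ/mol] (interface unit;
#'   stored internally in J/mol)
#' @param dS0 reference entropy change [J/mol/K]
#' @param dCp heat capacity change [J/mol/K]
#' @return a [ThermoTriplet-class] object
#' @examples
#' tt <- thermoTriplet(dG0 = 2.95, dS0 = 564, dCp = 0)
#' gibbsAtTemperature(tt, 333.15) / 1000  # kJ/mol
#' @export
thermoTriplet <- function(dG0 = 0, dS0 = 0, dCp = 0) {
  new("ThermoTriplet", dG0 = dG0 * 1000, dS0 = dS0, dCp = dCp)
}

setMethod("show", "ThermoTriplet", function(object) {
  cat(sprintf("ThermoTriplet: dG0 = %.3f kJ/mol, dS0 = %.1f J/mol/K, dCp = %.1f J/mol/K\n",
              object@dG0 / 1000, object@dS0, object@dCp))
})

#' @describeIn thermoTriplet accessor, reference Gibbs energy [J/mol]
#' @param x a ThermoTriplet
#' @export
refGibbs <- function(x) x@dG0
#' @describeIn thermoTriplet accessor, reference entropy [J/mol/K]
#' @export
refEntropy <- function(x) x@dS0
#' @describeIn thermoTriplet accessor, heat capacity change [J/mol/K]
#' @export
heatCapacityChange <- function(x) x@dCp

#' Gibbs free energy change at temperature
#'
#' Evaluates the closed-form temperature law (natural logarithm) for the
#' Gibbs free energy change of an elementary process parameterised by a
#' [ThermoTriplet-class].
#'
#' @param triplet a [ThermoTriplet-class]
#' @param T temperature [K], may be vectorised
#' @return Gibbs free energy change [J/mol]
#' @examples
#' tt <- thermoTriplet(2.95, 564, 0)
#' gibbsAtTemperature(tt, 298.15)  # returns the reference value, 2950 J/mol
#' @export
gibbsAtTemperature <- function(triplet, T) {
  stopifnot(is(triplet, "ThermoTriplet"))
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperature must be positive and finite")
  T0 <- .pc$T_ref
  triplet@dG0 + (triplet@dCp - triplet@dS0) * (T - T0) -
    triplet@dCp * T * log(T / T0)
}

#' Molar volume of bulk water at temperature
#'
#' Thermal-expansion law for water,
#' \eqn{\nu_W(T) = \nu_W^\circ \exp(\alpha_W (T-T^\circ) + \tfrac12 \beta_W (T-T^\circ)^2)},
#' with the reference value 0.018 L/mol at 298.15 K. Outside the fitted
#' validity window (240-380 K) the value is still returned, with a warning.
#'
#' @param T temperature [K]
#' @return molar volume [L/mol]
#' @export
waterMolarVolume <- function(T) {
  stopifnot(is.numeric(T), all(T > 0))
  if (any(T < 240 | T > 380))
    warning("temperature outside the 240-380 K validity window of the expansion")
  dT <- T - .pc$T_ref
  .pc$nu_Wb0 * exp(.pc$alpha_W * dT + 0.5 * .pc$beta_W * dT^2)
}

#' Molar volume under simple exponential thermal expansion
#'
#' Used for cosolvent and protein molar volumes:
#' \eqn{\nu(T) = \nu^\circ e^{\alpha (T - T^\circ)}}.
#'
#' @param nu0 molar volume at 298.15 K [L/mol]
#' @param alpha thermal expansivity [1/K]
#' @param T temperature [K]
#' @return molar volume [L/mol]
#' @export
expandedMolarVolume <- function(nu0, alpha, T) {
  stopifnot(is.numeric(nu0), all(nu0 > 0), is.numeric(T), all(T > 0))
  nu0 * exp(alpha * (T - .pc$T_ref))
}

#' Protein net charge from sequence and pH
#'
#' Henderson-Hasselbalch sum of fractional charges over the titratable
#' side chains (D, E, H, K, R, C, Y) and the two termini. Basic groups
#' contribute \eqn{+1/(1+10^{pH-pKa})}, acidic groups
#' \eqn{-1/(1+10^{pKa-pH})}; the result is continuous and monotonically
#' non-increasing in pH.
#'
#' @param sequence one-letter amino-acid string (or character vector of
#'   residues)
#' @param pH solution pH
#' @param pKa named numeric vector of pKa values; see [defaultPKaTable()]
#' @return net charge in elementary charge units
#' @examples
#' proteinCharge("ACDEFGHIKLMNPQRSTVWY", pH = 7)
#' @export
proteinCharge <- function(sequence, pH, pKa = defaultPKaTable()) {
  if (length(sequence) == 1L) sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  if (length(sequence) == 0L) stop("empty sequence")
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(unique(sequence), valid)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  need <- c("NTERM", "CTERM", "D", "E", "H", "K", "R", "C", "Y")
  if (!all(need %in% names(pKa)))
    stop("pKa table must name: ", paste(need, collapse = ", "))
  basic  <- c("K", "R", "H")
  acidic <- c("D", "E", "C", "Y")
  fPos <- function(pk)  1 / (1 + 10^(pH - pk))
  fNeg <- function(pk) -1 / (1 + 10^(pk - pH))
  z <- fPos(pKa[["NTERM"]]) + fNeg(pKa[["CTERM"]])
  for (res in basic)  z <- z + sum(sequence == res) * fPos(pKa[[res]])
  for (res in acidic) z <- z + sum(sequence == res) * fNeg(pKa[[res]])
  z
}

#' Ionic strength of a set of microion species
#'
#' \eqn{I = \tfrac12 \sum_i z_i^2 C_i} over the listed microions.
#' The protein macroion itself never enters this sum; its charge is
#' accounted for through [counterionIonicStrength()].
#'
#' @param C molar concentrations [mol/L]
#' @param z charge numbers
#' @return ionic strength [mol/L]
#' @examples
#' ionicStrength(c(0.01, 0.01), c(1, -1))  # a 1:1 salt at 10 mM
#' @export
ionicStrength <- function(C, z) {
  stopifnot(length(C) == length(z))
  if (any(C < 0)) stop("negative concentration")
  0.5 * sum(z^2 * C)
}

#' Counterion ionic strength of a macroion solution
#'
#' From the electroneutrality condition the molar concentration of
#' (monovalent) protein counterions is
#' \eqn{C_{ci} = C_P \sum_j x_j \alpha_j^{-1} |Z_j|}. The macroion charge is
#' counted as monovalent-equivalent ions for the electroneutral pair
#' bookkeeping (the macroion's own z^2 self-term is excluded: screening is
#' by small ions), giving \eqn{I_{ci} = C_{ci}}.
#'
#' @param CP nominal monomer molar concentration [mol/L]
#' @param x state molar fractions (sum to 1)
#' @param alpha aggregation numbers
#' @param Z state net charges
#' @return counterion ionic strength [mol/L]
#' @export
counterionIonicStrength <- function(CP, x, alpha, Z) {
  stopifnot(CP >= 0, length(x) == length(alpha), length(x) == length(Z))
  Cci <- CP * sum(x / alpha * abs(Z))
  0.5 * (Cci + Cci)
}

#' Reciprocal Debye screening length
#'
#' \eqn{\kappa_D = (2 N_A q_e^2 I / (\epsilon_0 \epsilon k_B T))^{1/2}},
#' with the ionic strength converted from mol/L to number per cubic metre,
#' returned in 1/Angstrom.
#'
#' @param I ionic strength [mol/L]
#' @param eps relative dielectric constant of the solvent
#' @param T temperature [K]
#' @return \eqn{\kappa_D} [1/Angstrom]
#' @examples
#' 1 / debyeKappa(0.01, 78.4, 298.15)  # about 30.4 Angstrom
#' @export
debyeKappa <- function(I, eps, T) {
  stopifnot(I >= 0, eps > 1, T > 0)
  I_m3 <- I * 1000 * .pc$N_A              # ions per m^3 (per unit z^2)
  kap_m <- sqrt(2 * I_m3 * .pc$q_e^2 / (.pc$eps0 * eps * .pc$k_B * T))
  kap_m * 1e-10
}

#' Debye-Hueckel electrostatic self energy of a charged protein state
#'
#' Electrostatic contribution to the stability of a spherical macroion of
#' radius R carrying Z elementary charges in a screening electrolyte:
#' \deqn{G_{el} = \frac{q_e^2 Z^2}{8\pi\epsilon_0\epsilon R}
#'   \left[1 - \frac{\kappa_D R}{1 + \kappa_D (R + a)}\right]}
#' converted to molar units [J/mol]. The difference
#' \eqn{\Delta G_{el,1j} = \alpha_j^{-1} G_{el,j} - G_{el,1}} is assembled
#' by the equilibrium solver.
#'
#' @param Z net charge [elementary charges]
#' @param R macroion radius [Angstrom]
#' @param kappaD reciprocal Debye length [1/Angstrom]
#' @param a mean microion radius [Angstrom], default 2
#' @param eps relative dielectric constant
#' @return electrostatic free energy [J/mol]
#' @export
electrostaticStateEnergy <- function(Z, R, kappaD, a = 2, eps) {
  if (any(R <= 0)) stop("radius must be positive")
  stopifnot(kappaD >= 0, eps > 1)
  R_m <- R * 1e-10
  a_m <- a * 1e-10
  kap_m <- kappaD * 1e10
  bracket <- 1 - kap_m * R_m / (1 + kap_m * (R_m + a_m))
  g <- .pc$q_e^2 * Z^2 / (8 * pi * .pc$eps0 * eps * R_m) * bracket
  g * .pc$N_A
}
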