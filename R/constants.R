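#' Physical constants used throughout the package
#'
#' Returns the fixed set of physical constants the scattering and
#' thermodynamic models rely on. The list is locked: values cannot be
#' modified after construction, which keeps every downstream computation
#' on a single consistent unit system (energies J/mol internally, lengths
#' in Angstrom, concentrations mol/L, scattering length densities cm^-2).
#'
#' @return A locked environment with elements:
#' \describe{
#'   \item{N_A}{Avogadro number [1/mol]}
#'   \item{k_B}{Boltzmann constant [J/K]}
#'   \item{R_gas}{molar gas constant [J/mol/K]}
#'   \item{q_e}{proton charge [C]}
#'   \item{eps0}{vacuum permittivity [C^2/J/m]}
#'   \item{r_e}{classical electron radius [cm]}
#'   \item{T_ref}{reference temperature 298.15 [K]}
#'   \item{nu_Wb0}{molar volume of bulk water at T_ref [L/mol]}
#'   \item{alpha_W}{water thermal expansivity at T_ref [1/K]}
#'   \item{beta_W}{first derivative of the water expansivity [1/K^2]}
#'   \item{N_We}{electrons per water molecule}
#'   \item{b_W}{X-ray scattering length of one water molecule, r_e * N_We [cm]}
#' }
#' @examples
#' pc <- physicalConstants()
#' pc$r_e * pc$N_We  # scattering length of water, cm
#' @export
physicalConstants <- function() {
  e <- new.env(parent = emptyenv())
  e$N_A    <- 6.02214076e23
  e$k_B    <- 1.380649e-23
  e$R_gas  <- 8.31446261815324
  e$q_e    <- 1.6e-19
  e$eps0   <- 8.8541878128e-12
  e$r_e    <- 0.28e-12
  e$T_ref  <- 298.15
  e$nu_Wb0 <- 0.018
  e$alpha_W <- 2.5e-4
  e$beta_W  <- 9.8e-6
  e$N_We   <- 10
  e$b_W    <- e$r_e * e$N_We
  for (nm in ls(e)) lockBinding(nm, e)
  lockEnvironment(e)
  e
}

# single shared instance; read-only by construction
.pc <- physicalConstants()

#' Relative dielectric constant of water
#'
#' Empirical polynomial for the static relative permittivity of pure
#' water as a function of temperature (Malmberg & Maryott form, Celsius
#' polynomial). The cosolvent effect on the dielectric constant is
#' neglected: at the cosolvent concentrations the model targets
#' (<= 0.25 M) the correction is second order.
#'
#' @param T temperature [K]
#' @return dimensionless relative dielectric constant (about 78.3 at 25 C)
#' @examples
#' waterDielectric(298.15)
#' @export
waterDielectric <- function(T) {
  stopifnot(is.numeric(T), all(T > 0))
  t <- T - 273.15
  87.740 - 0.40008 * t + 9.398e-4 * t^2 - 1.410e-6 * t^3
}

#' Side-chain and terminal pKa table
#'
#' Reads the packaged canonical pKa set (EMBOSS-style values) used by
#' [proteinCharge()]. Users can supply their own named vector instead;
#' required names are the titratable residues C, D, E, H, K, R, Y plus
#' "NTERM" and "CTERM".
#'
#' @return named numeric vector of pKa values
#' @export
defaultPKaTable <- function() {
  path <- system.file("extdata", "pka_sidechains.txt", package = "saxsolv",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  stats::setNames(tab$pKa, tab$group)
}

# van der Waals radii [Angstrom] for the protein surface definition
.vdwRadii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31,
               X = 1.70)

#' Van der Waals radius lookup
#'
#' @param element character vector of element symbols (case-insensitive);
#'   unknown elements fall back to the carbon radius with a warning.
#' @return numeric vector of radii [Angstrom]
#' @export
vdwRadius <- function(element) {
  key <- toupper(element)
  r <- .vdwRadii[key]
  bad <- is.na(r)
  if (any(bad)) {
    warning("unknown element(s) ", paste(unique(key[bad]), collapse = ", "),
            "; using carbon radius")
    r[bad] <- .vdwRadii[["C"]]
  }
  unname(r)
}

# electrons per neutral atom, for X-ray scattering lengths
.electronCount <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15,
                    FE = 26, ZN = 30, MG = 12, CA = 20)

#' Electron count lookup for elements
#' @param element character vector of element symbols
#' @return integer vector of electron numbers
#' @export
electronCount <- function(element) {
  key <- toupper(element)
  n <- .electronCount[key]
  if (anyNA(n)) stop("unknown element(s): ",
                     paste(unique(key[is.na(n)]), collapse = ", "))
  unname(n)
}
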