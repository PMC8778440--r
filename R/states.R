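#' AtomicStructure: minimal atomic coordinate container
#'
#' Coordinates in Angstrom plus element symbols, the only structural
#' information the scattering model needs. Built by [readPDB()] or by the
#' synthetic generators ([makeToyStructure()]).
#'
#' @slot xyz numeric matrix, n x 3 [Angstrom]
#' @slot element character vector, length n
#' @slot occupancy numeric vector, length n (weights scattering lengths)
#' @export
setClass("AtomicStructure",
         representation(xyz = "matrix", element = "character",
                        occupancy = "numeric"),
         validity = function(object) {
           n <- nrow(object@xyz)
           if (n < 1L) return("structure must contain at least one atom")
           if (ncol(object@xyz) != 3L) return("xyz must have 3 columns")
           if (length(object@element) != n) return("element length mismatch")
           if (length(object@occupancy) != n) return("occupancy length mismatch")
           if (!all(is.finite(object@xyz))) return("non-finite coordinates")
           TRUE
         })

#' Construct an AtomicStructure
#' @param xyz n x 3 coordinate matrix [Angstrom]
#' @param element element symbols, length n
#' @param occupancy per-atom occupancies, default 1
#' @return an [AtomicStructure-class]
#' @export
atomicStructure <- function(xyz, element, occupancy = rep(1, nrow(xyz))) {
  new("AtomicStructure", xyz = as.matrix(xyz), element = as.character(element),
      occupancy = as.numeric(occupancy))
}

setMethod("show", "AtomicStructure", function(object) {
  cat(sprintf("AtomicStructure: %d atoms (%s)\n", nrow(object@xyz),
              paste(names(sort(table(object@element), decreasing = TRUE)),
                    collapse = ",")))
})

#' @describeIn atomicStructure number of atoms
#' @param x an AtomicStructure
#' @export
nAtoms <- function(x) nrow(x@xyz)
#' @describeIn atomicStructure coordinate matrix [Angstrom]
#' @export
coords <- function(x) x@xyz
#' @describeIn atomicStructure element symbols
#' @export
elements <- function(x) x@element

#' ProteinState: one protein state in the multimeric equilibrium
#'
#' Describes state j of the protein: its aggregation number, hydration
#' site counts in the first and second shell, effective radius, net
#' charge, relative hydration-water density and (optionally) the atomic
#' structure or conformational ensemble used for the form factor.
#'
#' @slot id state label, e.g. "N", "I", "U" or "1", "2", "4", "6"
#' @slot alpha aggregation number (>= 1)
#' @slot m first-shell hydration site count
#' @slot m2 second-shell hydration site count
#' @slot R state radius [Angstrom]
#' @slot Z net charge at the working pH [elementary charges]
#' @slot d relative density of first-shell hydration water, in [1, 1.15]
#' @slot structure an [AtomicStructure-class], a list of them (ensemble),
#'   or NULL
#' @export
setClass("ProteinState",
         representation(id = "character", alpha = "numeric", m = "numeric",
                        m2 = "numeric", R = "numeric", Z = "numeric",
                        d = "numeric", structure = "ANY"),
         prototype(d = 1.07, structure = NULL),
         validity = function(object) {
           if (object@alpha < 1 || object@alpha != round(object@alpha))
             return("alpha must be an integer >= 1")
           if (object@m <= 0 || object@m2 <= 0)
             return("hydration site counts must be positive")
           if (object@R <= 0) return("radius must be positive")
           if (object@d < 1 || object@d > 1.15)
             return("hydration-water relative density d must lie in [1, 1.15]")
           TRUE
         })

#' Construct a ProteinState
#'
#' @param id state label
#' @param alpha aggregation number
#' @param m,m2 first/second shell hydration site counts
#' @param R state radius [Angstrom]
#' @param Z net charge
#' @param d relative hydration-water density (default 1.07)
#' @param structure optional [AtomicStructure-class] or list thereof
#' @return a [ProteinState-class]
#' @examples
#' proteinState("N", alpha = 1, m = 404, m2 = 465, R = 17, Z = 5)
#' @export
proteinState <- function(id, alpha, m, m2, R, Z, d = 1.07, structure = NULL) {
  new("ProteinState", id = as.character(id), alpha = alpha, m = m, m2 = m2,
      R = R, Z = Z, d = d, structure = structure)
}

setMethod("show", "ProteinState", function(object) {
  cat(sprintf("ProteinState '%s': alpha=%d, m=%g/%g, R=%.1f A, Z=%.2f, d=%.2f\n",
              object@id, as.integer(object@alpha), object@m, object@m2,
              object@R, object@Z, object@d))
})

#' Cosolvent: a small-molecule cosolvent in the binary solvent
#'
#' @slot id label (e.g. a modified-sugar code)
#' @slot nuGb0 bulk molar volume at 298.15 K [L/mol]
#' @slot alphaG thermal expansivity [1/K]
#' @slot Ne electrons per molecule
#' @slot ionic whether the compound dissociates into 1:1 microions
#' @export
setClass("Cosolvent",
         representation(id = "character", nuGb0 = "numeric",
                        alphaG = "numeric", Ne = "numeric", ionic = "logical"),
         prototype(alphaG = 5e-4, ionic = FALSE),
         validity = function(object) {
           if (object@nuGb0 <= .pc$nu_Wb0)
             return("cosolvent molar volume must exceed that of water")
           if (object@Ne <= 0) return("electron count must be positive")
           TRUE
         })

#' Construct a Cosolvent
#' @param id label
#' @param nuGb0 molar volume at 298.15 K [L/mol]
#' @param Ne electrons per molecule
#' @param alphaG thermal expansivity [1/K], default 5e-4
#' @param ionic logical, 1:1 electrolyte behaviour (adds 2*C_G to the
#'   added ionic strength)
#' @return a [Cosolvent-class]
#' @examples
#' cosolvent("EC3xx", nuGb0 = 0.2, Ne = 180)
#' @export
cosolvent <- function(id, nuGb0, Ne, alphaG = 5e-4, ionic = FALSE) {
  new("Cosolvent", id = as.character(id), nuGb0 = nuGb0, alphaG = alphaG,
      Ne = Ne, ionic = ionic)
}

setMethod("show", "Cosolvent", function(object) {
  cat(sprintf("Cosolvent '%s': nu0=%.3f L/mol, Ne=%g, alphaG=%.1e/K%s\n",
              object@id, object@nuGb0, object@Ne, object@alphaG,
              if (object@ionic) ", ionic (1:1)" else ""))
})

#' @describeIn cosolvent X-ray scattering length of one cosolvent
#'   molecule [cm]
#' @param x a Cosolvent
#' @export
scatteringLength <- function(x) .pc$r_e * x@Ne

#' SampleComposition: nominal composition of one SAXS sample
#'
#' Converts the experimentally controlled quantities (protein w/v
#' concentration and cosolvent molarity, both defined at the reference
#' temperature) into the temperature-invariant nominal molar fractions
#' X_P (protein monomers) and x_G (cosolvent fraction of the solvent)
#' through an ideal-volume mole balance on one litre at 298.15 K.
#'
#' @slot c0 protein w/v concentration at T_ref [g/L]
#' @slot M1 monomer molecular weight [g/mol]
#' @slot CG0 cosolvent molarity at T_ref [mol/L]
#' @slot pH solution pH
#' @slot T temperature [K]
#' @slot XP nominal protein monomer molar fraction
#' @slot xG nominal cosolvent molar fraction of the solvent
#' @slot nuP0 protein molar volume at T_ref [L/mol]
#' @slot alphaP protein thermal expansivity [1/K]
#' @slot cosolvent a [Cosolvent-class] or NULL
#' @export
setClass("SampleComposition",
         representation(c0 = "numeric", M1 = "numeric", CG0 = "numeric",
                        pH = "numeric", T = "numeric", XP = "numeric",
                        xG = "numeric", nuP0 = "numeric", alphaP = "numeric",
                        cosolvent = "ANY"),
         validity = function(object) {
           if (object@XP < 0 || object@XP >= 1) return("XP out of [0,1)")
           if (object@xG < 0 || object@xG >= 1) return("xG out of [0,1)")
           if (object@T <= 0) return("temperature must be positive")
           TRUE
         })

#' Construct a SampleComposition
#'
#' @param c0 protein concentration at 298.15 K [g/L]
#' @param M1 monomer molecular weight [g/mol]
#' @param T temperature [K]
#' @param CG0 cosolvent molarity at 298.15 K [mol/L], default 0
#' @param pH solution pH, default 7
#' @param cosolv a [Cosolvent-class] (required when CG0 > 0)
#' @param nuP0 protein molar volume at 298.15 K [L/mol]; default from a
#'   partial specific volume of 0.73 cm^3/g
#' @param alphaP protein thermal expansivity [1/K], default 0
#' @return a [SampleComposition-class]
#' @examples
#' sampleComposition(c0 = 2, M1 = 17000, T = 298.15)
#' @export
sampleComposition <- function(c0, M1, T, CG0 = 0, pH = 7, cosolv = NULL,
                              nuP0 = 0.73 * M1 / 1000, alphaP = 0) {
  stopifnot(c0 >= 0, M1 > 0, CG0 >= 0)
  if (CG0 > 0 && is.null(cosolv))
    stop("a Cosolvent must be supplied when CG0 > 0")
  nP <- c0 / M1
  nG <- CG0
  nuG <- if (is.null(cosolv)) 0 else cosolv@nuGb0
  volW <- 1 - nP * nuP0 - nG * nuG
  if (volW <= 0) stop("infeasible composition: solutes exceed one litre")
  nW <- volW / .pc$nu_Wb0
  XP <- nP / (nP + nG + nW)
  xG <- if (nG > 0) nG / (nG + nW) else 0
  new("SampleComposition", c0 = c0, M1 = M1, CG0 = CG0, pH = pH, T = T,
      XP = XP, xG = xG, nuP0 = nuP0, alphaP = alphaP, cosolvent = cosolv)
}

setMethod("show", "SampleComposition", function(object) {
  cat(sprintf(
    "SampleComposition: c0=%.2f g/L (M1=%g), CG0=%.3f M, pH=%.1f, T=%.2f K\n",
    object@c0, object@M1, object@CG0, object@pH, object@T))
  cat(sprintf("  XP=%.3e, xG=%.4e\n", object@XP, object@xG))
})

#' IonicEnvironment: electrostatic screening description
#'
#' Bundles the quantities the Debye-Hueckel terms need. The total ionic
#' strength is the added (buffer plus ionic cosolvent) part I_S plus the
#' counterion part I_ci computed self-consistently by the equilibrium
#' solver.
#'
#' @slot IS added ionic strength [mol/L]
#' @slot a mean microion radius [Angstrom]
#' @slot electrostatics logical, include the Debye-Hueckel term
#' @export
setClass("IonicEnvironment",
         representation(IS = "numeric", a = "numeric",
                        electrostatics = "logical"),
         prototype(IS = 0, a = 2, electrostatics = TRUE),
         validity = function(object) {
           if (object@IS < 0) return("added ionic strength must be >= 0")
           if (object@a <= 0) return("microion radius must be positive")
           TRUE
         })

#' Construct an IonicEnvironment
#' @param IS added ionic strength from buffer microions [mol/L]
#' @param a mean microion radius [Angstrom], default 2
#' @param electrostatics include the Debye-Hueckel stability term
#' @return an [IonicEnvironment-class]
#' @export
ionicEnvironment <- function(IS = 0, a = 2, electrostatics = TRUE) {
  new("IonicEnvironment", IS = IS, a = a, electrostatics = electrostatics)
}

setMethod("show", "IonicEnvironment", function(object) {
  cat(sprintf("IonicEnvironment: IS=%.4f M, a=%.1f A, electrostatics=%s\n",
              object@IS, object@a, object@electrostatics))
})
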