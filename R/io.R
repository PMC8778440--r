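#' Read an atomic structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), keeps altLoc blank or "A",
#' strips waters and - by default - all hetero atoms, and supports chain
#' selection (e.g. only chains A and B for an oligomer subset). Atoms
#' with occupancy below 1 are kept and their scattering lengths weighted
#' by occupancy.
#'
#' @param path PDB file path
#' @param chains character vector of chain ids to keep (NULL: all)
#' @param keepHetero keep non-water HETATM records (default FALSE)
#' @return an [AtomicStructure-class]
#' @export
readPDB <- function(path, chains = NULL, keepHetero = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$alt %in% c("", "A", NA), ]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), ]
  if (!keepHetero) at <- at[at$type == "ATOM", ]
  if (!is.null(chains)) at <- at[at$chain %in% chains, ]
  if (nrow(at) == 0L) stop("no atoms left after filtering")
  el <- at$elesy
  if (is.null(el) || all(is.na(el) | el == "")) {
    # fall back on the first letter of the atom name
    el <- sub("^[0-9]*", "", at$elety)
    el <- substr(el, 1, 1)
  }
  el <- trimws(el)
  occ <- at$o
  occ[is.na(occ)] <- 1
  atomicStructure(cbind(at$x, at$y, at$z), el, occ)
}

#' Amino-acid sequence from a PDB file
#'
#' One-letter sequence of the (filtered) polymer chains, for use with
#' [proteinCharge()].
#'
#' @inheritParams readPDB
#' @return character scalar, one-letter codes
#' @export
pdbSequence <- function(path, chains = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (!is.null(chains)) at <- at[at$chain %in% chains, ]
  ca <- at[at$elety == "CA", ]
  paste(bio3d::aa321(ca$resid), collapse = "")
}

#' Read a 3-column ASCII SAXS curve
#'
#' Columns: q [1/Angstrom], dSigma/dOmega [1/cm], sigma [1/cm]. Lines
#' starting with '#' are comments. q is sorted ascending if needed (with
#' a warning); non-positive sigmas and files with fewer than 20 points
#' are errors.
#'
#' @param path file path
#' @param c0,T,G,CG0 curve labels attached to the result
#' @param qUnit "A" (1/Angstrom, default) or "nm" (1/nm, converted)
#' @return a [ScatteringCurve-class]
#' @export
readCurve <- function(path, c0 = NA_real_, T = NA_real_, G = "", CG0 = 0,
                      qUnit = c("A", "nm")) {
  qUnit <- match.arg(qUnit)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(
    utils::read.table(path, comment.char = "#", colClasses = "numeric"),
    error = function(e) stop("non-numeric rows in ", path, ": ",
                             conditionMessage(e)))
  if (ncol(tab) < 3)
    stop("curve file must have 3 columns (q, I, sigma); the sigma column is missing in ", path)
  if (nrow(tab) < 20) stop("curve has fewer than 20 points: ", path)
  q <- tab[[1]]; I <- tab[[2]]; s <- tab[[3]]
  if (qUnit == "nm") q <- q / 10
  if (is.unsorted(q, strictly = TRUE)) {
    warning("q not strictly increasing; sorting")
    o <- order(q)
    q <- q[o]; I <- I[o]; s <- s[o]
  }
  if (any(s <= 0)) stop("non-positive sigma in ", path)
  scatteringCurve(q, I, s, c0 = c0, T = T, G = G, CG0 = CG0)
}

#' Write a SAXS curve as 3-column ASCII
#'
#' Values round-trip exactly through [readCurve()] (full double
#' precision). A header comment records the curve labels.
#'
#' @param curve a [ScatteringCurve-class]
#' @param path output file path
#' @return invisibly, the path
#' @export
writeCurve <- function(curve, path) {
  stopifnot(is(curve, "ScatteringCurve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# q[1/A] I[1/cm] sigma[1/cm] | c0=%g T=%g G=%s CG0=%g",
                     curve@c0, curve@T,
                     if (nzchar(curve@G)) curve@G else "-", curve@CG0), con)
  writeLines(sprintf("%.17g %.17g %.17g", curve@q, curve@I, curve@sigma),
             con)
  invisible(path)
}

#' Read / write a batch manifest
#'
#' Tab-separated table mapping curve files to the four curve labels:
#' columns file, c0, T, G, CG0.
#'
#' @param path manifest file path
#' @return data.frame with the five columns
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("file", "c0", "T", "G", "CG0")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$file)) stop("duplicate file entries in manifest")
  tab$G[is.na(tab$G)] <- ""
  tab
}

#' @rdname readManifest
#' @param manifest data.frame with columns file, c0, T, G, CG0
#' @export
writeManifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load the curves referenced by a manifest
#'
#' @param path manifest path; curve paths are resolved relative to the
#'   manifest's directory
#' @return list of [ScatteringCurve-class]
#' @export
readBatch <- function(path) {
  man <- readManifest(path)
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(k) {
    f <- man$file[k]
    if (!file.exists(f)) f <- file.path(base, man$file[k])
    readCurve(f, c0 = man$c0[k], T = man$T[k], G = man$G[k], CG0 = man$CG0[k])
  })
}

#' Build a SAXSSystem from a structured config
#'
#' YAML schema: top-level keys `sample` (M1, pH, IS), `qgrid` (n, qmin,
#' qmax, optional), `cosolvent` (id, molar_volume, electrons,
#' expansivity, ionic; optional), `states` (list: id, alpha, m, m2, R,
#' Z, d, structure: either `pdb: path` with optional `chains`, or `toy:
#' {kind, size, natoms, seed}`), `transitions` and `exchanges` (maps id
#' -> {dG0 [kJ/mol], dS0, dCp [J/mol/K]}).
#'
#' @param config path to a YAML file, or an equivalent nested list
#' @param baseDir directory against which relative PDB paths resolve
#' @return a [SAXSSystem-class]
#' @export
systemFromConfig <- function(config, baseDir = ".") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.character(config)) baseDir <- dirname(config)
  triplets <- function(block) {
    out <- list()
    for (id in names(block)) {
      b <- block[[id]]
      out[[id]] <- thermoTriplet(dG0 = b$dG0 %||% 0, dS0 = b$dS0 %||% 0,
                                 dCp = b$dCp %||% 0)
    }
    out
  }
  cs <- NULL
  if (!is.null(cfg$cosolvent))
    cs <- cosolvent(cfg$cosolvent$id, nuGb0 = cfg$cosolvent$molar_volume,
                    Ne = cfg$cosolvent$electrons,
                    alphaG = cfg$cosolvent$expansivity %||% 5e-4,
                    ionic = isTRUE(cfg$cosolvent$ionic))
  states <- lapply(cfg$states, function(st) {
    str <- if (!is.null(st$structure$pdb)) {
      p <- st$structure$pdb
      if (!file.exists(p)) p <- file.path(baseDir, st$structure$pdb)
      readPDB(p, chains = st$structure$chains)
    } else if (!is.null(st$structure$toy)) {
      ty <- st$structure$toy
      makeToyStructure(ty$kind, size = ty$size %||% 15,
                       nAtoms = ty$natoms %||% 300, seed = ty$seed %||% 1)
    } else stop("state ", st$id, ": structure needs a 'pdb' or 'toy' entry")
    proteinState(st$id, alpha = st$alpha, m = st$m, m2 = st$m2, R = st$R,
                 Z = st$Z, d = st$d %||% 1.07, structure = str)
  })
  qg <- cfg$qgrid
  q <- defaultQGrid(n = qg$n %||% 120, qmin = qg$qmin %||% 0.01,
                    qmax = qg$qmax %||% 0.35)
  saxsSystem(states, triplets(cfg$transitions), triplets(cfg$exchanges),
             M1 = cfg$sample$M1, pH = cfg$sample$pH %||% 7, cosolv = cs,
             env = ionicEnvironment(IS = cfg$sample$IS %||% 0), q = q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
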