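#' HydrationShellModel: dummy-sphere hydration sites around a structure
#'
#' Positions and shell assignment of solvent dummy spheres generated by
#' burying the protein in a close-packed lattice whose per-site volume
#' equals one water molecule. Shell s collects sites whose distance to
#' the nearest atom van der Waals surface lies in ((s-1)*thickness,
#' s*thickness].
#'
#' @slot sites numeric matrix, n x 3 site coordinates [Angstrom]
#' @slot shell integer vector of shell indices (1 or 2)
#' @slot m averaged first-shell site count
#' @slot m2 averaged second-shell site count
#' @slot thickness shell thickness [Angstrom]
#' @slot siteVolume effective volume per site [Angstrom^3]
#' @export
setClass("HydrationShellModel",
         representation(sites = "matrix", shell = "integer", m = "numeric",
                        m2 = "numeric", thickness = "numeric",
                        siteVolume = "numeric"),
         validity = function(object) {
           if (nrow(object@sites) != length(object@shell))
             return("site/shell length mismatch")
           if (object@m <= 0) return("first-shell count must be positive")
           TRUE
         })

setMethod("show", "HydrationShellModel", function(object) {
  cat(sprintf(
    "HydrationShellModel: m=%g (shell 1), m2=%g (shell 2), thickness=%.1f A, site volume %.1f A^3\n",
    object@m, object@m2, object@thickness, object@siteVolume))
})

#' @describeIn buildShells first-shell site count
#' @param x a HydrationShellModel
#' @export
firstShellCount <- function(x) x@m
#' @describeIn buildShells second-shell site count
#' @export
secondShellCount <- function(x) x@m2

# FCC lattice covering a box, per-site volume matching one water.
# Returns coordinates plus integer lattice indices (cell i,j,k and basis
# 0..3) so that nearest-neighbour connectivity is pure index arithmetic.
.fccBase <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))

.fccLattice <- function(lo, hi, a, frac = c(0, 0, 0)) {
  ni <- seq(floor(lo[1] / a) - 1, ceiling(hi[1] / a) + 1)
  nj <- seq(floor(lo[2] / a) - 1, ceiling(hi[2] / a) + 1)
  nk <- seq(floor(lo[3] / a) - 1, ceiling(hi[3] / a) + 1)
  ijk <- as.matrix(expand.grid(i = ni, j = nj, k = nk))
  nc <- nrow(ijk)
  cells <- ijk[rep(seq_len(nc), each = 4L), , drop = FALSE]
  basis <- rep(0:3, times = nc)
  pts <- (cells + .fccBase[basis + 1L, , drop = FALSE] +
            matrix(frac, nc * 4L, 3, byrow = TRUE)) * a
  list(pts = pts, cells = cells, basis = basis,
       dims = c(length(ni), length(nj), length(nk)),
       origin = c(min(ni), min(nj), min(nk)))
}

# 12 nearest-neighbour lattice offsets per basis index (cell shift + basis)
.fccNeighbours <- local({
  out <- vector("list", 4L)
  for (b in 1:4) {
    nb <- list()
    for (b2 in 1:4) for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      v <- c(di, dj, dk) + .fccBase[b2, ] - .fccBase[b, ]
      if (abs(sum(v^2) - 0.5) < 1e-9)
        nb[[length(nb) + 1L]] <- c(di, dj, dk, b2 - 1L)
    }
    out[[b]] <- do.call(rbind, nb)
  }
  out
})

# mark lattice sites connected to the box boundary through solvent sites.
# An edge between two solvent sites is passable only if its midpoint lies
# outside every atom: this stops the walk from tunnelling through walls
# thinner than the lattice bond. The exact midpoint check is needed only
# when both endpoints are closer to the surface than half a bond length
# (Lipschitz bound on the distance field).
.accessibleSites <- function(lat, solvent, dsurf, xyz, rvdw) {
  halfBond <- sqrt(0.5) * (4 * .pc$nu_Wb0 / .pc$N_A * 1e27)^(1 / 3) / 2
  dims <- lat$dims
  idOf <- function(cells, basis)
    (( (cells[, 1] - lat$origin[1]) * dims[2] +
         (cells[, 2] - lat$origin[2])) * dims[3] +
       (cells[, 3] - lat$origin[3])) * 4L + basis + 1L
  n <- nrow(lat$pts)
  id <- idOf(lat$cells, lat$basis)
  solv <- logical(max(id)); solv[id[solvent]] <- TRUE
  pos <- integer(max(id)); pos[id] <- seq_len(n)
  ci <- lat$cells[, 1] - lat$origin[1]
  cj <- lat$cells[, 2] - lat$origin[2]
  ck <- lat$cells[, 3] - lat$origin[3]
  boundary <- solvent & (ci <= 0 | cj <= 0 | ck <= 0 |
                           ci >= dims[1] - 1 | cj >= dims[2] - 1 |
                           ck >= dims[3] - 1)
  visited <- logical(max(id))
  frontier <- id[boundary]
  visited[frontier] <- TRUE
  while (length(frontier)) {
    rows <- pos[frontier]
    nxt <- integer(0)
    for (b in 0:3) {
      sel <- lat$basis[rows] == b
      if (!any(sel)) next
      rb <- rows[sel]
      off <- .fccNeighbours[[b + 1L]]
      for (o in seq_len(nrow(off))) {
        cells2 <- cbind(lat$cells[rb, 1] + off[o, 1],
                        lat$cells[rb, 2] + off[o, 2],
                        lat$cells[rb, 3] + off[o, 3])
        inside <- cells2[, 1] >= lat$origin[1] &
          cells2[, 1] <= lat$origin[1] + dims[1] - 1 &
          cells2[, 2] >= lat$origin[2] &
          cells2[, 2] <= lat$origin[2] + dims[2] - 1 &
          cells2[, 3] >= lat$origin[3] &
          cells2[, 3] <= lat$origin[3] + dims[3] - 1
        if (!any(inside)) next
        id2 <- idOf(cells2[inside, , drop = FALSE],
                    rep(off[o, 4], sum(inside)))
        src <- rb[inside]
        ok <- solv[id2] & !visited[id2]
        if (!any(ok)) next
        id2 <- id2[ok]; src <- src[ok]
        dst <- pos[id2]
        # edge passability: guaranteed clear if either endpoint is more
        # than half a bond from the surface, otherwise check the midpoint
        clear <- pmax(dsurf[src], dsurf[dst]) > halfBond
        if (any(!clear)) {
          mid <- (lat$pts[src[!clear], , drop = FALSE] +
                    lat$pts[dst[!clear], , drop = FALSE]) / 2
          clear[!clear] <- .surfaceDistance(mid, xyz, rvdw) > 0
        }
        new <- id2[clear]
        if (length(new)) { visited[new] <- TRUE; nxt <- c(nxt, new) }
      }
    }
    frontier <- unique(nxt)
  }
  visited[id]
}

# distance from each site to the nearest atom van der Waals surface
.surfaceDistance <- function(sites, xyz, rvdw, chunk = 2048L) {
  n <- nrow(sites)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    blk <- sites[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(xyz^2), "+") -
      2 * tcrossprod(blk, xyz)
    d2[d2 < 0] <- 0
    out[s:e] <- apply(sweep(sqrt(d2), 2, rvdw, "-"), 1, min)
  }
  out
}

#' Build hydration shells around an atomic structure
#'
#' Buries the structure in a close-packed (FCC) lattice of solvent dummy
#' spheres whose per-site volume equals one bulk water molecule
#' (about 29.9 A^3, lattice constant about 4.93 A), removes points
#' overlapping the van der Waals envelope and assigns the remainder to
#' hydration shells of the given thickness. Shell counts are averaged
#' over a small set of lattice offsets to reduce registration artifacts;
#' the reported site coordinates come from the first offset.
#'
#' @param structure an [AtomicStructure-class]
#' @param nShells number of shells (default 2)
#' @param thickness shell thickness [Angstrom], default 2.8
#' @param nOffsets number of lattice offsets averaged (default 4)
#' @param radii optional per-atom radii [Angstrom] overriding the van der
#'   Waals table (e.g. to treat one pseudo-atom as an ideal sphere)
#' @return a [HydrationShellModel-class]
#' @examples
#' sph <- makeToyStructure("sphere", size = 12, nAtoms = 150, seed = 1)
#' sh <- buildShells(sph)
#' firstShellCount(sh)
#' @export
buildShells <- function(structure, nShells = 2, thickness = 2.8,
                        nOffsets = 4, radii = NULL) {
  stopifnot(is(structure, "AtomicStructure"), nShells >= 1, thickness > 0)
  xyz <- coords(structure)
  if (nrow(xyz) < 1L) stop("empty structure")
  rvdw <- if (is.null(radii)) vdwRadius(elements(structure)) else
    rep_len(radii, nrow(xyz))
  vSite <- .pc$nu_Wb0 / .pc$N_A * 1e27      # A^3 per water molecule
  a <- (4 * vSite)^(1 / 3)
  margin <- max(rvdw) + nShells * thickness + a
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  # fixed fractional offsets: deterministic, spread over the cell
  offs <- rbind(c(0, 0, 0), c(0.5, 0.25, 0.75), c(0.25, 0.75, 0.5),
                c(0.75, 0.5, 0.25), c(0.125, 0.375, 0.625),
                c(0.625, 0.125, 0.375))
  nOffsets <- min(nOffsets, nrow(offs))
  counts <- matrix(0, nOffsets, nShells)
  sites1 <- NULL; shell1 <- NULL
  for (o in seq_len(nOffsets)) {
    lat <- .fccLattice(lo, hi, a, offs[o, ])
    dsurf <- .surfaceDistance(lat$pts, xyz, rvdw)
    solvent <- dsurf > 0
    # only solvent sites reachable from outside count: interior voids of
    # the packing are not hydration sites
    acc <- .accessibleSites(lat, solvent, dsurf, xyz, rvdw)
    sh <- ceiling(dsurf / thickness)
    keep <- acc & sh <= nShells
    sh <- sh[keep]
    for (s in seq_len(nShells)) counts[o, s] <- sum(sh == s)
    if (o == 1L) {
      sites1 <- lat$pts[keep, , drop = FALSE]
      shell1 <- as.integer(sh)
    }
  }
  mbar <- colMeans(counts)
  if (mbar[1] <= 0) stop("no first-shell sites found")
  new("HydrationShellModel", sites = sites1, shell = shell1,
      m = mbar[1], m2 = if (nShells >= 2) mbar[2] else 0,
      thickness = thickness, siteVolume = vSite)
}

#' Water molecules released by an association step
#'
#' From first-shell hydration site counts: an association that turns the
#' reactant states into one product state releases
#' \eqn{\sum m_{react} - m_{prod}} first-shell waters to the bulk.
#'
#' @param mReactants first-shell site counts of the reacting species
#' @param mProduct first-shell site count of the product
#' @return released water count (can be fractional per monomer after
#'   dividing by the stoichiometry)
#' @examples
#' releasedWaters(c(199, 199), 320)       # insulin dimer formation: 78
#' releasedWaters(c(404, 404), 753) / 2   # per myoglobin monomer: 27.5
#' @export
releasedWaters <- function(mReactants, mProduct) {
  stopifnot(all(mReactants > 0), mProduct > 0)
  sum(mReactants) - mProduct
}

#' LocalDomain: composition of the first+second shell region
#'
#' Occupancies and molar volumes of the local domain around one protein
#' state under preferential solvation: bound cosolvent (larger than
#' water) spills into the second shell, displacing k_j of its sites; the
#' remaining second-shell sites fill with bulk solvent.
#'
#' @slot k second-shell sites displaced by bound cosolvent
#' @slot NW1,NG1 first-shell water / cosolvent occupancies
#' @slot NW2,NG2 second-shell water / cosolvent occupancies
#' @slot xGld cosolvent molar fraction of the local domain
#' @slot nuWld,nuGld local-domain molar volumes [L/mol]
#' @export
setClass("LocalDomain",
         representation(k = "numeric", NW1 = "numeric", NG1 = "numeric",
                        NW2 = "numeric", NG2 = "numeric", xGld = "numeric",
                        nuWld = "numeric", nuGld = "numeric"),
         validity = function(object) {
           if (any(c(object@NW1, object@NG1, object@NW2, object@NG2) < 0))
             return("occupancies must be non-negative")
           if (object@xGld < 0 || object@xGld > 1) return("xGld out of [0,1]")
           TRUE
         })

setMethod("show", "LocalDomain", function(object) {
  cat(sprintf(
    "LocalDomain: k=%.2f, NW=(%.1f, %.1f), NG=(%.2f, %.2f), xGld=%.4e\n",
    object@k, object@NW1, object@NW2, object@NG1, object@NG2, object@xGld))
})

#' Local-domain composition under preferential solvation
#'
#' @param m,m2 first/second shell site counts
#' @param phi first-shell water occupancy in [0,1]
#' @param xGb bulk cosolvent fraction of the solvent in [0,1)
#' @param nuWs site water molar volume [L/mol] (bulk value over d_j)
#' @param nuGs site cosolvent molar volume [L/mol] (equal to bulk)
#' @param nuWb,nuGb bulk molar volumes [L/mol]
#' @return a [LocalDomain-class]
#' @export
localDomain <- function(m, m2, phi, xGb, nuWs, nuGs, nuWb, nuGb) {
  stopifnot(phi >= 0, phi <= 1, xGb >= 0, xGb < 1, nuGs >= nuWs)
  k <- m * (1 - phi) * (nuGs - nuWs) / nuWb
  if (k > m2) {
    warning("bound cosolvent overflows the second shell; clamping k to m2")
    k <- m2
  }
  NW1 <- m * phi
  NG1 <- m * (1 - phi)
  avail <- m2 - k
  den <- 1 + xGb * (nuGb / nuWb - 1)
  NW2 <- avail * (1 - xGb) / den
  NG2 <- avail * xGb / den
  tot <- NW1 + NG1 + NW2 + NG2
  xGld <- (NG1 + NG2) / tot
  nuWld <- if (NW1 + NW2 > 0) (NW1 * nuWs + NW2 * nuWb) / (NW1 + NW2) else nuWb
  nuGld <- if (NG1 + NG2 > 0) (NG1 * nuGs + NG2 * nuGb) / (NG1 + NG2) else nuGb
  new("LocalDomain", k = k, NW1 = NW1, NG1 = NG1, NW2 = NW2, NG2 = NG2,
      xGld = xGld, nuWld = nuWld, nuGld = nuGld)
}

# molar-fraction-weighted SLD of a two-component solvent [cm^-2]
.sldMix <- function(xG, nuW, nuG, bW, bG) {
  volPerMol <- (xG * nuG + (1 - xG) * nuW) * 1000 / .pc$N_A  # cm^3/molecule
  (xG * bG + (1 - xG) * bW) / volPerMol
}

#' Scattering length density of the bulk binary solvent
#'
#' \eqn{\rho_0 = [x_{Gb} b_G + (1-x_{Gb}) b_W] /
#'       [x_{Gb} \nu_{Gb} + (1-x_{Gb}) \nu_{Wb}]} with per-molecule
#' volumes. Pure water at 25 C gives about 9.37e10 cm^-2.
#'
#' @param xGb bulk cosolvent fraction of the solvent
#' @param nuWb,nuGb molar volumes [L/mol]
#' @param bW,bG molecular scattering lengths [cm]
#' @return SLD [cm^-2]
#' @examples
#' pc <- physicalConstants()
#' sldBulk(0, 0.018, 0.2, pc$b_W, 100 * pc$r_e)
#' @export
sldBulk <- function(xGb, nuWb, nuGb, bW, bG) {
  stopifnot(xGb >= 0, xGb <= 1, nuWb > 0, nuGb > 0)
  .sldMix(xGb, nuWb, nuGb, bW, bG)
}

#' Scattering length density of the local domain
#'
#' Same mixing rule as [sldBulk()] but with the local-domain composition
#' and molar volumes; assigned uniformly to all first- and second-shell
#' sites of the state.
#'
#' @param domain a [LocalDomain-class]
#' @param bW,bG molecular scattering lengths [cm]
#' @return SLD [cm^-2]
#' @export
sldLocal <- function(domain, bW, bG) {
  stopifnot(is(domain, "LocalDomain"))
  .sldMix(domain@xGld, domain@nuWld, domain@nuGld, bW, bG)
}
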