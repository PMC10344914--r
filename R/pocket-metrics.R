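#' Hydrogen-bond detection criteria
#'
#' Without hydrogens (the usual case for docking poses and predicted
#' structures) a distance-only donor-acceptor criterion is applied: two
#' polar heavy atoms (N or O) within `max_da_distance`. When the donor
#' carries an explicit hydrogen, the D-H...A angle must additionally exceed
#' `min_dha_angle`.
#'
#' @param max_da_distance donor-acceptor heavy-atom cutoff, Angstrom.
#' @param min_dha_angle minimum D-H...A angle in degrees, applied only when
#'   hydrogens are present.
#' @return list of class `HBondCriteria`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_dha_angle = 120) {
  if (max_da_distance <= 0) stop("max_da_distance must be positive")
  if (min_dha_angle <= 0 || min_dha_angle > 180) {
    stop("min_dha_angle must be in (0, 180]")
  }
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle),
            class = "HBondCriteria")
}

#' Count protein-ligand hydrogen bonds
#'
#' Counts unique pairs of one protein polar heavy atom (N/O) and one ligand
#' polar heavy atom (N/O) satisfying the geometric criteria. Deterministic;
#' a ligand without polar atoms yields 0 with a warning.
#'
#' @param protein a [Structure].
#' @param ligand a [ligand_pose()].
#' @param criteria a [hbond_criteria()].
#' @param model protein model index.
#' @return integer hydrogen-bond count.
#' @export
count_hbonds <- function(protein, ligand, criteria = hbond_criteria(),
                         model = 1L) {
  stopifnot(inherits(protein, "Structure"), inherits(ligand, "LigandPose"))
  lig_polar <- ligand$atoms$element %in% c("N", "O")
  if (!any(lig_polar)) {
    warning("ligand has no polar (N/O) atoms; hydrogen-bond count is 0")
    return(0L)
  }
  pa <- protein$atoms
  pxyz <- model_coords(protein, model)
  prot_polar <- which(pa$element %in% c("N", "O") & !pa$is_het)
  if (length(prot_polar) == 0L) return(0L)

  lp <- ligand$xyz[lig_polar, , drop = FALSE]
  pp <- pxyz[prot_polar, , drop = FALSE]
  d2 <- outer(rowSums(pp^2), rowSums(lp^2), "+") - 2 * pp %*% t(lp)
  d2[d2 < 0] <- 0
  hits <- which(d2 <= criteria$max_da_distance^2, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(0L)

  # angle filter only where an explicit hydrogen is bonded to the protein
  # donor (covalent H within 1.3 A); hydrogen-free inputs skip this branch
  h_idx <- which(pa$element == "H")
  if (length(h_idx) > 0L) {
    keep <- logical(nrow(hits))
    hxyz <- pxyz[h_idx, , drop = FALSE]
    for (r in seq_len(nrow(hits))) {
      d <- pp[hits[r, 1], ]
      a <- lp[hits[r, 2], ]
      dh <- sqrt(rowSums(sweep(hxyz, 2, d)^2))
      bonded <- which(dh <= 1.3)
      if (length(bonded) == 0L) { keep[r] <- TRUE; next }
      ang <- vapply(bonded, function(j) {
        h <- hxyz[j, ]
        v1 <- d - h; v2 <- a - h
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      }, numeric(1))
      keep[r] <- any(ang >= criteria$min_dha_angle)
    }
    hits <- hits[keep, , drop = FALSE]
  }
  nrow(hits)
}

#' Serine nucleophilic attack distance
#'
#' Euclidean distance from the catalytic serine hydroxyl oxygen (OG) to the
#' two ester carbonyl carbons of the ligand (atoms `C7` and `C10`). The
#' scoring pipeline consumes the minimum of the two — nucleophilic attack
#' proceeds on whichever carbonyl is closer — but both are available.
#'
#' @param protein a [Structure].
#' @param ligand a [ligand_pose()] containing atoms `C7` and `C10`.
#' @param site a [catalytic_site()].
#' @param mode `"min"` (default, scalar) or `"both"` (named pair).
#' @param model protein model index.
#' @return distance(s) in Angstrom.
#' @export
attack_distance <- function(protein, ligand, site, mode = c("min", "both"),
                            model = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(site, "CatalyticSite"))
  og <- model_coords(protein, model)[site$og_index, ]
  i7 <- which(ligand$atoms$name == "C7")
  i10 <- which(ligand$atoms$name == "C10")
  if (length(i7) == 0L) stop("ligand lacks atom C7")
  if (length(i10) == 0L) stop("ligand lacks atom C10")
  d7 <- sqrt(sum((ligand$xyz[i7[1], ] - og)^2))
  d10 <- sqrt(sum((ligand$xyz[i10[1], ] - og)^2))
  if (mode == "min") min(d7, d10) else c(C7 = d7, C10 = d10)
}

#' Cavity-grid parameters
#'
#' Dual-probe grid definition for cavity detection: the small probe
#' (`probe_in`, water-sized) delimits accessible space, the large probe
#' (`probe_out`) rolls in from the bulk and excludes open solvent, and what
#' the small probe reaches but the large probe cannot is cavity.
#'
#' @param spacing voxel edge, Angstrom (0 < spacing <= probe_in).
#' @param probe_in small probe radius, Angstrom.
#' @param probe_out large probe radius, Angstrom (> probe_in).
#' @param padding extra box margin beyond the atom extent, Angstrom.
#' @return list of class `CavityGrid`.
#' @export
cavity_grid <- function(spacing = 0.6, probe_in = 1.4, probe_out = 4.0,
                        padding = 1.0) {
  if (spacing <= 0 || spacing > probe_in) {
    stop("spacing must satisfy 0 < spacing <= probe_in")
  }
  if (probe_out <= probe_in) stop("probe_out must exceed probe_in")
  structure(list(spacing = spacing, probe_in = probe_in,
                 probe_out = probe_out, padding = padding),
            class = "CavityGrid")
}

#' Cavity volume between a ligand and its contact shell
#'
#' Grid-based dual-probe cavity detection restricted to the sub-box
#' enclosing the ligand plus the protein residues within `shell_cutoff` of
#' it. A voxel counts as cavity when its center (i) does not overlap any
#' heavy-atom van der Waals sphere, (ii) admits the small probe (distance
#' to every atom exceeds vdW radius + `probe_in`), and (iii) is not bulk
#' solvent — i.e. not within `probe_out` of the exterior region the large
#' probe can reach from outside the box. Volume is voxel count times
#' `spacing^3`; it is monotone non-increasing in `probe_in`.
#'
#' @param protein a [Structure].
#' @param ligand a [ligand_pose()].
#' @param grid a [cavity_grid()].
#' @param shell_cutoff contact-shell cutoff around the ligand, Angstrom.
#' @param model protein model index.
#' @return cavity volume in cubic Angstrom.
#' @export
cavity_volume <- function(protein, ligand, grid = cavity_grid(),
                          shell_cutoff = 4.0, model = 1L) {
  stopifnot(inherits(grid, "CavityGrid"))
  shell <- select_within(protein, ligand$xyz, shell_cutoff, model = model)
  if (nrow(shell) == 0L) {
    warning("no protein residues within ", shell_cutoff,
            " A of the ligand; cavity volume is 0")
    return(0)
  }
  key <- residue_keys(protein)
  shell_key <- paste(shell$chain, shell$resno, shell$inscode, sep = "|")
  sel <- key %in% shell_key & protein$atoms$element != "H"
  pxyz <- model_coords(protein, model)[sel, , drop = FALSE]
  prad <- vdw_radius(protein$atoms$element[sel])
  lheavy <- ligand$atoms$element != "H"
  axyz <- rbind(pxyz, ligand$xyz[lheavy, , drop = FALSE])
  arad <- c(prad, vdw_radius(ligand$atoms$element[lheavy]))
  .grid_cavity(axyz, arad, grid)
}

# Core dual-probe computation on an explicit atom set.
.grid_cavity <- function(axyz, arad, grid) {
  sp <- grid$spacing
  pad <- grid$padding + grid$probe_out + max(arad)
  lo <- apply(axyz, 2, min) - pad
  hi <- apply(axyz, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = sp)
  gy <- seq(lo[2], hi[2], by = sp)
  gz <- seq(lo[3], hi[3], by = sp)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)

  # nearest-atom distance minus vdW radius for every voxel center; only
  # distances below probe_out matter, so each atom touches just the voxels
  # inside its reach (vdW + probe_out + one voxel) — a cheap cell pruning
  dmin <- array(Inf, dim = c(nx, ny, nz))
  for (i in seq_len(nrow(axyz))) {
    reach <- arad[i] + grid$probe_out + sp
    ix <- which(abs(gx - axyz[i, 1]) <= reach)
    iy <- which(abs(gy - axyz[i, 2]) <= reach)
    iz <- which(abs(gz - axyz[i, 3]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - axyz[i, 1])^2
    dy2 <- (gy[iy] - axyz[i, 2])^2
    dz2 <- (gz[iz] - axyz[i, 3])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+")) - arad[i]
    dmin[ix, iy, iz] <- pmin(dmin[ix, iy, iz], d)
  }
  free_small <- dmin > grid$probe_in
  free_big <- dmin > grid$probe_out

  # exterior = large-probe-accessible region connected to the box boundary
  exterior <- .flood_from_boundary(free_big)
  # bulk solvent = small-probe space within probe_out of the exterior
  bulk <- .dilate(exterior, radius_vox = ceiling(grid$probe_out / sp))
  cavity <- free_small & !bulk
  sum(cavity) * sp^3
}

# 6-connected flood fill of TRUE voxels reachable from the array boundary.
.flood_from_boundary <- function(mask) {
  dm <- dim(mask)
  reach <- array(FALSE, dm)
  boundary <- array(FALSE, dm)
  boundary[1, , ] <- TRUE; boundary[dm[1], , ] <- TRUE
  boundary[, 1, ] <- TRUE; boundary[, dm[2], ] <- TRUE
  boundary[, , 1] <- TRUE; boundary[, , dm[3]] <- TRUE
  frontier <- mask & boundary
  reach <- frontier
  repeat {
    grown <- .shift_or(frontier)
    nxt <- grown & mask & !reach
    if (!any(nxt)) break
    reach <- reach | nxt
    frontier <- nxt
  }
  reach
}

# OR of the six axis-neighbor shifts of a logical 3D array.
.shift_or <- function(a) {
  dm <- dim(a)
  out <- array(FALSE, dm)
  out[-1, , ] <- out[-1, , ] | a[-dm[1], , ]
  out[-dm[1], , ] <- out[-dm[1], , ] | a[-1, , ]
  out[, -1, ] <- out[, -1, ] | a[, -dm[2], ]
  out[, -dm[2], ] <- out[, -dm[2], ] | a[, -1, ]
  out[, , -1] <- out[, , -1] | a[, , -dm[3]]
  out[, , -dm[3]] <- out[, , -dm[3]] | a[, , -1]
  out
}

# OR of the 26 neighbor shifts (full 3x3x3 cube minus center).
.shift_or26 <- function(a) {
  dm <- dim(a)
  out <- a
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- max(1, 1 + dx):min(dm[1], dm[1] + dx)
    sy <- max(1, 1 + dy):min(dm[2], dm[2] + dy)
    sz <- max(1, 1 + dz):min(dm[3], dm[3] + dz)
    out[sx, sy, sz] <- out[sx, sy, sz] | a[sx - dx, sy - dy, sz - dz]
  }
  out
}

# Approximate spherical dilation by alternating 6-connected (octahedral)
# and 26-connected (cubic) unit steps; the alternation keeps the grown
# region close to a Euclidean ball of the requested radius.
.dilate <- function(mask, radius_vox) {
  if (!any(mask) || radius_vox <= 0) return(mask)
  out <- mask
  grown <- 0
  use26 <- FALSE
  while (grown < radius_vox) {
    out <- if (use26) .shift_or26(out) else (out | .shift_or(out))
    grown <- grown + if (use26) sqrt(2) else 1  # average radial gain
    use26 <- !use26
  }
  out
}

#' Assemble the four scoring factors for one variant
#'
#' Combines the three computed geometric factors (hydrogen-bond count,
#' minimum serine attack distance, cavity volume) with the ingested docking
#' binding energy into one record of the scoring table. Binding energies
#' come from an external docking run and are looked up by variant id.
#'
#' @param variant_id id to look up in `binding_energy_table`.
#' @param protein a [Structure].
#' @param ligand a [ligand_pose()].
#' @param site a [catalytic_site()].
#' @param binding_energy_table data.frame with columns `variant_id`,
#'   `binding_energy_kcal_mol` (e.g. from [read_binding_energies()]).
#' @param criteria a [hbond_criteria()].
#' @param grid a [cavity_grid()].
#' @param shell_cutoff contact-shell cutoff, Angstrom.
#' @return one-row data.frame `variant_id, A_binding_energy, B_hbond_count,
#'   C_attack_distance, D_cavity_volume`.
#' @export
assemble_factors <- function(variant_id, protein, ligand, site,
                             binding_energy_table,
                             criteria = hbond_criteria(),
                             grid = cavity_grid(), shell_cutoff = 4.0) {
  tab <- binding_energy_table
  if (anyDuplicated(tab$variant_id)) {
    stop("duplicate variant ids in binding-energy table: ",
         paste(unique(tab$variant_id[duplicated(tab$variant_id)]),
               collapse = ", "))
  }
  i <- match(variant_id, tab$variant_id)
  if (is.na(i)) {
    stop("no binding energy for '", variant_id, "'; available: ",
         paste(tab$variant_id, collapse = ", "))
  }
  data.frame(
    variant_id = variant_id,
    A_binding_energy = tab$binding_energy_kcal_mol[i],
    B_hbond_count = count_hbonds(protein, ligand, criteria),
    C_attack_distance = attack_distance(protein, ligand, site, mode = "min"),
    D_cavity_volume = cavity_volume(protein, ligand, grid, shell_cutoff)
  )
}

#' Read a binding-energy table
#'
#' @param path delimited file with header
#'   `variant_id,binding_energy_kcal_mol`.
#' @return data.frame.
#' @export
read_binding_energies <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "binding_energy_kcal_mol")
  if (!all(need %in% names(tab))) {
    stop("binding-energy table must have columns ",
         paste(need, collapse = ", "))
  }
  tab
}
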