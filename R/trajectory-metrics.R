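#' Construct a trajectory
#'
#' Wraps a multi-model [Structure] whose models are frames stored at a
#' uniform time interval, together with the residue keys of the substrate
#' copies and waters. Frame times are in nanoseconds.
#'
#' @param s a multi-model [Structure] with constant topology.
#' @param times numeric vector of frame times (ns), one per model.
#' @param ligand_ids residue keys (`"chain|resno|inscode"`) of substrate
#'   copies.
#' @param water_ids residue keys of water molecules.
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(s, times, ligand_ids = character(),
                       water_ids = character()) {
  stopifnot(inherits(s, "Structure"))
  if (length(times) != n_models(s)) {
    stop("frame count (", n_models(s), ") and time count (", length(times),
         ") differ")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(structure = s, times = times, ligand_ids = ligand_ids,
                 water_ids = water_ids),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d frames over %.1f-%.1f ns, %d ligand(s), %d water(s)\n",
    length(x$times), min(x$times), max(x$times),
    length(x$ligand_ids), length(x$water_ids)))
  invisible(x)
}

#' Time window for trajectory analysis
#'
#' @param start_ns,end_ns window bounds in nanoseconds (start < end).
#' @return object of class `AnalysisWindow`.
#' @export
analysis_window <- function(start_ns, end_ns) {
  if (start_ns < 0 || start_ns >= end_ns) {
    stop("need 0 <= start_ns < end_ns")
  }
  structure(list(start_ns = start_ns, end_ns = end_ns),
            class = "AnalysisWindow")
}

# Frame indices whose times fall inside the window (inclusive bounds).
window_frames <- function(traj, window) {
  which(traj$times >= window$start_ns & traj$times <= window$end_ns)
}

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body superposition of a mobile coordinate set onto a
#' reference over a common atom selection, via SVD of the covariance
#' matrix with the usual reflection correction. Returns the transformed
#' coordinates and the post-fit RMSD.
#'
#' @param mobile numeric matrix `n x 3` to transform (all atoms).
#' @param reference numeric matrix `n x 3`.
#' @param selection indices of the atoms used for the fit (>= 3); the
#'   transform is applied to all rows of `mobile`.
#' @return list with `coords` (transformed `mobile`), `rmsd` (Angstrom,
#'   over the selection), `rotation`, `translation`.
#' @export
superpose <- function(mobile, reference, selection = seq_len(nrow(mobile))) {
  if (length(selection) < 3L) stop("need at least 3 atoms to superpose")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("selection cardinality differs between sets")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fit <- sweep(sweep(mobile, 2, ca) %*% t(R), 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((fit[selection, , drop = FALSE] - B)^2)))
  list(coords = fit, rmsd = rmsd, rotation = R,
       translation = cb - as.vector(R %*% ca))
}

#' Mass-weighted radius of gyration
#'
#' @param s a [Structure].
#' @param selection atom indices (default: all heavy atoms).
#' @param model model index.
#' @return radius of gyration in Angstrom (0 for a single atom).
#' @export
radius_of_gyration <- function(s, selection = NULL, model = 1L) {
  stopifnot(inherits(s, "Structure"))
  if (is.null(selection)) selection <- which(s$atoms$element != "H")
  if (length(selection) == 0L) stop("empty selection")
  xyz <- model_coords(s, model)[selection, , drop = FALSE]
  m <- atomic_mass(s$atoms$element[selection])
  com <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames in the analysis window are first superposed onto the
#' window-average structure (computed by one fit-average refinement pass),
#' then each residue's representative atom fluctuates about its own window
#' mean. A static trajectory gives exactly zero for every residue.
#'
#' @param traj a [trajectory()].
#' @param window an [analysis_window()], e.g. the last 40 ns.
#' @param selection atom indices of the per-residue representative atoms
#'   (default: protein CA atoms; falls back to first atom per residue).
#' @param fit superpose frames before measuring fluctuations (disable for
#'   fixtures that are already in a common frame, where the closed-form
#'   per-residue fluctuation is wanted exactly).
#' @return data.frame `chain, resno, inscode, rmsf` (Angstrom).
#' @export
rmsf <- function(traj, window, selection = NULL, fit = TRUE) {
  stopifnot(inherits(traj, "Trajectory"))
  s <- traj$structure
  frames <- window_frames(traj, window)
  if (length(frames) < 2L) stop("analysis window contains fewer than 2 frames")
  if (is.null(selection)) {
    is_prot <- !s$atoms$is_het
    selection <- which(is_prot & s$atoms$name == "CA")
    if (length(selection) == 0L) {
      key <- residue_keys(s)
      selection <- which(is_prot & !duplicated(key))
    }
  }
  if (fit) {
    ref <- model_coords(s, frames[1])
    fitted <- lapply(frames, function(k) {
      superpose(model_coords(s, k), ref,
                selection)$coords[selection, , drop = FALSE]
    })
    mean_xyz <- Reduce(`+`, fitted) / length(fitted)
    # refit onto the window average so fluctuations are about the true mean
    fitted <- lapply(frames, function(k) {
      m <- model_coords(s, k)[selection, , drop = FALSE]
      superpose(m, mean_xyz)$coords
    })
  } else {
    fitted <- lapply(frames, function(k) {
      model_coords(s, k)[selection, , drop = FALSE]
    })
  }
  mean_xyz <- Reduce(`+`, fitted) / length(fitted)
  dev2 <- Reduce(`+`, lapply(fitted, function(f) {
    rowSums((f - mean_xyz)^2)
  })) / length(fitted)
  data.frame(chain = s$atoms$chain[selection],
             resno = s$atoms$resno[selection],
             inscode = s$atoms$inscode[selection],
             rmsf = sqrt(dev2))
}

# Deterministic quasi-uniform sphere points (golden-spiral lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic sphere-point SASA: each heavy atom is covered with a
#' golden-spiral lattice of `n_points` points at radius vdW + probe, and
#' the exposed fraction is the share of points not buried inside any
#' neighbor's probe-expanded sphere.
#'
#' @param s a [Structure].
#' @param probe probe radius, Angstrom (water = 1.4).
#' @param n_points points per atom (>= 16; more points, less quadrature
#'   error).
#' @param selection atom indices (default: all heavy atoms).
#' @param model model index.
#' @return list with `total` (Angstrom^2), `per_atom`, and `per_residue`
#'   (data.frame `chain, resno, inscode, sasa`).
#' @export
sasa <- function(s, probe = 1.4, n_points = 960L, selection = NULL,
                 model = 1L) {
  stopifnot(inherits(s, "Structure"))
  if (n_points < 16L) stop("n_points must be at least 16")
  if (is.null(selection)) selection <- which(s$atoms$element != "H")
  xyz <- model_coords(s, model)[selection, , drop = FALSE]
  rad <- vdw_radius(s$atoms$element[selection]) + probe
  # degenerate input: exactly coincident equal-radius atoms describe one
  # sphere, so duplicates are dropped from the point test (their exposed
  # area would otherwise be double-counted)
  dup <- duplicated(round(cbind(xyz, rad), 6))
  if (any(dup)) {
    selection <- selection[!dup]
    xyz <- xyz[!dup, , drop = FALSE]
    rad <- rad[!dup]
  }
  pts <- .sphere_points(n_points)
  n <- nrow(xyz)
  per_atom <- numeric(n)
  # neighbor lists keep the point-burial test local
  for (i in seq_len(n)) {
    di <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nb <- which(di < rad[i] + rad & seq_len(n) != i)
    sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    if (length(nb) == 0L) {
      exposed <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        d2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        buried <- buried | d2 < rad[j]^2
        if (all(buried)) break
      }
      exposed <- sum(!buried)
    }
    per_atom[i] <- 4 * pi * rad[i]^2 * exposed / n_points
  }
  key <- residue_keys(s)[selection]
  per_res <- stats::aggregate(per_atom, by = list(key = key), FUN = sum)
  first <- !duplicated(key)
  ord <- match(unique(key), per_res$key)
  per_residue <- data.frame(chain = s$atoms$chain[selection][first],
                            resno = s$atoms$resno[selection][first],
                            inscode = s$atoms$inscode[selection][first],
                            sasa = per_res$x[ord])
  list(total = sum(per_atom), per_atom = per_atom,
       per_residue = per_residue)
}

#' Molecule occupancy at the substrate binding site
#'
#' The substrate binding site is modelled as a sphere of `cutoff` Angstrom
#' around the catalytic Ser hydroxyl oxygen (OG) — a simple reproducible
#' proxy for the substrate binding cleft. A molecule occupies the site in a
#' frame when at least one of its heavy atoms lies within the cutoff.
#' Returns the per-frame counts over the window plus the window mean and
#' per-10-ns-bin means.
#'
#' @param traj a [trajectory()].
#' @param window an [analysis_window()].
#' @param site a [catalytic_site()] resolvable in the topology.
#' @param species `"ligand"` or `"water"`.
#' @param cutoff site radius, Angstrom.
#' @param bin_ns width of the aggregate bins, ns.
#' @return list with `times`, `counts` (integer per frame), `mean`, and
#'   `bins` (data.frame `start_ns, end_ns, mean_count`).
#' @export
site_occupancy <- function(traj, window, site, species = c("ligand", "water"),
                           cutoff = 6.0, bin_ns = 10) {
  species <- match.arg(species)
  stopifnot(inherits(traj, "Trajectory"), inherits(site, "CatalyticSite"))
  ids <- if (species == "ligand") traj$ligand_ids else traj$water_ids
  if (length(ids) == 0L) stop("trajectory has no ", species, " molecules")
  s <- traj$structure
  frames <- window_frames(traj, window)
  if (length(frames) == 0L) stop("analysis window contains no frames")
  key <- residue_keys(s)
  heavy <- s$atoms$element != "H"
  mol_atoms <- lapply(ids, function(id) which(key == id & heavy))
  counts <- vapply(frames, function(k) {
    xyz <- model_coords(s, k)
    og <- xyz[site$og_index, ]
    sum(vapply(mol_atoms, function(idx) {
      any(rowSums(sweep(xyz[idx, , drop = FALSE], 2, og)^2) <= cutoff^2)
    }, logical(1)))
  }, integer(1))
  times <- traj$times[frames]
  bin <- floor((times - window$start_ns) / bin_ns)
  bins <- stats::aggregate(counts, by = list(bin = bin), FUN = mean)
  list(times = times, counts = counts, mean = mean(counts),
       bins = data.frame(start_ns = window$start_ns + bins$bin * bin_ns,
                         end_ns = pmin(window$start_ns + (bins$bin + 1) * bin_ns,
                                       window$end_ns),
                         mean_count = bins$x))
}

#' Ser OG to ligand carbonyl-carbon distance series
#'
#' Per-frame Euclidean distances from the catalytic serine OG to the two
#' ester carbonyl carbons (C7, C10) of one substrate copy. No smoothing by
#' default; an optional centered running mean is available.
#'
#' @param traj a [trajectory()].
#' @param site a [catalytic_site()].
#' @param ligand_id residue key of the substrate copy.
#' @param smooth_width odd window width of an optional running mean
#'   (0 = none).
#' @return data.frame `time_ns, d_C7, d_C10` (Angstrom).
#' @export
distance_series <- function(traj, site, ligand_id, smooth_width = 0L) {
  stopifnot(inherits(traj, "Trajectory"), inherits(site, "CatalyticSite"))
  s <- traj$structure
  key <- residue_keys(s)
  i7 <- which(key == ligand_id & s$atoms$name == "C7")
  i10 <- which(key == ligand_id & s$atoms$name == "C10")
  if (length(i7) == 0L) stop("ligand ", ligand_id, " lacks atom C7")
  if (length(i10) == 0L) stop("ligand ", ligand_id, " lacks atom C10")
  nf <- n_models(s)
  d7 <- numeric(nf); d10 <- numeric(nf)
  for (k in seq_len(nf)) {
    xyz <- model_coords(s, k)
    og <- xyz[site$og_index, ]
    d7[k] <- sqrt(sum((xyz[i7[1], ] - og)^2))
    d10[k] <- sqrt(sum((xyz[i10[1], ] - og)^2))
  }
  if (smooth_width > 1L) {
    sm <- function(x) as.numeric(stats::filter(x, rep(1 / smooth_width,
                                                      smooth_width),
                                               sides = 2))
    d7s <- sm(d7); d10s <- sm(d10)
    d7 <- ifelse(is.na(d7s), d7, d7s)
    d10 <- ifelse(is.na(d10s), d10, d10s)
  }
  data.frame(time_ns = traj$times, d_C7 = d7, d_C10 = d10)
}

#' Spatial distribution grid of a molecular species
#'
#' Frames are superposed onto the first window frame over the protein
#' atoms, then each voxel records the fraction of window frames in which
#' at least one heavy atom of the species falls inside it — a bounded,
#' resolution-robust occupancy statistic.
#'
#' @param traj a [trajectory()].
#' @param window an [analysis_window()].
#' @param species `"ligand"` or `"water"`.
#' @param spacing voxel edge, Angstrom.
#' @param superpose_frames superpose frames on protein atoms first
#'   (disable for pre-aligned synthetic trajectories).
#' @return object of class `Grid3D`: list with `origin`, `spacing`, `dims`,
#'   and `fraction` (3D array in `[0, 1]`).
#' @export
spatial_distribution <- function(traj, window, species = c("ligand", "water"),
                                 spacing = 1.0, superpose_frames = TRUE) {
  species <- match.arg(species)
  stopifnot(inherits(traj, "Trajectory"))
  s <- traj$structure
  frames <- window_frames(traj, window)
  if (length(frames) == 0L) stop("analysis window contains no frames")
  ids <- if (species == "ligand") traj$ligand_ids else traj$water_ids
  key <- residue_keys(s)
  sp_idx <- which(key %in% ids & s$atoms$element != "H")
  prot_idx <- which(!s$atoms$is_het)

  ref <- model_coords(s, frames[1])
  coords <- lapply(frames, function(k) {
    m <- model_coords(s, k)
    if (superpose_frames && length(prot_idx) >= 3L) {
      m <- superpose(m, ref, prot_idx)$coords
    }
    m[sp_idx, , drop = FALSE]
  })
  all_pts <- do.call(rbind, c(coords, list(ref[sp_idx, , drop = FALSE])))
  if (nrow(all_pts) == 0L) {
    origin <- c(0, 0, 0); dims <- c(1L, 1L, 1L)
    frac <- array(0, dims)
    return(structure(list(origin = origin, spacing = spacing, dims = dims,
                          fraction = frac), class = "Grid3D"))
  }
  origin <- floor(apply(all_pts, 2, min) / spacing) * spacing
  dims <- pmax(1L, ceiling((apply(all_pts, 2, max) - origin) / spacing) + 1L)
  hit_count <- array(0L, dims)
  for (m in coords) {
    if (nrow(m) == 0L) next
    v <- floor(sweep(m, 2, origin) / spacing) + 1L
    v[v < 1L] <- 1L
    for (d in 1:3) v[v[, d] > dims[d], d] <- dims[d]
    lin <- unique((v[, 3] - 1L) * dims[1] * dims[2] +
                    (v[, 2] - 1L) * dims[1] + v[, 1])
    hit_count[lin] <- hit_count[lin] + 1L
  }
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 fraction = hit_count / length(frames)),
            class = "Grid3D")
}

#' Write a Grid3D as a Gaussian cube file
#'
#' @param grid a `Grid3D` from [spatial_distribution()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, path) {
  stopifnot(inherits(grid, "Grid3D"))
  bohr <- 1 / 0.529177210903
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("occupancy fraction grid", "generated by barriereng"), con)
  o <- grid$origin * bohr
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", 1L, o[1], o[2], o[3]), con)
  sp <- grid$spacing * bohr
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", grid$dims[1], sp, 0, 0), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", grid$dims[2], 0, sp, 0), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", grid$dims[3], 0, 0, sp), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", 1L, 0, o[1], o[2], o[3]),
             con)
  # cube order: x slowest, z fastest
  vals <- as.vector(aperm(grid$fraction, c(3, 2, 1)))
  writeLines(paste(sprintf("%13.5e", vals), collapse = " "), con)
  invisible(path)
}
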