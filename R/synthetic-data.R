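#' Generator configuration
#'
#' One seeded configuration object drives every synthetic fixture. The
#' defaults reproduce the study conditions the analyses assume: 30
#' substrate copies in the box, frames stored every 0.5 ns over a 100 ns
#' production run, a 10 Angstrom box margin around the protein, and a 6
#' Angstrom substrate-binding-site sphere around the catalytic Ser OG.
#'
#' @param seed integer seed fixing every stochastic output.
#' @param n_residues residues in the toy protein (>= 20).
#' @param n_ligands substrate copies in the box.
#' @param n_waters water molecules in the box.
#' @param frame_interval_ns trajectory storage interval, ns.
#' @param duration_ns production length, ns.
#' @param occupancy_schedule list of `list(start_ns, end_ns, count)`
#'   windows during which exactly `count` ligands are held inside the
#'   site; windows must not overlap.
#' @param jitter_sigma Gaussian positional jitter of protein atoms per
#'   frame, Angstrom (0 = static protein).
#' @param step_sigma random-walk step of free molecules per frame,
#'   Angstrom.
#' @param site_cutoff site sphere radius around Ser OG, Angstrom.
#' @param box_margin box margin beyond the protein extent, Angstrom.
#' @param decay_noise,kinetics_noise multiplicative log-normal noise
#'   levels of the assay generators.
#' @return list of class `GeneratorConfig`.
#' @export
generator_config <- function(seed = 1L, n_residues = 60L, n_ligands = 30L,
                             n_waters = 120L, frame_interval_ns = 0.5,
                             duration_ns = 100, occupancy_schedule = list(),
                             jitter_sigma = 0.15, step_sigma = 1.0,
                             site_cutoff = 6.0, box_margin = 10,
                             decay_noise = 0.05, kinetics_noise = 0.05) {
  if (n_residues < 20L) stop("toy protein needs at least 20 residues")
  if (length(occupancy_schedule) > 1L) {
    ss <- vapply(occupancy_schedule, function(w) w[[1]], numeric(1))
    ee <- vapply(occupancy_schedule, function(w) w[[2]], numeric(1))
    o <- order(ss)
    if (any(ss[o][-1] < ee[o][-length(ee)])) {
      stop("occupancy schedule windows must not overlap")
    }
  }
  for (w in occupancy_schedule) {
    if (w[[2]] > duration_ns) stop("schedule window exceeds duration")
    if (w[[3]] > n_ligands) stop("scheduled count exceeds n_ligands")
  }
  structure(list(seed = as.integer(seed), n_residues = as.integer(n_residues),
                 n_ligands = as.integer(n_ligands),
                 n_waters = as.integer(n_waters),
                 frame_interval_ns = frame_interval_ns,
                 duration_ns = duration_ns,
                 occupancy_schedule = occupancy_schedule,
                 jitter_sigma = jitter_sigma, step_sigma = step_sigma,
                 site_cutoff = site_cutoff, box_margin = box_margin,
                 decay_noise = decay_noise, kinetics_noise = kinetics_noise),
            class = "GeneratorConfig")
}

#' Build a pocket-bearing toy protein
#'
#' Parametric alpha-helix backbone (1.5 Angstrom rise, 100 degrees per
#' residue) wound along a horseshoe arc so the fold encloses an open
#' pocket; the residue at the middle of the arc is a serine whose OG atom
#' points into the pocket mouth. Realism is deliberately minimal — only
#' backbone N/CA/C/O plus the one OG — because every downstream operation
#' needs heavy-atom geometry, names and numbering, nothing more.
#'
#' @param cfg a [generator_config()].
#' @return a [Structure] (single model, chain A) whose catalytic Ser is at
#'   residue `ceiling(n_residues / 2)`.
#' @export
build_toy_protein <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_residues
  arc_radius <- 9.0
  arc_span <- 300 * pi / 180
  theta <- seq(-arc_span / 2, arc_span / 2, length.out = n)
  psi <- (seq_len(n) - 1) * 100 * pi / 180    # helical phase
  helix_r <- 1.5
  ca <- cbind((arc_radius + helix_r * cos(psi)) * cos(theta),
              (arc_radius + helix_r * cos(psi)) * sin(theta),
              helix_r * sin(psi))
  # small seeded backbone perturbation so different seeds give different
  # folds while the horseshoe pocket survives
  ca <- ca + matrix(stats::rnorm(length(ca), 0, 0.15), ncol = 3)
  ser_idx <- ceiling(n / 2)

  rows <- list(); coords <- list(); serial <- 0L
  for (i in seq_len(n)) {
    resname <- if (i == ser_idx) "SER" else c("ALA", "GLY", "VAL", "LEU")[
      1 + (i %% 4)]
    # minimal backbone offsets around CA
    local <- rbind(N = c(-1.2, 0.4, 0), CA = c(0, 0, 0),
                   C = c(1.2, 0.4, 0), O = c(1.8, 1.4, 0))
    el <- c("N", "C", "C", "O")
    nm <- c("N", "CA", "C", "O")
    if (i == ser_idx) {
      # OG points from the CA toward the arc center (the pocket mouth)
      inward <- -ca[i, ] / sqrt(sum(ca[i, ]^2))
      local <- rbind(local, OG = inward * 2.4)
      el <- c(el, "O"); nm <- c(nm, "OG")
    }
    for (j in seq_len(nrow(local))) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = nm[j], altloc = " ", resname = resname,
        chain = "A", resno = i, inscode = "", element = el[j],
        occupancy = 1, bfactor = 0, is_het = FALSE,
        stringsAsFactors = FALSE)
      coords[[serial]] <- ca[i, ] + local[j, ]
    }
  }
  Structure(do.call(rbind, rows), do.call(rbind, coords),
            header = sprintf("TOY HORSESHOE PROTEIN seed=%d", cfg$seed))
}

# Idealized planar BHET heavy-atom template (18 atoms): benzene ring
# C1-C6, ester arms C7(=O1)-O2-C8-C9-O3 and C10(=O4)-O5-C11-C12-O6.
# C7 and C10 are the two ester carbonyl carbons; their through-space
# span is the para-dicarbonyl distance (~5.8 Angstrom).
.bhet_template <- function() {
  ring_r <- 1.39
  ang <- (0:5) * pi / 3
  ring <- cbind(ring_r * cos(ang), ring_r * sin(ang), 0)
  arm <- function(dir, side) {
    # dir: unit vector from ring center through the attachment carbon;
    # the hydroxyethyl tail takes a folded (gauche-like) conformation so
    # the molecule stays compact, as the solution conformer is
    perp <- c(-dir[2], dir[1], 0)
    up <- c(0, 0, 1) * side
    c7 <- dir * (ring_r + 1.49)
    o1 <- c7 + perp * 1.23                                    # carbonyl O
    o2 <- c7 + (dir * cos(1.0) - perp * sin(1.0)) * 1.34      # ester O
    c8 <- o2 + (dir * 0.30 - perp * 0.55 + up * 0.78) * 1.44
    c9 <- c8 + (dir * 0.45 + perp * 0.45 + up * 0.77) * 1.52
    o3 <- c9 + (-dir * 0.50 + perp * 0.40 + up * 0.77) * 1.42
    rbind(c7, o1, o2, c8, c9, o3)
  }
  xyz <- rbind(ring, arm(c(1, 0, 0), 1), arm(c(-1, 0, 0), -1))
  rownames(xyz) <- NULL
  list(
    xyz = xyz,
    name = c(paste0("C", 1:6), "C7", "O1", "O2", "C8", "C9", "O3",
             "C10", "O4", "O5", "C11", "C12", "O6"),
    element = c(rep("C", 6), "C", "O", "O", "C", "C", "O",
                "C", "O", "O", "C", "C", "O")
  )
}

#' Build an idealized BHET-like ligand pose
#'
#' Eighteen heavy atoms with conventional names: benzene ring C1-C6, the
#' two ester carbonyl carbons C7 and C10, carbonyl/ester/hydroxyl oxygens
#' and the two hydroxyethyl arms. Bond lengths follow chemical norms
#' (1.2-1.6 Angstrom); the C7-C10 through-space span is the
#' para-dicarbonyl distance of about 5.8 Angstrom.
#'
#' @param center 3-vector, Angstrom: where to place the ligand centroid.
#' @param binding_energy optional docking energy to attach, kcal/mol.
#' @param pose_id identifier.
#' @param resno residue number of the ligand residue.
#' @param chain chain identifier.
#' @return a [ligand_pose()]-compatible `LigandPose`.
#' @export
build_bhet_ligand <- function(center = c(0, 0, 0), binding_energy = NULL,
                              pose_id = "BHT", resno = 1L, chain = "B") {
  tpl <- .bhet_template()
  xyz <- sweep(tpl$xyz, 2, center - colMeans(tpl$xyz), "+")
  atoms <- data.frame(
    serial = seq_along(tpl$name), name = tpl$name, altloc = " ",
    resname = "BHT", chain = chain, resno = as.integer(resno), inscode = "",
    element = tpl$element, occupancy = 1, bfactor = 0, is_het = TRUE,
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, xyz = xyz, binding_energy = binding_energy,
                 pose_id = pose_id),
            class = "LigandPose")
}

#' Simulate a trajectory with scheduled site occupancy
#'
#' Builds a box (protein extent plus margin) containing the toy protein,
#' `n_ligands` BHET copies and `n_waters` waters. Free molecules execute
#' seeded random walks with reflective box boundaries; during each
#' occupancy-schedule window the first `count` ligands are held inside the
#' site sphere around the catalytic Ser OG while all other ligands are
#' excluded from it, so site-occupancy counts reproduce the schedule
#' exactly. Protein atoms receive Gaussian jitter of `jitter_sigma` for
#' RMSF testing (0 = static).
#'
#' @param protein a [Structure] from [build_toy_protein()] (or compatible:
#'   single chain A with one SER carrying OG).
#' @param cfg a [generator_config()].
#' @return list with `trajectory` (a [trajectory()]), `site` (the
#'   [catalytic_site()]), and `manifest` (ground truth: schedule, seed,
#'   cutoffs).
#' @export
simulate_trajectory <- function(protein, cfg = generator_config()) {
  stopifnot(inherits(protein, "Structure"), inherits(cfg, "GeneratorConfig"))
  set.seed(cfg$seed + 1L)
  ser_resno <- unique(protein$atoms$resno[protein$atoms$resname == "SER"])[1]
  site <- catalytic_site(protein, "A", ser_resno)
  og0 <- model_coords(protein, 1)[site$og_index, ]

  lo <- apply(model_coords(protein, 1), 2, min) - cfg$box_margin
  hi <- apply(model_coords(protein, 1), 2, max) + cfg$box_margin

  times <- seq(0, cfg$duration_ns, by = cfg$frame_interval_ns)
  nf <- length(times)
  tpl <- .bhet_template()
  nlat <- nrow(tpl$xyz)
  offs <- sweep(tpl$xyz, 2, colMeans(tpl$xyz))  # centroid-relative atoms

  # assemble topology: protein + ligands (chain B) + waters (chain W)
  prot_atoms <- protein$atoms
  lig_atoms <- do.call(rbind, lapply(seq_len(cfg$n_ligands), function(i) {
    a <- build_bhet_ligand(resno = i)$atoms
    a$chain <- "B"
    a
  }))
  wat_atoms <- if (cfg$n_waters > 0) data.frame(
    serial = 0L, name = "O", altloc = " ", resname = "HOH", chain = "W",
    resno = seq_len(cfg$n_waters), inscode = "", element = "O",
    occupancy = 1, bfactor = 0, is_het = TRUE, stringsAsFactors = FALSE
  ) else NULL
  atoms <- rbind(prot_atoms, lig_atoms, wat_atoms)
  atoms$serial <- seq_len(nrow(atoms))
  np <- nrow(prot_atoms)

  rand_in_box <- function() lo + stats::runif(3) * (hi - lo)
  reflect <- function(p) {
    for (d in 1:3) {
      if (p[d] < lo[d]) p[d] <- lo[d] + (lo[d] - p[d])
      if (p[d] > hi[d]) p[d] <- hi[d] - (p[d] - hi[d])
      p[d] <- min(max(p[d], lo[d]), hi[d])
    }
    p
  }
  # minimum centroid distance along direction v so that every ligand atom
  # clears the site sphere (orientation is fixed, so the worst-case atom
  # projection toward the site is exact)
  req_dist <- function(vhat) {
    cfg$site_cutoff + 0.3 + max(0, -(offs %*% vhat))
  }
  in_box <- function(p) all(p >= lo) && all(p <= hi)
  push_out <- function(p, og) {
    p <- reflect(p)
    v <- p - og
    d <- sqrt(sum(v^2))
    vhat <- if (d < 1e-9) c(1, 0, 0) else v / d
    req <- req_dist(vhat)
    if (d >= req) return(p)
    cand <- og + vhat * req
    if (in_box(cand)) return(cand)
    # pushed through a wall: place along the ray to the farthest corner,
    # which always has room for the exclusion distance
    corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                     c(lo[3], hi[3])))
    far <- corners[which.max(rowSums(sweep(corners, 2, og)^2)), ]
    vhat <- (far - og) / sqrt(sum((far - og)^2))
    og + vhat * req_dist(vhat)
  }
  scheduled_count <- function(t) {
    for (w in cfg$occupancy_schedule) {
      if (t >= w[[1]] && t <= w[[2]]) return(w[[3]])
    }
    0L
  }

  lig_pos <- t(vapply(seq_len(cfg$n_ligands), function(i) {
    push_out(rand_in_box(), og0)
  }, numeric(3)))
  wat_pos <- if (cfg$n_waters > 0) {
    t(vapply(seq_len(cfg$n_waters), function(i) rand_in_box(), numeric(3)))
  } else matrix(numeric(0), 0, 3)

  xyz <- array(NA_real_, dim = c(nrow(atoms), 3L, nf))
  for (k in seq_len(nf)) {
    pcoord <- model_coords(protein, 1)
    if (cfg$jitter_sigma > 0) {
      pcoord <- pcoord + matrix(stats::rnorm(length(pcoord), 0,
                                             cfg$jitter_sigma),
                                ncol = 3)
    }
    og <- pcoord[site$og_index, ]
    cnt <- scheduled_count(times[k])
    if (k > 1L) {
      step <- matrix(stats::rnorm(3 * cfg$n_ligands, 0, cfg$step_sigma),
                     ncol = 3)
      lig_pos <- lig_pos + step
    }
    for (i in seq_len(cfg$n_ligands)) {
      if (i <= cnt) {
        # held in the site: centroid within 2 A of OG (jittered each frame)
        lig_pos[i, ] <- og + stats::rnorm(3, 0, 0.5)
        v <- lig_pos[i, ] - og
        d <- sqrt(sum(v^2))
        if (d > 2.0) lig_pos[i, ] <- og + v / d * 2.0
      } else {
        lig_pos[i, ] <- push_out(lig_pos[i, ], og)
      }
    }
    if (cfg$n_waters > 0 && k > 1L) {
      wat_pos <- wat_pos + matrix(stats::rnorm(3 * cfg$n_waters, 0,
                                               cfg$step_sigma), ncol = 3)
      wat_pos <- t(apply(wat_pos, 1, reflect))
    }
    frame <- matrix(NA_real_, nrow(atoms), 3)
    frame[seq_len(np), ] <- pcoord
    for (i in seq_len(cfg$n_ligands)) {
      r0 <- np + (i - 1L) * nlat
      frame[(r0 + 1L):(r0 + nlat), ] <-
        sweep(tpl$xyz, 2, lig_pos[i, ] - colMeans(tpl$xyz), "+")
    }
    if (cfg$n_waters > 0) {
      frame[(np + cfg$n_ligands * nlat + 1L):nrow(atoms), ] <- wat_pos
    }
    xyz[, , k] <- frame
  }

  s <- Structure(atoms, xyz,
                 header = sprintf("SYNTHETIC TRAJECTORY seed=%d", cfg$seed))
  lig_ids <- paste("B", seq_len(cfg$n_ligands), "", sep = "|")
  wat_ids <- if (cfg$n_waters > 0) {
    paste("W", seq_len(cfg$n_waters), "", sep = "|")
  } else character(0)
  site <- catalytic_site(s, "A", ser_resno)
  list(trajectory = trajectory(s, times, lig_ids, wat_ids),
       site = site,
       manifest = list(seed = cfg$seed,
                       schedule = cfg$occupancy_schedule,
                       site_cutoff = cfg$site_cutoff,
                       jitter_sigma = cfg$jitter_sigma,
                       n_ligands = cfg$n_ligands, n_waters = cfg$n_waters))
}

#' Simulate a factor table with a designated dominant variant
#'
#' Samples plausible docking factors for `n_variants` variants and forces
#' the first to dominate on all four: most negative binding energy, most
#' hydrogen bonds, shortest attack distance, largest cavity. Under min-max
#' scoring the dominator must score exactly 1 and rank first, which makes
#' the table a closed-loop oracle for the scoring stage.
#'
#' @param n_variants number of variants (>= 2).
#' @param cfg a [generator_config()] (the seed is used).
#' @return list with `records` (factor data.frame) and `best_id`.
#' @export
simulate_factor_table <- function(n_variants, cfg = generator_config()) {
  if (n_variants < 2L) stop("need at least 2 variants")
  set.seed(cfg$seed + 2L)
  ids <- sprintf("V%02d", seq_len(n_variants))
  rec <- data.frame(
    variant_id = ids,
    A_binding_energy = stats::runif(n_variants, -7.5, -5.0),
    B_hbond_count = sample(0:5, n_variants, replace = TRUE),
    C_attack_distance = stats::runif(n_variants, 3.5, 9.0),
    D_cavity_volume = stats::runif(n_variants, 120, 320)
  )
  rec$A_binding_energy[1] <- min(rec$A_binding_energy) - 0.8
  rec$B_hbond_count[1] <- max(rec$B_hbond_count) + 1L
  rec$C_attack_distance[1] <- min(rec$C_attack_distance) - 0.5
  rec$D_cavity_volume[1] <- max(rec$D_cavity_volume) + 30
  list(records = rec, best_id = ids[1])
}

#' Simulate a thermal-inactivation time course
#'
#' `E_t = exp(-k t)` sampled every 0.5 h by default (mirroring residual
#' activity read every 30 min), with multiplicative log-normal noise so
#' activities stay positive for log-linear fitting. `noise = 0` returns
#' exact model values.
#'
#' @param k true inactivation rate, 1/h (> 0).
#' @param noise log-normal noise sd (>= 0).
#' @param t_max last time point, h.
#' @param dt sampling interval, h.
#' @param cfg a [generator_config()] (seed).
#' @return data.frame `time_h, activity` plus attribute `k_true`.
#' @export
simulate_decay <- function(k, noise = 0, t_max = 10, dt = 0.5,
                           cfg = generator_config()) {
  if (k <= 0) stop("k must be positive")
  if (noise < 0) stop("noise level must be non-negative")
  set.seed(cfg$seed + 3L)
  times <- seq(0, t_max, by = dt)
  act <- exp(-k * times)
  if (noise > 0) act <- act * exp(stats::rnorm(length(act), 0, noise))
  out <- data.frame(time_h = times, activity = act)
  attr(out, "k_true") <- k
  out
}

#' Simulate a Michaelis-Menten initial-rate dataset
#'
#' Default substrate design spans 0.8-15 mM. `noise = 0` returns exact
#' model rates; otherwise multiplicative log-normal noise is applied.
#'
#' @param K_M true Michaelis constant, mM (> 0).
#' @param Vmax true maximal rate (> 0).
#' @param design substrate concentrations, mM.
#' @param noise log-normal noise sd (>= 0).
#' @param cfg a [generator_config()] (seed).
#' @return data.frame `substrate_mM, rate` with attributes `K_M_true`,
#'   `Vmax_true`.
#' @export
simulate_kinetics <- function(K_M, Vmax,
                              design = c(0.8, 1.5, 2.5, 4, 6, 8, 11, 15),
                              noise = 0, cfg = generator_config()) {
  if (K_M <= 0 || Vmax <= 0) stop("K_M and Vmax must be positive")
  if (noise < 0) stop("noise level must be non-negative")
  set.seed(cfg$seed + 4L)
  rate <- Vmax * design / (K_M + design)
  if (noise > 0) rate <- rate * exp(stats::rnorm(length(rate), 0, noise))
  out <- data.frame(substrate_mM = design, rate = rate)
  attr(out, "K_M_true") <- K_M
  attr(out, "Vmax_true") <- Vmax
  out
}
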