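# multi-model structure from a list of coordinate matrices over one topology
make_traj_structure <- function(atoms_df, frames, is_het = FALSE) {
  s1 <- make_structure(cbind(atoms_df, frames[[1]]), is_het = is_het)
  xyz <- array(NA_real_, dim = c(nrow(atoms_df), 3, length(frames)))
  for (k in seq_along(frames)) xyz[, , k] <- as.matrix(frames[[k]])
  Structure(s1$atoms, xyz)
}

test_that("superposition recovers rigid transforms and zero RMSD", {
  set.seed(1)
  A <- matrix(rnorm(30, sd = 5), 10, 3)
  fit <- superpose(A, A)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  shifted <- sweep(A, 2, c(5, 0, 0), "+")
  expect_equal(superpose(shifted, A)$rmsd, 0, tolerance = 1e-8)
  R <- random_rotation()
  moved <- sweep(A %*% t(R), 2, c(3, -2, 9), "+")
  fit2 <- superpose(moved, A)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit2$coords, A, tolerance = 1e-8)
  expect_error(superpose(A[1:2, ], A[1:2, ]), "3 atoms")
})

test_that("Kabsch RMSD equals the independent quaternion-method result", {
  set.seed(2)
  for (i in 1:25) {
    A <- matrix(rnorm(30, sd = 4), 10, 3)
    B <- matrix(rnorm(30, sd = 4), 10, 3)
    expect_equal(superpose(A, B)$rmsd, quaternion_rmsd(A, B),
                 tolerance = 1e-8)
  }
})

test_that("superposed RMSD agrees with bio3d's least-squares fit", {
  set.seed(3)
  A <- matrix(rnorm(60, sd = 5), 20, 3)
  B <- A + matrix(rnorm(60, sd = 0.7), 20, 3)
  got <- superpose(A, B)$rmsd
  xyz_a <- matrix(t(A), nrow = 1)
  xyz_b <- matrix(t(B), nrow = 1)
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz_b[1, ],
                                            mobile = xyz_a))
  want <- bio3d::rmsd(xyz_b[1, ], fitted)
  expect_equal(got, want, tolerance = 1e-3)  # bio3d prints at 3 decimals
})

test_that("radius of gyration follows the closed form", {
  one <- make_structure(data.frame(name = "CA", element = "C",
                                   resname = "ALA", resno = 1, chain = "A",
                                   x = 4, y = 5, z = 6))
  expect_equal(radius_of_gyration(one), 0)
  # two equal-mass atoms 2 A apart: Rg = 1
  two <- make_structure(data.frame(name = c("CA", "CA"), element = "C",
                                   resname = "ALA", resno = 1:2, chain = "A",
                                   x = c(0, 2), y = 0, z = 0))
  expect_equal(radius_of_gyration(two), 1)
  # random cloud vs direct mass-weighted formula
  set.seed(4)
  n <- 40
  el <- sample(c("C", "N", "O", "S"), n, TRUE)
  df <- data.frame(name = "X", element = el, resname = "ALA",
                   resno = seq_len(n), chain = "A",
                   x = rnorm(n, sd = 4), y = rnorm(n, sd = 4),
                   z = rnorm(n, sd = 4))
  s <- make_structure(df)
  m <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)[el]
  xyz <- as.matrix(df[, c("x", "y", "z")])
  com <- colSums(xyz * m) / sum(m)
  want <- sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(s), want)
  expect_error(radius_of_gyration(s, integer(0)), "empty")
})

test_that("RMSF is zero for a static trajectory and exact for an oscillator", {
  n <- 12
  df <- data.frame(name = "CA", element = "C", resname = "ALA",
                   resno = seq_len(n), chain = "A")
  base <- data.frame(x = cos(seq_len(n)) * 8, y = sin(seq_len(n)) * 8,
                     z = seq_len(n) * 1.5)
  static <- make_traj_structure(df, rep(list(base), 10))
  traj <- trajectory(static, seq(0, 4.5, by = 0.5))
  out <- rmsf(traj, analysis_window(0, 4.5))
  expect_equal(out$rmsf, rep(0, n))

  # residue 5 oscillates +/- 1 A along x; frames share the common frame,
  # so the closed form rmsf = 1 applies without refitting
  frames <- lapply(1:10, function(k) {
    fr <- base
    fr$x[5] <- fr$x[5] + ifelse(k %% 2 == 0, 1, -1)
    fr
  })
  osc <- trajectory(make_traj_structure(df, frames), seq(0, 4.5, by = 0.5))
  out2 <- rmsf(osc, analysis_window(0, 4.5), fit = FALSE)
  expect_equal(out2$rmsf[5], 1.0)
  expect_equal(out2$rmsf[-5], rep(0, n - 1))

  expect_error(rmsf(traj, analysis_window(0, 0.4)), "fewer than 2")
})

test_that("RMSF matches the brute-force per-residue computation on a random walk", {
  set.seed(5)
  n <- 8; nf <- 20
  df <- data.frame(name = "CA", element = "C", resname = "ALA",
                   resno = seq_len(n), chain = "A")
  base <- matrix(rnorm(n * 3, sd = 6), n, 3)
  frames <- list(); cur <- base
  for (k in 1:nf) {
    cur <- cur + matrix(rnorm(n * 3, sd = 0.3), n, 3)
    frames[[k]] <- as.data.frame(cur)
  }
  for (k in 1:nf) names(frames[[k]]) <- c("x", "y", "z")
  traj <- trajectory(make_traj_structure(df, frames),
                     seq(0, by = 0.5, length.out = nf))
  got <- rmsf(traj, analysis_window(0, 100), fit = FALSE)
  arr <- simplify2array(lapply(frames, as.matrix))
  for (i in seq_len(n)) {
    mu <- rowMeans(arr[i, , ])
    want <- sqrt(mean(colSums((arr[i, , ] - mu)^2)))
    expect_equal(got$rmsf[i], want)
  }
})

test_that("SASA of an isolated atom matches the analytic sphere within 2%", {
  o <- make_structure(data.frame(name = "O", element = "O", resname = "HOH",
                                 resno = 1, chain = "W", x = 0, y = 0, z = 0),
                      is_het = TRUE)
  got <- sasa(o)$total
  want <- 4 * pi * (1.52 + 1.4)^2
  expect_lt(abs(got - want) / want, 0.02)
  expect_error(sasa(o, n_points = 8), "at least 16")
})

test_that("coincident atoms count once and buried atoms approach zero SASA", {
  dup <- make_structure(data.frame(name = c("O", "O"), element = "O",
                                   resname = "HOH", resno = 1:2, chain = "W",
                                   x = 0, y = 0, z = 0), is_het = TRUE)
  one <- make_structure(data.frame(name = "O", element = "O", resname = "HOH",
                                   resno = 1, chain = "W", x = 0, y = 0,
                                   z = 0), is_het = TRUE)
  expect_equal(sasa(dup)$total, sasa(one)$total)

  shell <- sphere_shell(60, 2.5)
  df <- data.frame(name = "C", element = "C", resname = "ALA",
                   resno = seq_len(61), chain = "A",
                   x = c(0, shell[, 1]), y = c(0, shell[, 2]),
                   z = c(0, shell[, 3]))
  s <- make_structure(df)
  per_atom <- sasa(s)$per_atom
  expect_equal(per_atom[1], 0)
})

test_that("SASA quadrature error decreases with the point count", {
  o <- make_structure(data.frame(name = "O", element = "O", resname = "HOH",
                                 resno = 1, chain = "W", x = c(0, 2.2),
                                 y = 0, z = 0)[c(1, 1), ], is_het = TRUE)
  o$atoms$resno <- 1:2
  o$xyz[2, 1, 1] <- 2.2
  want <- NULL
  errs <- vapply(c(60, 240, 960), function(np) {
    sasa(o, n_points = np)$total
  }, numeric(1))
  # two overlapping spheres: analytic union area
  r <- 1.52 + 1.4; d <- 2.2
  cap_h <- r - d / 2
  analytic <- 2 * (4 * pi * r^2 - 2 * pi * r * cap_h)
  rel <- abs(errs - analytic) / analytic
  expect_lt(rel[3], 0.02)
  expect_lt(rel[3], rel[1] + 1e-9)
})

test_that("site occupancy counts reproduce constructed fixtures", {
  # protein with Ser OG at origin; one ligand parked 3 A away in all frames
  prot_df <- data.frame(name = c("CA", "OG"), element = c("C", "O"),
                        resname = "SER", resno = 1, chain = "A")
  lig_df <- data.frame(name = c("C7", "C10"), element = "C",
                       resname = "BHT", resno = 1, chain = "B")
  atoms <- rbind(cbind(prot_df, is_het = FALSE),
                 cbind(lig_df, is_het = TRUE))
  nf <- 8
  near <- lapply(1:nf, function(k) {
    data.frame(x = c(-1, 0, 3, 4.5), y = 0, z = 0)
  })
  mk <- function(frames) {
    s1 <- Structure(data.frame(serial = 1:4, name = atoms$name, altloc = " ",
                               resname = atoms$resname, chain = atoms$chain,
                               resno = atoms$resno, inscode = "",
                               element = atoms$element, occupancy = 1,
                               bfactor = 0, is_het = atoms$is_het),
                    array(unlist(lapply(frames, as.matrix)),
                          dim = c(4, 3, length(frames))))
    trajectory(s1, seq(0, by = 0.5, length.out = length(frames)),
               ligand_ids = "B|1|")
  }
  traj <- mk(near)
  site <- catalytic_site(traj$structure, "A", 1)
  occ <- site_occupancy(traj, analysis_window(0, 10), site, "ligand")
  expect_equal(occ$counts, rep(1L, nf))
  expect_equal(occ$mean, 1)

  far <- lapply(1:nf, function(k) data.frame(x = c(-1, 0, 25, 27), y = 0, z = 0))
  occ0 <- site_occupancy(mk(far), analysis_window(0, 10), site, "ligand")
  expect_equal(occ0$counts, rep(0L, nf))
  expect_error(site_occupancy(traj, analysis_window(0, 10), site, "water"),
               "no water")
})

test_that("scheduled occupancy and per-bin means match the generator ground truth", {
  cfg <- generator_config(seed = 13, n_residues = 24, n_ligands = 4,
                          n_waters = 5, duration_ns = 20,
                          frame_interval_ns = 0.5,
                          occupancy_schedule = list(list(0, 10, 0),
                                                    list(10.5, 20, 2)))
  sim <- simulate_trajectory(build_toy_protein(cfg), cfg)
  occ <- site_occupancy(sim$trajectory, analysis_window(0, 10), sim$site,
                        "ligand", cutoff = cfg$site_cutoff)
  expect_equal(occ$counts, rep(0L, length(occ$counts)))
  occ2 <- site_occupancy(sim$trajectory, analysis_window(10.5, 20), sim$site,
                         "ligand", cutoff = cfg$site_cutoff)
  expect_equal(occ2$counts, rep(2L, length(occ2$counts)))
  # counts never exceed the molecule count
  occ_all <- site_occupancy(sim$trajectory, analysis_window(0, 20), sim$site,
                            "ligand", cutoff = cfg$site_cutoff, bin_ns = 10)
  expect_true(all(occ_all$counts <= cfg$n_ligands))
  expect_equal(occ_all$bins$mean_count[1], 0)
  expect_gt(occ_all$bins$mean_count[2], 1.8)
})

test_that("distance series follow parked, approaching and random fixtures", {
  cfg <- generator_config(seed = 17, n_residues = 24, n_ligands = 2,
                          n_waters = 0, duration_ns = 5,
                          frame_interval_ns = 0.5, jitter_sigma = 0,
                          occupancy_schedule = list(list(0, 5, 1)))
  sim <- simulate_trajectory(build_toy_protein(cfg), cfg)
  ds <- distance_series(sim$trajectory, sim$site, "B|1|")
  expect_equal(nrow(ds), 11L)
  expect_true(all(is.finite(ds$d_C7)) && all(is.finite(ds$d_C10)))
  # direct per-frame recomputation
  s <- sim$trajectory$structure
  key <- paste(s$atoms$chain, s$atoms$resno, s$atoms$inscode, sep = "|")
  i7 <- which(key == "B|1|" & s$atoms$name == "C7")
  og_i <- sim$site$og_index
  for (k in c(1, 5, 11)) {
    xyz <- model_coords(s, k)
    expect_equal(ds$d_C7[k], sqrt(sum((xyz[i7, ] - xyz[og_i, ])^2)))
  }

  # linearly approaching ligand: strictly decreasing distances
  prot <- data.frame(name = c("CA", "OG"), element = c("C", "O"),
                     resname = "SER", resno = 1, chain = "A")
  lig <- data.frame(name = c("C7", "C10"), element = "C", resname = "BHT",
                    resno = 1, chain = "B")
  frames <- lapply(0:9, function(k) {
    data.frame(x = c(-1, 0, 20 - k, 22 - k), y = 0, z = 0)
  })
  atoms_df <- rbind(prot, lig)
  s2 <- make_traj_structure(atoms_df, frames,
                            is_het = c(FALSE, FALSE, TRUE, TRUE))
  tr <- trajectory(s2, seq(0, by = 1, length.out = 10), ligand_ids = "B|1|")
  site2 <- catalytic_site(s2, "A", 1)
  ds2 <- distance_series(tr, site2, "B|1|")
  expect_true(all(diff(ds2$d_C7) < 0))
  expect_error(distance_series(tr, site2, "B|9|"), "C7")
})

test_that("spatial distribution grids report per-voxel occupancy fractions", {
  prot <- data.frame(name = c("CA", "OG"), element = c("C", "O"),
                     resname = "SER", resno = 1, chain = "A")
  lig <- data.frame(name = "C7", element = "C", resname = "BHT",
                    resno = 1, chain = "B")
  # ligand parked in one voxel for all frames
  frames <- lapply(1:6, function(k) {
    data.frame(x = c(-1, 0, 5.2), y = c(0, 0, 3.1), z = c(0, 0, 0.4))
  })
  s <- make_traj_structure(rbind(prot, lig), frames,
                           is_het = c(FALSE, FALSE, TRUE))
  tr <- trajectory(s, seq(0, by = 0.5, length.out = 6), ligand_ids = "B|1|")
  g <- spatial_distribution(tr, analysis_window(0, 10), "ligand",
                            superpose_frames = FALSE)
  expect_equal(max(g$fraction), 1)
  expect_equal(sum(g$fraction == 1), 1)
  expect_true(all(g$fraction %in% c(0, 1)))

  # two-state hopping: half the frames in each of two voxels
  hop <- lapply(1:6, function(k) {
    x <- if (k %% 2 == 0) 5.2 else -4.8
    data.frame(x = c(-1, 0, x), y = c(0, 0, 3.1), z = 0)
  })
  s2 <- make_traj_structure(rbind(prot, lig), hop,
                            is_het = c(FALSE, FALSE, TRUE))
  tr2 <- trajectory(s2, seq(0, by = 0.5, length.out = 6), ligand_ids = "B|1|")
  g2 <- spatial_distribution(tr2, analysis_window(0, 10), "ligand",
                             superpose_frames = FALSE)
  expect_equal(sort(g2$fraction[g2$fraction > 0]), c(0.5, 0.5))

  # absent species: all-zero grid
  g3 <- spatial_distribution(tr2, analysis_window(0, 10), "water",
                             superpose_frames = FALSE)
  expect_true(all(g3$fraction == 0))

  f <- withr::local_tempfile(fileext = ".cube")
  write_cube(g2, f)
  expect_gt(file.size(f), 0)
})
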