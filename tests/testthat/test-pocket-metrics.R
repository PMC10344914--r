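# a one-residue protein with a backbone N at a chosen spot, plus a
# single-oxygen "ligand" — the minimal hydrogen-bond geometry fixture
hbond_fixture <- function(n_pos, o_pos) {
  prot <- make_structure(data.frame(
    name = c("N", "CA"), element = c("N", "C"), resname = "ALA",
    resno = 1, chain = "A",
    x = c(n_pos[1], n_pos[1] + 3), y = c(n_pos[2], n_pos[2]),
    z = c(n_pos[3], n_pos[3])))
  ligs <- make_structure(data.frame(
    name = "O1", element = "O", resname = "BHT", resno = 1, chain = "B",
    x = o_pos[1], y = o_pos[2], z = o_pos[3]), is_het = TRUE)
  list(protein = prot, ligand = ligand_pose(ligs, "BHT"))
}

test_that("hydrogen bonds respect the donor-acceptor distance criterion", {
  fx <- hbond_fixture(c(0, 0, 0), c(2.9, 0, 0))
  expect_equal(count_hbonds(fx$protein, fx$ligand), 1L)
  fx2 <- hbond_fixture(c(0, 0, 0), c(4.0, 0, 0))
  expect_equal(count_hbonds(fx2$protein, fx2$ligand), 0L)
  # apolar ligand warns and returns 0
  apolar <- make_structure(data.frame(
    name = "C1", element = "C", resname = "BHT", resno = 1, chain = "B",
    x = 2.9, y = 0, z = 0), is_het = TRUE)
  expect_warning(n <- count_hbonds(fx$protein, ligand_pose(apolar, "BHT")),
                 "polar")
  expect_equal(n, 0L)
})

test_that("hydrogen-bond counting equals the brute-force pairwise oracle", {
  set.seed(99)
  for (rep in 1:100) {
    np <- sample(5:20, 1)
    nl <- sample(2:8, 1)
    prot <- make_structure(data.frame(
      name = "N", element = sample(c("N", "O", "C"), np, replace = TRUE),
      resname = "ALA", resno = seq_len(np), chain = "A",
      x = runif(np, 0, 12), y = runif(np, 0, 12), z = runif(np, 0, 12)))
    ligs <- make_structure(data.frame(
      name = paste0("O", seq_len(nl)),
      element = sample(c("O", "C"), nl, replace = TRUE),
      resname = "BHT", resno = 1, chain = "B",
      x = runif(nl, 0, 12), y = runif(nl, 0, 12), z = runif(nl, 0, 12)),
      is_het = TRUE)
    lig <- ligand_pose(ligs, "BHT")
    # independent O(N*M) scan
    want <- 0L
    pxyz <- model_coords(prot, 1)
    for (i in seq_len(np)) {
      if (!prot$atoms$element[i] %in% c("N", "O")) next
      for (j in seq_len(nl)) {
        if (!lig$atoms$element[j] %in% c("N", "O")) next
        if (sqrt(sum((pxyz[i, ] - lig$xyz[j, ])^2)) <= 3.5) want <- want + 1L
      }
    }
    got <- if (any(lig$atoms$element %in% c("N", "O"))) {
      count_hbonds(prot, lig)
    } else {
      suppressWarnings(count_hbonds(prot, lig))
    }
    expect_equal(got, want)
  }
})

test_that("explicit donor hydrogens enforce the D-H...A angle threshold", {
  # donor N with H pointing at the acceptor: linear, angle 180 -> counted
  prot <- make_structure(data.frame(
    name = c("N", "H"), element = c("N", "H"), resname = "ALA", resno = 1,
    chain = "A", x = c(0, 1.0), y = 0, z = 0))
  lig <- ligand_pose(make_structure(data.frame(
    name = "O1", element = "O", resname = "BHT", resno = 1, chain = "B",
    x = 2.9, y = 0, z = 0), is_het = TRUE), "BHT")
  expect_equal(count_hbonds(prot, lig), 1L)
  # H pointing away: D-H...A angle ~0 -> rejected
  prot2 <- make_structure(data.frame(
    name = c("N", "H"), element = c("N", "H"), resname = "ALA", resno = 1,
    chain = "A", x = c(0, -1.0), y = 0, z = 0))
  expect_equal(count_hbonds(prot2, lig), 0L)
})

test_that("attack distance measures OG to the named carbonyl carbons", {
  prot <- make_structure(data.frame(
    name = c("CA", "OG"), element = c("C", "O"), resname = "SER",
    resno = 7, chain = "A", x = c(-1, 0), y = 0, z = 0))
  site <- catalytic_site(prot, "A", 7)
  lig_s <- make_structure(data.frame(
    name = c("C7", "C10"), element = "C", resname = "BHT", resno = 1,
    chain = "B", x = 0, y = 0, z = c(3.2, 5.0)), is_het = TRUE)
  lig <- ligand_pose(lig_s, "BHT")
  expect_equal(attack_distance(prot, lig, site), 3.2)
  expect_equal(attack_distance(prot, lig, site, "both"),
               c(C7 = 3.2, C10 = 5.0))
  # coincident OG and C7
  lig0 <- ligand_pose(make_structure(data.frame(
    name = c("C7", "C10"), element = "C", resname = "BHT", resno = 1,
    chain = "B", x = 0, y = 0, z = c(0, 5)), is_het = TRUE), "BHT")
  expect_equal(attack_distance(prot, lig0, site), 0)
  # missing atoms are named in the error
  bad <- ligand_pose(make_structure(data.frame(
    name = "C7", element = "C", resname = "BHT", resno = 1, chain = "B",
    x = 0, y = 0, z = 3), is_het = TRUE), "BHT")
  expect_error(attack_distance(prot, bad, site), "C10")
})

test_that("random poses give hand-computed Euclidean attack distances", {
  set.seed(12)
  prot <- make_structure(data.frame(
    name = c("CA", "OG"), element = c("C", "O"), resname = "SER",
    resno = 1, chain = "A", x = c(-1, 0.3), y = c(0, -0.2), z = c(0, 0.9)))
  site <- catalytic_site(prot, "A", 1)
  og <- model_coords(prot, 1)[site$og_index, ]
  for (i in 1:20) {
    p7 <- rnorm(3, sd = 4); p10 <- rnorm(3, sd = 4)
    lig <- ligand_pose(make_structure(data.frame(
      name = c("C7", "C10"), element = "C", resname = "BHT", resno = 1,
      chain = "B", x = c(p7[1], p10[1]), y = c(p7[2], p10[2]),
      z = c(p7[3], p10[3])), is_het = TRUE), "BHT")
    both <- attack_distance(prot, lig, site, "both")
    expect_equal(unname(both["C7"]), sqrt(sum((p7 - og)^2)))
    expect_equal(unname(both["C10"]), sqrt(sum((p10 - og)^2)))
  }
})

test_that("hollow-sphere cavity volume approaches the analytic ball volume", {
  # shell tight enough that the large probe cannot leak inside; the
  # small-probe-accessible interior is a ball of radius 4
  shell <- sphere_shell(2500, 7.1)
  vol <- barriereng:::.grid_cavity(shell, rep(1.7, 2500),
                                   cavity_grid(spacing = 0.6,
                                               probe_out = 2.0))
  true <- 4 / 3 * pi * 4^3
  expect_lt(abs(vol - true) / true, 0.10)
})

test_that("grid error shrinks monotonically with spacing on the sphere fixture", {
  shell <- sphere_shell(2500, 7.1)
  true <- 4 / 3 * pi * 4^3
  errs <- vapply(c(1.0, 0.6, 0.3), function(sp) {
    v <- barriereng:::.grid_cavity(shell, rep(1.7, 2500),
                                   cavity_grid(spacing = sp,
                                               probe_in = max(sp, 1.4),
                                               probe_out = 2.0))
    abs(v - true) / true
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # halving the spacing changes the estimate by under 5%
  v06 <- barriereng:::.grid_cavity(shell, rep(1.7, 2500),
                                   cavity_grid(spacing = 0.6, probe_out = 2.0))
  v03 <- barriereng:::.grid_cavity(shell, rep(1.7, 2500),
                                   cavity_grid(spacing = 0.3, probe_out = 2.0))
  expect_lt(abs(v06 - v03) / v03, 0.05)
})

test_that("a solid close-packed block has no cavity and probe_in is monotone", {
  block <- as.matrix(expand.grid(x = seq(0, 6, 1.5), y = seq(0, 6, 1.5),
                                 z = seq(0, 6, 1.5)))
  expect_equal(barriereng:::.grid_cavity(block, rep(1.7, nrow(block)),
                                         cavity_grid()), 0)
  shell <- sphere_shell(800, 7.1)
  v_small <- barriereng:::.grid_cavity(shell, rep(1.7, 800),
                                       cavity_grid(probe_in = 1.2))
  v_large <- barriereng:::.grid_cavity(shell, rep(1.7, 800),
                                       cavity_grid(probe_in = 1.6))
  expect_gte(v_small, v_large)
})

test_that("cavity_volume runs on a protein-ligand complex and flags empty shells", {
  p <- build_toy_protein(generator_config(seed = 1))
  site <- catalytic_site(p, "A", unique(p$atoms$resno[p$atoms$resname == "SER"]))
  og <- model_coords(p, 1)[site$og_index, ]
  lig <- build_bhet_ligand(center = og)
  v <- cavity_volume(p, lig, cavity_grid(spacing = 1.0, probe_in = 1.4))
  expect_gte(v, 0)
  far <- build_bhet_ligand(center = og + 500)
  expect_warning(v0 <- cavity_volume(p, far), "no protein residues")
  expect_equal(v0, 0)
  expect_error(cavity_grid(spacing = 2.0, probe_in = 1.4), "spacing")
})

test_that("geometric factors are invariant under a joint rigid transform", {
  p <- build_toy_protein(generator_config(seed = 21))
  ser <- unique(p$atoms$resno[p$atoms$resname == "SER"])
  site <- catalytic_site(p, "A", ser)
  og <- model_coords(p, 1)[site$og_index, ]
  lig <- build_bhet_ligand(center = og + c(2, 0.5, -1))

  set.seed(77)
  R <- random_rotation(); tr <- c(13, -7, 2)
  p2 <- transform_structure(p, R, tr)
  lig2 <- lig
  lig2$xyz <- sweep(lig$xyz %*% t(R), 2, tr, "+")
  site2 <- catalytic_site(p2, "A", ser)

  expect_equal(attack_distance(p2, lig2, site2, "both"),
               attack_distance(p, lig, site, "both"), tolerance = 1e-6)
  expect_equal(count_hbonds(p2, lig2), count_hbonds(p, lig))

  g <- cavity_grid(spacing = 1.0, probe_in = 1.4)
  v1 <- cavity_volume(p, lig, g)
  # pure translation keeps the grid anchored to the atoms: exact equality
  p3 <- transform_structure(p, diag(3), tr)
  lig3 <- lig; lig3$xyz <- sweep(lig$xyz, 2, tr, "+")
  expect_equal(cavity_volume(p3, lig3, g), v1)
  # rotation re-discretizes; agreement within a few percent of the volume
  v2 <- cavity_volume(p2, lig2, g)
  expect_lt(abs(v2 - v1), max(0.05 * v1, 5 * g$spacing^3))
})

test_that("assemble_factors composes computed factors with ingested energies", {
  p <- build_toy_protein(generator_config(seed = 1))
  ser <- unique(p$atoms$resno[p$atoms$resname == "SER"])
  site <- catalytic_site(p, "A", ser)
  og <- model_coords(p, 1)[site$og_index, ]
  lig <- build_bhet_ligand(center = og + c(2, 0, 0))
  tab <- data.frame(variant_id = c("wt", "d5"),
                    binding_energy_kcal_mol = c(-6.1, -7.2))
  rec <- assemble_factors("d5", p, lig, site, tab,
                          grid = cavity_grid(spacing = 1.0))
  expect_equal(rec$A_binding_energy, -7.2)
  expect_equal(rec$C_attack_distance,
               attack_distance(p, lig, site))
  expect_gte(rec$B_hbond_count, 0)
  expect_gte(rec$D_cavity_volume, 0)

  expect_error(assemble_factors("nope", p, lig, site, tab), "available")
  dup <- rbind(tab, tab[1, ])
  expect_error(assemble_factors("d5", p, lig, site, dup), "duplicate")
})

test_that("binding-energy tables are read and schema-checked", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("variant_id,binding_energy_kcal_mol", "v1,-7.2", "v2,-6.0"), f)
  tab <- read_binding_energies(f)
  expect_equal(tab$binding_energy_kcal_mol, c(-7.2, -6.0))
  writeLines(c("id,energy", "v1,-7.2"), f)
  expect_error(read_binding_energies(f), "columns")
})
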