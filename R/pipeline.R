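#' Default pipeline configuration
#'
#' Single nested document holding every parameter any stage consumes, so a
#' run is reproducible from its config alone. Stages: `simulate` (toy
#' system + synthetic factor table), `design` (truncation variants),
#' `score` (weighted min-max scoring), `traj` (occupancy and distance
#' observables), `assay` (decay and kinetics fits). Unknown keys are
#' rejected by [validate_config()].
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "barriereng-run",
    simulate = list(
      n_residues = 60L, n_ligands = 30L, n_waters = 120L,
      frame_interval_ns = 0.5, duration_ns = 20,
      occupancy_schedule = list(list(10, 20, 1)),
      jitter_sigma = 0.15, n_variants = 5L
    ),
    design = list(
      linker = "GG",
      region_length = 6L
    ),
    score = list(
      weights = c(0.10, 0.30, 0.40, 0.20),
      top_k = 1L
    ),
    traj = list(
      enabled = TRUE,
      site_cutoff = 6.0,
      window = c(10, 20),
      bin_ns = 5
    ),
    assay = list(
      enabled = TRUE,
      decay_k = 0.0181311, decay_noise = 0,
      K_M = 1.0, Vmax = 10.0, kinetics_noise = 0
    )
  )
}

# recursively compare keys of cfg against the reference schema
.unknown_keys <- function(cfg, ref, prefix = "") {
  bad <- character(0)
  if (!is.list(cfg) || is.null(names(cfg))) return(bad)
  for (k in names(cfg)) {
    path <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (!k %in% names(ref)) {
      bad <- c(bad, path)
    } else if (is.list(cfg[[k]]) && is.list(ref[[k]]) &&
                 !is.null(names(ref[[k]]))) {
      bad <- c(bad, .unknown_keys(cfg[[k]], ref[[k]], path))
    }
  }
  bad
}

#' Validate a pipeline configuration
#'
#' Checks a config document (path to YAML, or a list) against the schema
#' of [default_config()]: unknown keys anywhere are errors, scoring
#' weights must sum to 1, cutoffs and windows must be positive and
#' ordered.
#'
#' @param config path to a YAML file, or a named list.
#' @return data.frame of diagnostics (`path`, `message`); zero rows means
#'   the config is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  diags <- data.frame(path = character(), message = character())
  note <- function(path, msg) {
    rbind(diags, data.frame(path = path, message = msg))
  }
  for (p in .unknown_keys(config, default_config())) {
    diags <- note(p, "unknown key")
  }
  w <- config$score$weights
  if (!is.null(w)) {
    if (length(w) != 4 || abs(sum(w) - 1) > 1e-9) {
      diags <- note("score.weights", "four weights summing to 1 required")
    }
    if (any(w < 0 | w > 1)) {
      diags <- note("score.weights", "weights must lie in [0, 1]")
    }
  }
  if (!is.null(config$traj$site_cutoff) && config$traj$site_cutoff <= 0) {
    diags <- note("traj.site_cutoff", "cutoff must be positive")
  }
  win <- config$traj$window
  if (!is.null(win) && (length(win) != 2 || win[1] < 0 || win[1] >= win[2])) {
    diags <- note("traj.window", "window must be 0 <= start < end")
  }
  if (!is.null(config$assay$decay_k) && config$assay$decay_k <= 0) {
    diags <- note("assay.decay_k", "decay rate must be positive")
  }
  diags
}

# fill unset keys from defaults, recursively
.merge_config <- function(cfg, ref) {
  for (k in names(ref)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- ref[[k]]
    } else if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      cfg[[k]] <- .merge_config(cfg[[k]], ref[[k]])
    }
  }
  cfg
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the stages in dependency order: simulate the toy system and a
#' synthetic factor table with a designated dominant variant; design one
#' truncation variant per synthetic barrier region; score the factor
#' table; optionally compute trajectory observables and assay fits. All
#' outputs are CSV files under the run directory; the returned manifest
#' records the effective config, input/output checksums and per-stage
#' timings, so identical seeded runs are byte-identical.
#'
#' @param config path to YAML, or named list (missing keys filled from
#'   [default_config()]).
#' @return list of class `RunManifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  diags <- validate_config(config)
  if (nrow(diags) > 0) {
    stop("invalid config:\n",
         paste(sprintf("  %s: %s", diags$path, diags$message),
               collapse = "\n"))
  }
  cfg <- .merge_config(config, default_config())
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "barriereng",
                   version = as.character(utils::packageVersion("barriereng")),
                   stages = list(), outputs = list())
  tmp <- tempfile(fileext = ".json")
  # the hash covers parameters, not the output location
  jsonlite::write_json(cfg[setdiff(names(cfg), "output_dir")], tmp,
                       auto_unbox = TRUE, digits = NA)
  manifest$config_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  stamp <- function(name, t0, files) {
    manifest$stages[[name]] <<- list(seconds = round(as.numeric(
      Sys.time() - t0, units = "secs"), 3))
    for (f in files) manifest$outputs[[basename(f)]] <- unname(tools::md5sum(f))
  }

  # -- simulate ------------------------------------------------------------
  t0 <- Sys.time()
  gcfg <- generator_config(
    seed = cfg$seed, n_residues = cfg$simulate$n_residues,
    n_ligands = cfg$simulate$n_ligands, n_waters = cfg$simulate$n_waters,
    frame_interval_ns = cfg$simulate$frame_interval_ns,
    duration_ns = cfg$simulate$duration_ns,
    occupancy_schedule = cfg$simulate$occupancy_schedule,
    jitter_sigma = cfg$simulate$jitter_sigma,
    site_cutoff = cfg$traj$site_cutoff)
  protein <- build_toy_protein(gcfg)
  sim <- simulate_trajectory(protein, gcfg)
  fac <- simulate_factor_table(cfg$simulate$n_variants, gcfg)
  pdb_path <- file.path(cfg$output_dir, "toy_protein.pdb")
  write_structure(protein, pdb_path)
  stamp("simulate", t0, pdb_path)

  # -- design --------------------------------------------------------------
  t0 <- Sys.time()
  seqinfo <- extract_sequence(protein, "A")
  n <- nchar(seqinfo$sequence)
  len <- cfg$design$region_length
  nv <- cfg$simulate$n_variants
  starts <- round(seq(5, n - len - 5, length.out = nv))
  regions <- lapply(seq_len(nv), function(i) {
    barrier_region(paste0("D", i), starts[i], starts[i] + len - 1L)
  })
  variants <- batch_design(seqinfo$sequence, regions,
                           linker = cfg$design$linker,
                           numbering = seqinfo$numbering,
                           parent_id = "toy")
  fasta_path <- file.path(cfg$output_dir, "variants.fasta")
  write_variants(variants, fasta_path)
  stamp("design", t0, fasta_path)

  # -- score ---------------------------------------------------------------
  t0 <- Sys.time()
  rec <- fac$records
  vids <- vapply(variants, function(v) v$variant_id, character(1))
  best_row <- match(fac$best_id, rec$variant_id)
  rec$variant_id <- vids
  best_id <- vids[best_row]
  w <- cfg$score$weights
  tab <- score_variants(rec, scoring_weights(w[1], w[2], w[3], w[4]))
  score_path <- file.path(cfg$output_dir, "scores.csv")
  utils::write.csv(tab, score_path, row.names = FALSE)
  top <- rank_variants(tab, cfg$score$top_k)
  stamp("score", t0, score_path)

  # -- traj ----------------------------------------------------------------
  occ_path <- NULL
  if (isTRUE(cfg$traj$enabled)) {
    t0 <- Sys.time()
    win <- analysis_window(cfg$traj$window[1], cfg$traj$window[2])
    occ <- site_occupancy(sim$trajectory, win, sim$site, "ligand",
                          cutoff = cfg$traj$site_cutoff,
                          bin_ns = cfg$traj$bin_ns)
    occ_path <- file.path(cfg$output_dir, "site_occupancy.csv")
    utils::write.csv(data.frame(time_ns = occ$times, count = occ$counts),
                     occ_path, row.names = FALSE)
    stamp("traj", t0, occ_path)
  }

  # -- assay ---------------------------------------------------------------
  assay_path <- NULL
  if (isTRUE(cfg$assay$enabled)) {
    t0 <- Sys.time()
    dec <- simulate_decay(cfg$assay$decay_k, cfg$assay$decay_noise,
                          cfg = gcfg)
    dfit <- fit_inactivation(dec$time_h, dec$activity)
    kin <- simulate_kinetics(cfg$assay$K_M, cfg$assay$Vmax,
                             noise = cfg$assay$kinetics_noise, cfg = gcfg)
    kfit <- fit_michaelis_menten(kin$substrate_mM, kin$rate)
    assay_path <- file.path(cfg$output_dir, "assay_fits.csv")
    utils::write.csv(data.frame(
      quantity = c("inactivation_k_per_h", "half_life_h", "K_M_mM", "Vmax"),
      value = c(dfit$k, dfit$t_half, kfit$K_M, kfit$Vmax)),
      assay_path, row.names = FALSE)
    stamp("assay", t0, assay_path)
  }

  manifest$top_variant <- top[1]
  manifest$designated_best <- best_id
  manifest$score_table <- tab
  structure(manifest, class = "RunManifest")
}

#' @export
print.RunManifest <- function(x, ...) {
  cat("barriereng run", x$version, "\n")
  cat("  top-ranked variant:", x$top_variant, "\n")
  cat("  stages:", paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}
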