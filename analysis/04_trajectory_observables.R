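#!/usr/bin/env Rscript
# Stage 4 - trajectory observables used for barrier identification and
# variant verification: per-residue RMSF over the late analysis window,
# substrate/water occupancy of the binding site, Ser OG - carbonyl carbon
# distance series, and the spatial occupancy grid of the substrate.
# Reads the stage-1 outputs.

suppressPackageStartupMessages(library(barriereng))

out <- "results/analysis"
traj_pdb <- file.path(out, "trajectory.pdb")
if (!file.exists(traj_pdb)) {
  stop("run analysis/01_simulate_system.R first")
}
gt <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                          simplifyVector = TRUE)

s <- read_structure(traj_pdb)
lig_ids <- unique(paste(s$atoms$chain, s$atoms$resno, s$atoms$inscode,
                        sep = "|")[s$atoms$resname == "BHT"])
wat_ids <- unique(paste(s$atoms$chain, s$atoms$resno, s$atoms$inscode,
                        sep = "|")[s$atoms$resname == "HOH"])
times <- seq(0, by = 0.5, length.out = n_models(s))
traj <- trajectory(s, times, lig_ids, wat_ids)
ser <- unique(s$atoms$resno[s$atoms$resname == "SER"])
site <- catalytic_site(s, "A", ser)

# late-window flexibility profile (the analysis window of the study is the
# last 40% of the run)
win <- analysis_window(max(times) * 0.6, max(times))
flex <- rmsf(traj, win)
write.csv(flex, file.path(out, "rmsf.csv"), row.names = FALSE)
cat(sprintf("RMSF over %.1f-%.1f ns: mean %.2f A, max %.2f A at residue %d\n",
            win$start_ns, win$end_ns, mean(flex$rmsf), max(flex$rmsf),
            flex$resno[which.max(flex$rmsf)]))

# site occupancy for both species, 5-ns bins
for (sp in c("ligand", "water")) {
  occ <- site_occupancy(traj, analysis_window(0, max(times)), site, sp,
                        cutoff = gt$site_cutoff, bin_ns = 5)
  write.csv(data.frame(time_ns = occ$times, count = occ$counts),
            file.path(out, paste0("occupancy_", sp, ".csv")),
            row.names = FALSE)
  cat(sprintf("%s occupancy: mean %.2f; per-5ns bins: %s\n", sp, occ$mean,
              paste(sprintf("%.2f", occ$bins$mean_count), collapse = " ")))
}

# distance series for the first substrate copy (held in the site during
# the scheduled window, so the curves drop and flatten there)
ds <- distance_series(traj, site, lig_ids[1])
write.csv(ds, file.path(out, "distance_series.csv"), row.names = FALSE)
late <- ds$time_ns > max(times) / 2
cat(sprintf("OG-C7 distance: %.1f A (mean first half) -> %.1f A (mean second half)\n",
            mean(ds$d_C7[!late]), mean(ds$d_C7[late])))

# spatial occupancy grid of the substrate over the scheduled window
g <- spatial_distribution(traj, analysis_window(max(times) / 2, max(times)),
                          "ligand", spacing = 1.0)
write_cube(g, file.path(out, "bhet_occupancy.cube"))
cat(sprintf("substrate occupancy grid: peak voxel fraction %.2f; %d voxels occupied in >25%% of frames\n",
            max(g$fraction), sum(g$fraction > 0.25)))
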