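#!/usr/bin/env Rscript
# Stage 3 - compute the four docking factors on a synthetic complex and
# rank variants with the weighted min-max score (10% binding energy, 30%
# hydrogen bonds, 40% serine attack distance, 20% cavity volume). Binding
# energies are ingested, never computed; here a synthetic factor table
# with a planted dominant variant provides the closed-loop check that the
# scoring recovers the known best.

suppressPackageStartupMessages(library(barriereng))

out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- generator_config(seed = 1)

# (a) geometric factors on an explicit complex: toy protein + BHET pose
protein <- build_toy_protein(cfg)
ser <- unique(protein$atoms$resno[protein$atoms$resname == "SER"])
site <- catalytic_site(protein, "A", ser)
og <- model_coords(protein, 1)[site$og_index, ]
lig <- build_bhet_ligand(center = og + c(2, 0.5, -0.5))
energies <- data.frame(variant_id = "toy-complex",
                       binding_energy_kcal_mol = -7.2)
rec <- assemble_factors("toy-complex", protein, lig, site, energies,
                        grid = cavity_grid(spacing = 0.6))
cat("toy complex factors:\n")
cat(sprintf("  binding energy (ingested): %.1f kcal/mol\n",
            rec$A_binding_energy))
cat(sprintf("  hydrogen bonds:            %d\n", rec$B_hbond_count))
cat(sprintf("  Ser attack distance:       %.2f A\n", rec$C_attack_distance))
cat(sprintf("  cavity volume:             %.1f A^3\n", rec$D_cavity_volume))
cat("  (a snugly docked pose leaves little interstitial volume; the\n",
    "  scoring uses cavity volumes relatively, across variants)\n")
write.csv(rec, file.path(out, "complex_factors.csv"), row.names = FALSE)

# (b) score a synthetic five-variant table with a planted best
ft <- simulate_factor_table(5, cfg)
tab <- score_variants(ft$records)
write.csv(tab, file.path(out, "variant_scores.csv"), row.names = FALSE)
cat("\nvariant scores (planted best:", ft$best_id, ")\n")
print(tab[order(tab$rank), ], row.names = FALSE)
top <- rank_variants(tab, 1)
cat("top-ranked:", top,
    if (top == ft$best_id) "- matches the planted dominant variant\n"
    else "- MISMATCH\n")
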