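#!/usr/bin/env Rscript
# Stage 2 - design the truncation variants of the two BHET hydrolases:
# delete each candidate barrier region (inclusive) and bridge the junction
# with the flexible Gly-Gly linker. Sequences here are length-matched
# placeholders (the analyses downstream need counts and numbering maps,
# not real side chains); real parent sequences drop in unchanged.

suppressPackageStartupMessages(library(barriereng))

out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(1)

aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
parents <- list(
  BsEst = list(seq = paste(sample(aa, 418, TRUE), collapse = ""),
               regions = builtin_regions("bsest"), ser = 189),
  ChryBHETase = list(seq = paste(sample(aa, 400, TRUE), collapse = ""),
                     regions = builtin_regions("chrybhetase"), ser = 194)
)

rows <- list()
for (nm in names(parents)) {
  p <- parents[[nm]]
  variants <- batch_design(p$seq, p$regions, parent_id = nm)
  write_variants(variants, file.path(out, paste0(tolower(nm),
                                                 "_variants.fasta")))
  for (v in variants) {
    rows[[length(rows) + 1]] <- data.frame(
      parent = nm, variant = v$variant_id,
      region = paste0(v$region$start, "-", v$region$end),
      removed = v$removed_count,
      length = nchar(v$sequence),
      ser_new = map_residue(v, p$ser))
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "variant_summary.csv"), row.names = FALSE)
print(tab, row.names = FALSE)
cat("\nvalidated spans: BsEst D5 removes", tab$removed[5],
    "residues; ChryBHETase D2 removes", tab$removed[7], "residues\n")
cat("catalytic Ser keeps its number in every variant whose region lies",
    "downstream of it\n")
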