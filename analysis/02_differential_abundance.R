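#!/usr/bin/env Rscript
# Step 2 — per-hairpin negative-binomial differential abundance.
#
# For each cell line: median-of-ratios size factors, method-of-moments
# dispersions shared against a 1/mean trend, then Wald tests for the two
# contrasts the hit cascade consumes — treated vs untreated (the hit
# criteria) and treated vs t0 (the secondary depletion filter) — with BH
# FDR across all hairpins per contrast. Writes result tables and annotated
# volcano tables under results/da/.

suppressPackageStartupMessages(library(dropscreen))

sim_dir <- "results/sim"
out <- "results/da"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest(file.path(sim_dir, "manifest.tsv"))
lines <- sub("_counts\\.tsv$", "",
             basename(list.files(sim_dir, pattern = "_counts\\.tsv$")))
th <- hit_thresholds()  # log2fc < -1, FDR < 0.1, baseMeanA > 100

for (cl in lines) {
  sheet <- read_sample_sheet(file.path(sim_dir, paste0(cl, "_sheet.tsv")))
  counts <- read_counts(file.path(sim_dir, paste0(cl, "_counts.tsv")), manifest, sheet)
  sf <- compute_size_factors(counts)
  disp <- estimate_dispersions(counts, groups = sheet$arm, sf = sf)
  res_tu <- test_contrast(counts, sheet, manifest, sf, disp, "untreated", "treated")
  res_t0 <- test_contrast(counts, sheet, manifest, sf, disp, "t0", "treated")
  write_results(res_tu, file.path(out, paste0(cl, "_treated_vs_untreated.tsv")))
  write_results(res_t0, file.path(out, paste0(cl, "_treated_vs_t0.tsv")))
  volcano <- volcano_table(res_tu, th)
  write_results(volcano, file.path(out, paste0(cl, "_volcano.tsv")))
  cat(sprintf("%s: size factors %.2f-%.2f, median dispersion %.3f, %d/%d hairpins beyond the volcano cutoffs\n",
              cl, min(sf), max(sf), median(disp$alpha),
              sum(volcano$beyond_cutoff), nrow(volcano)))
}
cat("Wrote per-hairpin results and volcano tables to", out, "\n")
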