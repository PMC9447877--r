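#!/usr/bin/env Rscript
# Step 3 — two-step gene-level hit selection.
#
# Primary: a gene needs >= 2 hairpins with log2fc < -1, FDR < 0.1 and
# baseMeanA > 100 in treated-vs-untreated, and no hairpin significantly
# changed in the opposite direction. Secondary: its supporting hairpins must
# also show log2fc < -1 in treated-vs-t0, removing shRNAs that merely rose
# in the untreated arm. Writes per-line gene-call tables under results/hits/.

suppressPackageStartupMessages(library(dropscreen))

sim_dir <- "results/sim"
da_dir <- "results/da"
out <- "results/hits"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest(file.path(sim_dir, "manifest.tsv"))
lines <- sub("_treated_vs_untreated\\.tsv$", "",
             basename(list.files(da_dir, pattern = "_treated_vs_untreated\\.tsv$")))
th <- hit_thresholds()

for (cl in lines) {
  res_tu <- read_results(file.path(da_dir, paste0(cl, "_treated_vs_untreated.tsv")))
  res_t0 <- read_results(file.path(da_dir, paste0(cl, "_treated_vs_t0.tsv")))
  primary <- call_hits_primary(res_tu, manifest, th, cell_line = cl)
  calls <- call_hits_secondary(primary, res_t0, th)
  write_results(calls, file.path(out, paste0(cl, "_gene_calls.tsv")))
  elim <- table(calls$eliminated_at[!calls$is_hit])
  cat(sprintf("%s: %d primary hits, %d after the t0 filter (%s)\n",
              cl, sum(primary$is_hit), sum(calls$is_hit),
              paste(sprintf("%s: %d", names(elim), elim), collapse = ", ")))
  hits <- calls$gene_symbol[calls$is_hit]
  cat(sprintf("  hits: %s\n", paste(hits, collapse = ", ")))
}
cat("Wrote gene-call tables to", out, "\n")
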