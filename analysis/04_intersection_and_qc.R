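#!/usr/bin/env Rscript
# Step 4 — cross-line intersection, recovery vs ground truth, and screen QC.
#
# Intersects the per-line hit sets (the Venn readout whose three-way region
# is the screen's headline result), checks every planted sensitizer against
# the calls, and summarizes essential vs non-essential control separation.
# Writes results/intersection.json and results/control_separation.tsv.

suppressPackageStartupMessages(library(dropscreen))

sim_dir <- "results/sim"
da_dir <- "results/da"
hits_dir <- "results/hits"

manifest <- read_manifest(file.path(sim_dir, "manifest.tsv"))
truth <- read_results(file.path(sim_dir, "truth_gene_effects.tsv"))
lines <- sub("_gene_calls\\.tsv$", "",
             basename(list.files(hits_dir, pattern = "_gene_calls\\.tsv$")))

calls <- lapply(lines, function(cl) read_results(file.path(hits_dir, paste0(cl, "_gene_calls.tsv"))))
names(calls) <- lines

ix <- intersect_hits(calls)
jsonlite::write_json(ix, "results/intersection.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("Venn regions of the union of hit sets:\n")
print(ix$regions[, c("region", "n_genes", "genes")])
cat(sprintf("Common hits across all %d lines: %s\n", length(lines),
            if (ix$n_shared == 0) "(none)" else paste(ix$shared_genes, collapse = ", ")))

for (cl in lines) {
  planted <- truth$gene_symbol[truth$cell_line == cl & truth$lfc_treated_vs_untreated != 0]
  hits <- calls[[cl]]$gene_symbol[calls[[cl]]$is_hit]
  cat(sprintf("%s: planted %s | recovered %d/%d | spurious: %s\n", cl,
              paste(sort(planted), collapse = ","),
              length(intersect(hits, planted)), length(planted),
              if (length(setdiff(hits, planted)) == 0) "none"
              else paste(setdiff(hits, planted), collapse = ",")))
}

qc <- list()
for (cl in lines) {
  res_t0 <- read_results(file.path(da_dir, paste0(cl, "_treated_vs_t0.tsv")))
  cs <- summarize_controls(res_t0, manifest)
  cs$cell_line <- cl
  cs$separation <- attr(cs, "difference")
  qc[[cl]] <- cs
  cat(sprintf("%s control separation (essential - nonessential median log2fc vs t0): %.2f\n",
              cl, attr(cs, "difference")))
}
write_results(do.call(rbind, c(qc, make.row.names = FALSE)),
              "results/control_separation.tsv")
cat("Wrote results/intersection.json and results/control_separation.tsv\n")
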