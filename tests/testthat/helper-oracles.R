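# Independent brute-force oracles, written literally from the definitions.
# They deliberately share no code with the package implementation.

# median-of-ratios size factors, rescaled to geometric mean 1
oracle_size_factors <- function(m) {
  geomeans <- apply(m, 1L, function(r) prod(r)^(1 / length(r)))
  usable <- geomeans > 0
  sf <- vapply(seq_len(ncol(m)), function(j) {
    stats::median(m[usable, j] / geomeans[usable])
  }, numeric(1L))
  sf / exp(mean(log(sf)))
}

# Benjamini-Hochberg step-up, computed by exhaustive minimization
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(vapply(i:m, function(j) min(1, m * p[o[j]] / j), numeric(1L)))
  }, numeric(1L))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Literal enumeration of the two-step hit-selection rules, gene by gene.
oracle_cascade <- function(res_tu, res_t0, manifest, lfc_max = -1, fdr_max = 0.1,
                           basemean_min = 100, min_hairpins = 2L,
                           t0_quorum = "min_hairpins") {
  targeting <- manifest[manifest$hairpin_class == "targeting", ]
  genes <- sort(unique(targeting$gene_symbol))
  t0_lfc <- stats::setNames(res_t0$log2fc, res_t0$hairpin_id)
  is_hit <- logical(length(genes))
  for (gi in seq_along(genes)) {
    hps <- targeting$hairpin_id[targeting$gene_symbol == genes[gi]]
    supp <- character(0)
    opposite <- FALSE
    for (h in hps) {
      row <- res_tu[res_tu$hairpin_id == h, ]
      if (row$log2fc < lfc_max && row$fdr < fdr_max && row$baseMeanA > basemean_min) {
        supp <- c(supp, h)
      }
      if (row$log2fc > -lfc_max && row$fdr < fdr_max) opposite <- TRUE
    }
    primary <- length(supp) >= min_hairpins && !opposite
    if (!primary) next
    n_pass_t0 <- sum(vapply(supp, function(h) t0_lfc[[h]] < lfc_max, logical(1L)))
    need <- switch(t0_quorum, any = 1L, min_hairpins = min_hairpins, all = length(supp))
    is_hit[gi] <- n_pass_t0 >= need
  }
  data.frame(gene_symbol = genes, is_hit = is_hit, stringsAsFactors = FALSE)
}
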