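# In-code fixture builders shared across test files.

tiny_manifest <- function(genes = c("AKT1", "CDK2"), hairpins_per_gene = 2L,
                          gene_class = "kinase") {
  validate_manifest(data.frame(
    hairpin_id = paste0(rep(genes, each = hairpins_per_gene), "_sh",
                        rep(seq_len(hairpins_per_gene), length(genes))),
    gene_symbol = rep(genes, each = hairpins_per_gene),
    gene_class = gene_class,
    hairpin_class = "targeting",
    stringsAsFactors = FALSE
  ))
}

tiny_sheet <- function(cell_line = "CL1", arms = c("t0", "untreated", "treated"),
                       n_rep = 2L) {
  validate_sample_sheet(data.frame(
    sample_id = paste(cell_line, rep(arms, each = n_rep), rep(seq_len(n_rep), length(arms)),
                      sep = "_"),
    cell_line = cell_line, arm = rep(arms, each = n_rep),
    replicate = rep(seq_len(n_rep), length(arms)), stringsAsFactors = FALSE
  ))
}

# hairpin-results table with arbitrary statistics, for hit-calling tests
make_results <- function(manifest, log2fc, fdr = 0.01, baseMeanA = 500,
                         contrast = "treated_vs_untreated") {
  n <- nrow(manifest)
  data.frame(
    hairpin_id = manifest$hairpin_id,
    gene_symbol = manifest$gene_symbol,
    contrast = contrast,
    baseMeanA = rep_len(baseMeanA, n),
    log2fc = rep_len(log2fc, n),
    pvalue = rep_len(fdr, n),
    fdr = rep_len(fdr, n),
    stringsAsFactors = FALSE
  )
}

# random screen-like result tables for property tests: a mix of strong
# depletions, enrichments and nulls so every rule stage gets exercised
random_gene_table <- function(n_genes = 15L, max_hairpins = 5L) {
  n_hp <- sample(max_hairpins, n_genes, replace = TRUE)
  genes <- sprintf("G%02d", seq_len(n_genes))
  manifest <- validate_manifest(data.frame(
    hairpin_id = paste0(rep(genes, n_hp), "_sh",
                        unlist(lapply(n_hp, seq_len))),
    gene_symbol = rep(genes, n_hp),
    gene_class = "kinase",
    hairpin_class = "targeting",
    stringsAsFactors = FALSE
  ))
  m <- nrow(manifest)
  res_tu <- data.frame(
    hairpin_id = manifest$hairpin_id,
    gene_symbol = manifest$gene_symbol,
    contrast = "treated_vs_untreated",
    baseMeanA = exp(stats::runif(m, log(20), log(2000))),
    log2fc = stats::rnorm(m, 0, 1.5),
    pvalue = stats::rbeta(m, 0.5, 2),
    stringsAsFactors = FALSE
  )
  res_tu$fdr <- stats::p.adjust(res_tu$pvalue, "BH")
  res_t0 <- res_tu
  res_t0$contrast <- "treated_vs_t0"
  res_t0$log2fc <- stats::rnorm(m, -0.5, 1.5)
  list(manifest = manifest, res_tu = res_tu, res_t0 = res_t0)
}

hit_set <- function(calls) sort(calls$gene_symbol[calls$is_hit])
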