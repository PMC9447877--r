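#' Hit-selection thresholds
#'
#' The gene-level hit criteria of a dropout screen: a supporting hairpin
#' must show log2 fold change below `lfc_max`, FDR below `fdr_max` and
#' reference-arm abundance (baseMeanA) above `basemean_min`; a gene is a hit
#' when at least `min_hairpins` hairpins support it and none of its hairpins
#' is a significant change in the opposite direction. All inequalities are
#' strict. Defaults are the screen cutoffs: log2FC < -1, FDR < 0.1,
#' baseMeanA > 100, at least 2 independent shRNAs.
#'
#' @param lfc_max log2 fold-change ceiling for depletion; must be negative
#' @param fdr_max FDR ceiling, in (0, 1]
#' @param basemean_min baseMeanA floor, >= 0
#' @param min_hairpins minimum supporting hairpins per gene, >= 1
#' @param opposite_lfc_min log2fc floor defining an opposite-direction
#'   (enriched) hairpin; default mirrors `lfc_max` (i.e. +1). Set to 0 to veto
#'   on any nominally significant enrichment.
#' @param opposite_fdr_max FDR ceiling of the opposite-direction veto;
#'   default mirrors `fdr_max`. Kept separate so the hit criteria and the
#'   veto can be tightened independently (each dial is then monotone in the
#'   hit set).
#' @param t0_quorum how many of a primary hit's supporting hairpins must also
#'   be depleted versus the t=0 reference in the secondary step: "min_hairpins"
#'   (default, same quorum as the primary rule), "any" (one suffices), or
#'   "all"
#' @return object of class `hit_thresholds`
#' @export
hit_thresholds <- function(lfc_max = -1, fdr_max = 0.1, basemean_min = 100,
                           min_hairpins = 2L,
                           opposite_lfc_min = -lfc_max,
                           opposite_fdr_max = fdr_max,
                           t0_quorum = c("min_hairpins", "any", "all")) {
  t0_quorum <- match.arg(t0_quorum)
  if (!is.finite(lfc_max) || lfc_max >= 0) {
    abort_validation("lfc_max must be negative for a dropout screen")
  }
  if (!is.finite(fdr_max) || fdr_max <= 0 || fdr_max > 1) {
    abort_validation("fdr_max must lie in (0, 1]")
  }
  if (!is.finite(basemean_min) || basemean_min < 0) {
    abort_validation("basemean_min must be non-negative")
  }
  min_hairpins <- as.integer(min_hairpins)
  if (is.na(min_hairpins) || min_hairpins < 1L) {
    abort_validation("min_hairpins must be a positive integer")
  }
  if (!is.finite(opposite_fdr_max) || opposite_fdr_max <= 0 || opposite_fdr_max > 1) {
    abort_validation("opposite_fdr_max must lie in (0, 1]")
  }
  structure(list(lfc_max = lfc_max, fdr_max = fdr_max, basemean_min = basemean_min,
                 min_hairpins = min_hairpins, opposite_lfc_min = opposite_lfc_min,
                 opposite_fdr_max = opposite_fdr_max, t0_quorum = t0_quorum),
            class = "hit_thresholds")
}

#' @export
print.hit_thresholds <- function(x, ...) {
  cat(sprintf(paste0("hit thresholds: log2fc < %g, FDR < %g, baseMeanA > %g, ",
                     ">= %d hairpins; opposite veto at log2fc > %g; t0 quorum: %s\n"),
              x$lfc_max, x$fdr_max, x$basemean_min, x$min_hairpins,
              x$opposite_lfc_min, x$t0_quorum))
  invisible(x)
}

new_gene_calls <- function(gene_symbol, cell_line, is_hit, supporting, eliminated_at) {
  df <- data.frame(
    gene_symbol = gene_symbol,
    cell_line = cell_line,
    is_hit = is_hit,
    n_supporting = vapply(supporting, length, 1L),
    supporting_hairpins = vapply(supporting, paste, "", collapse = ";"),
    eliminated_at = eliminated_at,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$gene_symbol), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_calls", "data.frame")
  df
}

split_hairpins <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1L]]
}

#' Primary gene-level hit calling (treated vs untreated)
#'
#' Applies the first step of the hit-selection cascade to per-hairpin results
#' of the treated-versus-untreated contrast. A hairpin supports its gene when
#' log2fc < lfc_max AND fdr < fdr_max AND baseMeanA > basemean_min. A gene is
#' a primary hit when at least `min_hairpins` hairpins support it AND no
#' hairpin of the gene is significantly changed in the opposite direction
#' (log2fc > opposite_lfc_min AND fdr < opposite_fdr_max). Control genes
#' (essential/non-essential spike-ins) are never callable and are excluded
#' from the output; they feed [summarize_controls()] instead.
#'
#' Non-hits record the first stage that eliminated them: `too_few_hairpins`
#' or `opposite_direction`.
#'
#' @param results `hairpin_results` table for the treated-vs-untreated
#'   contrast, covering every targeting hairpin of the manifest
#' @param manifest validated library manifest
#' @param thresholds a [hit_thresholds()] object
#' @param cell_line label recorded in the output
#' @return `gene_calls` data frame with one row per targeting gene
#' @export
call_hits_primary <- function(results, manifest, thresholds = hit_thresholds(),
                              cell_line = "unspecified") {
  unknown <- setdiff(results$gene_symbol, manifest$gene_symbol)
  if (length(unknown) > 0L) {
    abort_validation(sprintf("results contain gene(s) absent from manifest: %s",
                             paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  targeting <- manifest[manifest$hairpin_class == "targeting", , drop = FALSE]
  missing <- setdiff(targeting$hairpin_id, results$hairpin_id)
  if (length(missing) > 0L) {
    abort_validation(sprintf("results must cover all targeting hairpins; missing: %s",
                             paste(utils::head(missing, 5L), collapse = ", ")))
  }
  r <- results[results$hairpin_id %in% targeting$hairpin_id, , drop = FALSE]
  th <- thresholds
  supp_ok <- r$log2fc < th$lfc_max & r$fdr < th$fdr_max & r$baseMeanA > th$basemean_min
  opp_ok <- r$log2fc > th$opposite_lfc_min & r$fdr < th$opposite_fdr_max

  genes <- sort(unique(targeting$gene_symbol))
  supporting <- lapply(genes, function(g) sort(r$hairpin_id[r$gene_symbol == g & supp_ok]))
  names(supporting) <- genes
  n_opp <- vapply(genes, function(g) sum(r$gene_symbol == g & opp_ok), 1L)

  n_supp <- vapply(supporting, length, 1L)
  is_hit <- n_supp >= th$min_hairpins & n_opp == 0L
  eliminated <- ifelse(is_hit, "none",
                       ifelse(n_supp < th$min_hairpins, "too_few_hairpins",
                              "opposite_direction"))
  new_gene_calls(genes, cell_line, is_hit, supporting, eliminated)
}

#' Secondary hit filtering against the t=0 reference
#'
#' The second step of the cascade removes genes whose apparent depletion is
#' driven by enrichment in the untreated arm rather than loss under
#' treatment: each supporting hairpin of a primary hit must also show
#' log2 fold change < lfc_max in the treated-versus-t0 contrast (fold change
#' only; no FDR or abundance condition at this step). The gene survives when
#' the configured quorum of its supporting hairpins passes
#' (default: `min_hairpins`, the same quorum as the primary rule); survivors
#' keep only the doubly-passing hairpins as support, failures are marked
#' `eliminated_at = "t0_filter"`.
#'
#' @param primary `gene_calls` table from [call_hits_primary()]
#' @param results_t0 `hairpin_results` table for the treated-vs-t0 contrast,
#'   covering every supporting hairpin of the primary hits
#' @param thresholds a [hit_thresholds()] object
#' @return updated `gene_calls` data frame
#' @export
call_hits_secondary <- function(primary, results_t0, thresholds = hit_thresholds()) {
  if (nrow(primary) == 0L) return(primary)
  th <- thresholds
  quorum <- function(n_supp) {
    switch(th$t0_quorum,
           any = 1L,
           min_hairpins = th$min_hairpins,
           all = n_supp)
  }
  t0_lfc <- stats::setNames(results_t0$log2fc, results_t0$hairpin_id)

  out <- primary
  for (i in which(primary$is_hit)) {
    supp <- split_hairpins(primary$supporting_hairpins[i])
    missing <- setdiff(supp, names(t0_lfc))
    if (length(missing) > 0L) {
      abort_validation(sprintf(
        "supporting hairpin(s) of gene %s missing from treated-vs-t0 results: %s",
        primary$gene_symbol[i], paste(missing, collapse = ", ")))
    }
    pass <- supp[t0_lfc[supp] < th$lfc_max]
    if (length(pass) >= quorum(length(supp))) {
      out$supporting_hairpins[i] <- paste(sort(pass), collapse = ";")
      out$n_supporting[i] <- length(pass)
    } else {
      out$is_hit[i] <- FALSE
      out$eliminated_at[i] <- "t0_filter"
    }
  }
  out
}

#' Intersect hit sets across cell lines
#'
#' Computes the set of genes called hits in every cell line together with the
#' full Venn partition of the union of hit sets (one region per non-empty
#' subset-membership pattern; region counts partition the union exactly).
#'
#' @param per_line_calls named list (cell line -> `gene_calls` table), length
#'   >= 2
#' @return list with `cell_lines`, `shared_genes`, `n_shared`, and `regions`
#'   (data frame: region label, number of lines, gene count,
#'   semicolon-joined genes)
#' @export
intersect_hits <- function(per_line_calls) {
  if (!is.list(per_line_calls) || length(per_line_calls) < 2L) {
    abort_validation("intersection needs gene calls for at least 2 cell lines")
  }
  if (is.null(names(per_line_calls)) || any(!nzchar(names(per_line_calls)))) {
    abort_validation("per_line_calls must be a named list keyed by cell line")
  }
  lines <- names(per_line_calls)
  hit_sets <- lapply(per_line_calls, function(gc) sort(gc$gene_symbol[gc$is_hit]))
  union_genes <- sort(unique(unlist(hit_sets)))
  membership <- vapply(hit_sets, function(s) union_genes %in% s,
                       logical(length(union_genes)))
  if (length(union_genes) == 1L) membership <- matrix(membership, nrow = 1L,
                                                      dimnames = list(NULL, lines))
  # one Venn region per non-empty membership pattern
  patterns <- apply(membership, 1L, function(m) paste(lines[m], collapse = "&"))
  all_patterns <- unlist(lapply(seq_along(lines), function(k) {
    utils::combn(lines, k, paste, collapse = "&")
  }))
  region_genes <- lapply(all_patterns, function(p) {
    if (length(union_genes) == 0L) character(0) else sort(union_genes[patterns == p])
  })
  regions <- data.frame(
    region = all_patterns,
    n_lines = lengths(strsplit(all_patterns, "&", fixed = TRUE)),
    n_genes = vapply(region_genes, length, 1L),
    genes = vapply(region_genes, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  shared <- Reduce(intersect, hit_sets)
  list(cell_lines = lines,
       shared_genes = sort(shared),
       n_shared = length(shared),
       regions = regions)
}

#' Annotate per-hairpin results with volcano-plot cutoff flags
#'
#' Flags each hairpin as beyond the volcano cutoffs when log2fc < lfc_max and
#' fdr < fdr_max (the dashed-line cutoffs of a depletion volcano). The table
#' is sorted by fdr, then log2fc, so flagged hairpins lead.
#'
#' @param results `hairpin_results` table (may be empty)
#' @param thresholds a [hit_thresholds()] object
#' @return the results table with a logical `beyond_cutoff` column, sorted
#' @export
volcano_table <- function(results, thresholds = hit_thresholds()) {
  out <- as.data.frame(results)
  out$beyond_cutoff <- if (nrow(out) == 0L) logical(0) else {
    out$log2fc < thresholds$lfc_max & out$fdr < thresholds$fdr_max
  }
  out <- out[order(out$fdr, out$log2fc), , drop = FALSE]
  rownames(out) <- NULL
  out
}
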