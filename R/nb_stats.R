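#' Median-of-ratios size factors
#'
#' Estimates one positive depth factor per sample as the median, over
#' hairpins whose counts are positive in every sample, of the ratio of the
#' sample's count to the hairpin's geometric mean across samples. Factors
#' are rescaled to geometric mean 1, which removes the arbitrary global
#' scale and makes small worked examples deterministic.
#'
#' @param counts non-negative count matrix, hairpins x samples
#' @return named numeric vector of strictly positive size factors, one per
#'   sample, with geometric mean 1
#' @examples
#' m <- rbind(c(2, 4), c(6, 12), c(10, 20))
#' colnames(m) <- c("s1", "s2")
#' compute_size_factors(m)  # (1/sqrt(2), sqrt(2))
#' @export
compute_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L) abort_validation("count matrix has no samples")
  logc <- log(counts)
  log_geomean <- rowMeans(logc)
  usable <- is.finite(log_geomean)
  if (!any(usable)) {
    abort_validation(paste("no hairpin has positive counts in every sample;",
                           "size factors cannot be estimated (consider filtering",
                           "empty rows or adding a pseudocount upstream)"))
  }
  ratios <- exp(logc[usable, , drop = FALSE] - log_geomean[usable])
  sf <- apply(ratios, 2L, stats::median)
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Divide counts by per-sample size factors
#'
#' @param counts count matrix, hairpins x samples
#' @param sf size factors from [compute_size_factors()]; names (if present)
#'   must match the matrix's sample columns
#' @return real-valued matrix of depth-normalized counts
#' @export
normalize_counts <- function(counts, sf) {
  counts <- as.matrix(counts)
  if (length(sf) != ncol(counts)) {
    abort_validation("size factor vector length must equal the number of samples")
  }
  if (!is.null(names(sf)) && !is.null(colnames(counts))) {
    if (!setequal(names(sf), colnames(counts))) {
      abort_validation("size factor names do not match count matrix samples")
    }
    sf <- sf[colnames(counts)]
  }
  if (any(!is.finite(sf) | sf <= 0)) abort_validation("size factors must be strictly positive")
  sweep(counts, 2L, sf, "/")
}

#' Per-hairpin negative-binomial dispersion estimates
#'
#' The NB model is Var = mu + alpha * mu^2. For each hairpin a
#' method-of-moments (MoM) estimate is formed from the pooled within-group
#' variance of normalized counts, subtracting the depth-rescaled Poisson
#' component: alpha_mom = (v - mean(1/sf) * mu) / mu^2. A mean-dispersion
#' trend alpha(mu) = a0 + a1/mu is then fit by least squares to the MoM
#' values, and each hairpin's final dispersion is the maximum of its own MoM
#' estimate and the trend evaluated at its mean — the conservative sharing
#' scheme that guards the downstream Wald test against underestimated
#' per-hairpin variances at small replicate numbers.
#'
#' If any group has fewer than two samples, estimation falls back to a
#' pooled ("blind") estimate treating all samples as one group.
#'
#' @param counts count matrix, hairpins x samples
#' @param groups character/factor of length ncol(counts) assigning each
#'   sample to a group (typically the screen arm)
#' @param sf size factors from [compute_size_factors()]
#' @return object of class `dispersion_estimates`: list with `alpha`
#'   (named per-hairpin dispersions, all >= 0), `trend_coef` (a0, a1),
#'   `mean` (per-hairpin mean normalized count) and `method`
#'   ("within-group" or "blind")
#' @export
estimate_dispersions <- function(counts, groups, sf) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  if (n < 2L) abort_validation("dispersion estimation needs at least 2 samples")
  if (length(groups) != n) abort_validation("groups must have one entry per sample")
  k <- normalize_counts(counts, sf)
  if (!is.null(names(sf)) && !is.null(colnames(counts))) sf <- sf[colnames(counts)]

  idx <- split(seq_len(n), as.character(groups))
  method <- "within-group"
  if (any(vapply(idx, length, 1L) < 2L)) {
    idx <- list(all = seq_len(n))
    method <- "blind"
  }
  mu <- rowMeans(k)
  ss <- 0
  df <- 0L
  for (j in idx) {
    kg <- k[, j, drop = FALSE]
    ss <- ss + rowSums((kg - rowMeans(kg))^2)
    df <- df + length(j) - 1L
  }
  if (df < 1L) abort_validation("not enough replication to estimate dispersions")
  v <- ss / df
  xi <- mean(1 / sf)
  alpha_mom <- ifelse(mu > 0, (v - xi * mu) / mu^2, NA_real_)

  fit_rows <- is.finite(alpha_mom) & mu > 0
  if (sum(fit_rows) >= 2L && stats::var(1 / mu[fit_rows]) > 0) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[fit_rows]), alpha_mom[fit_rows])
    trend_coef <- fit$coefficients
  } else {
    # degenerate input (single usable row or constant mean): flat trend
    trend_coef <- c(max(0, mean(alpha_mom[fit_rows], na.rm = TRUE)), 0)
    if (!is.finite(trend_coef[1L])) trend_coef[1L] <- 0
  }
  names(trend_coef) <- c("a0", "a1")
  trend_at <- function(m) pmax(0, trend_coef[[1L]] + trend_coef[[2L]] / m)

  # all-zero hairpins have no information; evaluate the trend just above 0
  mu_eval <- pmax(mu, if (any(mu > 0)) min(mu[mu > 0]) else 1)
  alpha <- pmax(alpha_mom, trend_at(mu_eval), 0, na.rm = TRUE)
  names(alpha) <- rownames(counts)

  structure(list(alpha = alpha, trend_coef = trend_coef, mean = mu, method = method),
            class = "dispersion_estimates")
}

#' @export
print.dispersion_estimates <- function(x, ...) {
  cat(sprintf("dispersion estimates (%s): %d hairpins, median alpha %.4g, trend a0=%.4g a1=%.4g\n",
              x$method, length(x$alpha), stats::median(x$alpha),
              x$trend_coef[[1L]], x$trend_coef[[2L]]))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values, clipped to 1. A thin validated front
#' to `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\]
#' @return vector of BH-adjusted values (FDR), same length and order
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort_validation("p-values must be finite and within [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-hairpin two-group negative-binomial contrast
#'
#' For each hairpin, compares mean normalized counts between a test arm and
#' a reference arm. The log2 fold change is
#' log2((mean_test + c) / (mean_ref + c)) with pseudocount `c` (default 0.5
#' normalized counts) so fold changes stay finite at zero counts while the
#' bias is negligible at the abundances where hits are called
#' (baseMeanA > 100). The two-sided p-value is a Wald test on the natural-log
#' fold change, with the NB variance of each arm mean
#' (Var(mean) = (mu * sum(1/sf) + n * alpha * mu^2) / n^2) propagated to the
#' log scale by the delta method. Hairpins with zero counts in both arms are
#' uninformative and receive log2fc = 0, p = 1. FDR is the BH adjustment
#' across all hairpins of the contrast (targeting and control alike, matching
#' a single-FDR-axis volcano).
#'
#' @param counts count matrix, hairpins x samples
#' @param sheet validated sample sheet covering the matrix's samples
#' @param manifest validated library manifest covering the matrix's hairpins
#' @param sf size factors
#' @param disp `dispersion_estimates` object
#' @param reference_arm,test_arm arm labels ("t0", "untreated", "treated");
#'   baseMeanA is the mean normalized count of the reference arm
#' @param pseudocount normalized-count offset `c` used in the fold change
#' @return data frame of class `hairpin_results` with columns `hairpin_id`,
#'   `gene_symbol`, `contrast`, `baseMeanA`, `log2fc`, `pvalue`, `fdr`
#' @export
test_contrast <- function(counts, sheet, manifest, sf, disp,
                          reference_arm, test_arm, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  for (arm in c(reference_arm, test_arm)) {
    if (!arm %in% ARMS) abort_validation(sprintf("unknown arm label '%s'", arm))
    if (!any(sheet$arm == arm)) {
      abort_validation(sprintf("arm '%s' has no samples in the sheet", arm))
    }
  }
  jA <- which(colnames(counts) %in% sheet$sample_id[sheet$arm == reference_arm])
  jB <- which(colnames(counts) %in% sheet$sample_id[sheet$arm == test_arm])
  if (length(jA) == 0L || length(jB) == 0L) {
    abort_validation("contrast arms not present among count matrix samples")
  }
  if (!is.null(names(sf))) sf <- sf[colnames(counts)]
  k <- normalize_counts(counts, sf)
  alpha <- disp$alpha[rownames(counts)]
  if (any(is.na(alpha))) abort_validation("dispersions missing for some hairpins")

  mA <- rowMeans(k[, jA, drop = FALSE])
  mB <- rowMeans(k[, jB, drop = FALSE])
  nA <- length(jA)
  nB <- length(jB)
  c0 <- pseudocount

  log2fc <- log2((mB + c0) / (mA + c0))
  # delta method: Var(log(m + c)) ~ Var(m) / (m + c)^2
  vA <- (mA * sum(1 / sf[jA]) + nA * alpha * mA^2) / nA^2
  vB <- (mB * sum(1 / sf[jB]) + nB * alpha * mB^2) / nB^2
  se2 <- vA / (mA + c0)^2 + vB / (mB + c0)^2
  z <- ifelse(se2 > 0, log((mB + c0) / (mA + c0)) / sqrt(se2), 0)
  pvalue <- 2 * stats::pnorm(-abs(z))

  empty <- mA == 0 & mB == 0
  pvalue[empty] <- 1
  log2fc[empty] <- 0

  gene <- manifest$gene_symbol[match(rownames(counts), manifest$hairpin_id)]
  if (any(is.na(gene))) abort_validation("count matrix contains hairpins absent from the manifest")

  res <- data.frame(
    hairpin_id = rownames(counts),
    gene_symbol = gene,
    contrast = paste0(test_arm, "_vs_", reference_arm),
    baseMeanA = mA,
    log2fc = log2fc,
    pvalue = pvalue,
    fdr = bh_adjust(pvalue),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$gene_symbol, res$hairpin_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("hairpin_results", "data.frame")
  res
}
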