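#' Synthetic pooled-screen parameters
#'
#' Parameter set of the synthetic kinome dropout screen. Defaults emulate the
#' screened library and design: 518 kinase + 17 kinase-related targeting
#' genes at 5 hairpins each, 243 essential-control and 272
#' non-essential-control hairpins, 1000x sequencing coverage per hairpin,
#' negative-binomial counts with dispersion 0.05, three replicates per arm,
#' planted sensitizers depleted 4-fold (log2 -2) in the treated arm, and
#' essential controls depleted 4-fold from t=0 in both end arms.
#'
#' Per-hairpin activity multipliers (lognormal, sdlog `hairpin_effect_sd`)
#' scale the planted log2 effect of each hairpin, and a fraction
#' `inert_fraction` of hairpins are inert (no knockdown), so the
#' at-least-two-hairpins rule is exercised nontrivially. Per-sample depth
#' factors (lognormal, sdlog `depth_factor_sd`) exercise size-factor
#' normalization.
#'
#' @param n_kinase_genes,n_kinase_related numbers of targeting genes by class
#' @param hairpins_per_gene hairpins per targeting gene
#' @param n_essential_control_hairpins,n_nonessential_control_hairpins
#'   control hairpin counts
#' @param coverage expected reads per hairpin (library coverage)
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2)
#' @param n_replicates replicates per arm (t0, untreated, treated)
#' @param sensitizer_lfc treated-vs-untreated log2 effect of planted hits
#' @param essential_lfc end-vs-t0 log2 effect of essential controls
#' @param hairpin_effect_sd sdlog of hairpin activity multipliers
#' @param inert_fraction probability a hairpin is inert
#' @param depth_factor_sd sdlog of per-sample depth factors
#' @param planted_common_hits genes planted as hits in every cell line
#' @param planted_private_hits named list (cell line -> genes) of
#'   line-specific hits
#' @param cell_lines cell-line labels for [simulate_three_line_study()]
#' @param seed integer seed
#' @return object of class `screen_sim_params`
#' @export
screen_sim_params <- function(n_kinase_genes = 518L,
                              n_kinase_related = 17L,
                              hairpins_per_gene = 5L,
                              n_essential_control_hairpins = 243L,
                              n_nonessential_control_hairpins = 272L,
                              coverage = 1000,
                              dispersion = 0.05,
                              n_replicates = 3L,
                              sensitizer_lfc = -2,
                              essential_lfc = -2,
                              hairpin_effect_sd = 0.3,
                              inert_fraction = 0.2,
                              depth_factor_sd = 0.2,
                              planted_common_hits = character(0),
                              planted_private_hits = list(),
                              cell_lines = c("CAL51", "CAL120", "HCC1806"),
                              seed = 1L) {
  p <- list(n_kinase_genes = as.integer(n_kinase_genes),
            n_kinase_related = as.integer(n_kinase_related),
            hairpins_per_gene = as.integer(hairpins_per_gene),
            n_essential_control_hairpins = as.integer(n_essential_control_hairpins),
            n_nonessential_control_hairpins = as.integer(n_nonessential_control_hairpins),
            coverage = coverage, dispersion = dispersion,
            n_replicates = as.integer(n_replicates),
            sensitizer_lfc = sensitizer_lfc, essential_lfc = essential_lfc,
            hairpin_effect_sd = hairpin_effect_sd,
            inert_fraction = inert_fraction,
            depth_factor_sd = depth_factor_sd,
            planted_common_hits = as.character(planted_common_hits),
            planted_private_hits = planted_private_hits,
            cell_lines = as.character(cell_lines),
            seed = as.integer(seed))
  with(p, {
    if (n_kinase_genes < 0L || n_kinase_related < 0L || hairpins_per_gene < 1L ||
        n_kinase_genes + n_kinase_related < 1L) {
      abort_validation("library must contain at least one targeting gene with >= 1 hairpin")
    }
    if (n_essential_control_hairpins < 0L || n_nonessential_control_hairpins < 0L) {
      abort_validation("control hairpin counts must be non-negative")
    }
    if (coverage <= 0) abort_validation("coverage must be positive")
    if (dispersion < 0) abort_validation("dispersion must be >= 0")
    if (n_replicates < 1L) abort_validation("n_replicates must be >= 1")
    if (inert_fraction < 0 || inert_fraction >= 1) {
      abort_validation("inert_fraction must lie in [0, 1)")
    }
    if (hairpin_effect_sd < 0 || depth_factor_sd < 0) {
      abort_validation("lognormal spread parameters must be >= 0")
    }
  })
  if (length(p$planted_private_hits) > 0L) {
    bad <- setdiff(names(p$planted_private_hits), p$cell_lines)
    if (length(bad) > 0L) {
      abort_validation(sprintf("planted_private_hits names unknown cell line(s): %s",
                               paste(bad, collapse = ", ")))
    }
  }
  structure(p, class = "screen_sim_params")
}

#' Build the default kinome-like library manifest
#'
#' Constructs a manifest with `n_kinase_genes + n_kinase_related` targeting
#' genes at `hairpins_per_gene` hairpins each, plus exactly the requested
#' numbers of essential-control and non-essential-control hairpins. Control
#' hairpins are grouped into pseudo-genes of up to 5 hairpins; only the
#' hairpin-level control totals are meaningful.
#'
#' @param params a [screen_sim_params()] object
#' @return validated library manifest
#' @export
build_default_manifest <- function(params = screen_sim_params()) {
  stopifnot(inherits(params, "screen_sim_params"))
  gene_block <- function(genes, gclass, hp_per_gene) {
    if (length(genes) == 0L) return(NULL)
    data.frame(
      hairpin_id = paste0(rep(genes, each = hp_per_gene), "_sh",
                          rep(seq_len(hp_per_gene), times = length(genes))),
      gene_symbol = rep(genes, each = hp_per_gene),
      gene_class = gclass,
      hairpin_class = if (gclass == "control") NA_character_ else "targeting",
      stringsAsFactors = FALSE
    )
  }
  control_block <- function(n_hairpins, prefix, hclass) {
    if (n_hairpins == 0L) return(NULL)
    n_genes <- ceiling(n_hairpins / 5L)
    gene <- paste0(prefix, formatC(rep(seq_len(n_genes), each = 5L)[seq_len(n_hairpins)],
                                   width = 3L, flag = "0"))
    idx <- stats::ave(seq_len(n_hairpins), gene, FUN = seq_along)
    data.frame(hairpin_id = paste0(gene, "_sh", idx),
               gene_symbol = gene, gene_class = "control", hairpin_class = hclass,
               stringsAsFactors = FALSE)
  }
  kin <- if (params$n_kinase_genes > 0L) {
    paste0("KIN", formatC(seq_len(params$n_kinase_genes), width = 4L, flag = "0"))
  } else character(0)
  krg <- if (params$n_kinase_related > 0L) {
    paste0("KRG", formatC(seq_len(params$n_kinase_related), width = 3L, flag = "0"))
  } else character(0)
  manifest <- rbind(
    gene_block(kin, "kinase", params$hairpins_per_gene),
    gene_block(krg, "kinase_related", params$hairpins_per_gene),
    control_block(params$n_essential_control_hairpins, "ESSC", "essential_control"),
    control_block(params$n_nonessential_control_hairpins, "NONC", "nonessential_control")
  )
  validate_manifest(manifest)
}

# Gene-level true log2 effects for one cell line:
# L_g(s) = 0 at t0; essential effect at untreated end;
# essential + sensitizer effect at treated end.
gene_truth_for_line <- function(manifest, params, cell_line) {
  genes <- unique(manifest[, c("gene_symbol", "gene_class")])
  essential_genes <- unique(manifest$gene_symbol[manifest$hairpin_class == "essential_control"])
  sens_genes <- union(params$planted_common_hits,
                      params$planted_private_hits[[cell_line]])
  unknown <- setdiff(sens_genes, manifest$gene_symbol[manifest$hairpin_class == "targeting"])
  if (length(unknown) > 0L) {
    abort_validation(sprintf("planted hit(s) not targeting genes of the manifest: %s",
                             paste(unknown, collapse = ", ")))
  }
  essential <- ifelse(genes$gene_symbol %in% essential_genes, params$essential_lfc, 0)
  sensitizer <- ifelse(genes$gene_symbol %in% sens_genes, params$sensitizer_lfc, 0)
  data.frame(cell_line = cell_line,
             gene_symbol = genes$gene_symbol,
             lfc_treated_vs_untreated = sensitizer,
             lfc_treated_vs_t0 = essential + sensitizer,
             lfc_untreated_vs_t0 = essential,
             stringsAsFactors = FALSE)
}

draw_hairpin_activity <- function(manifest, params) {
  n <- nrow(manifest)
  data.frame(hairpin_id = manifest$hairpin_id,
             activity = stats::rlnorm(n, 0, params$hairpin_effect_sd),
             inert = stats::runif(n) < params$inert_fraction,
             stringsAsFactors = FALSE)
}

#' Simulate one cell line of a pooled dropout screen
#'
#' Draws hairpin counts for a single cell line: a t=0 reference arm sampled
#' at infection and untreated / treated end arms, each with
#' `params$n_replicates` replicate samples. The expected count of hairpin h
#' (gene g) in sample s is
#' `mu = coverage * depth_s * 2^(L_g(s) * e_h)`, where `L_g(s)` is the gene's
#' true log2 effect in that arm (0 at t0; essential effect at untreated end;
#' essential + sensitizer effect at treated end), and `e_h` is the hairpin's
#' effect penetrance: 0 for inert hairpins, otherwise its lognormal activity
#' multiplier. Counts are drawn NB(mu, dispersion); with dispersion 0 the
#' draw is Poisson.
#'
#' @param manifest validated library manifest
#' @param params a [screen_sim_params()] object
#' @param cell_line label used in sample ids and the truth table
#' @param seed integer seed for this line's draws (default `params$seed`)
#' @param activity optional pre-drawn hairpin activity table (shared library
#'   across cell lines); drawn from `seed` when NULL
#' @return list with `counts` (integer matrix), `sheet` (sample sheet),
#'   `truth` (gene-level true effects + hairpin activity table) and
#'   `expected` (the matrix of true means mu)
#' @export
simulate_screen <- function(manifest, params, cell_line = "CAL51",
                            seed = params$seed, activity = NULL) {
  stopifnot(inherits(params, "screen_sim_params"))
  set.seed(seed)
  if (is.null(activity)) activity <- draw_hairpin_activity(manifest, params)
  if (!identical(sort(activity$hairpin_id), sort(manifest$hairpin_id))) {
    abort_validation("activity table does not cover the manifest hairpins")
  }
  truth_genes <- gene_truth_for_line(manifest, params, cell_line)

  n_rep <- params$n_replicates
  sheet <- data.frame(
    sample_id = paste(cell_line, rep(ARMS, each = n_rep), rep(seq_len(n_rep), 3L), sep = "_"),
    cell_line = cell_line,
    arm = rep(ARMS, each = n_rep),
    replicate = rep(seq_len(n_rep), 3L),
    stringsAsFactors = FALSE
  )
  sheet <- validate_sample_sheet(sheet)
  depth <- stats::rlnorm(nrow(sheet), 0, params$depth_factor_sd)
  names(depth) <- sheet$sample_id

  act <- activity[match(manifest$hairpin_id, activity$hairpin_id), , drop = FALSE]
  penetrance <- ifelse(act$inert, 0, act$activity)
  gi <- match(manifest$gene_symbol, truth_genes$gene_symbol)
  L <- cbind(t0 = 0,
             untreated = truth_genes$lfc_untreated_vs_t0[gi],
             treated = truth_genes$lfc_treated_vs_t0[gi])

  mu <- matrix(0, nrow(manifest), nrow(sheet),
               dimnames = list(manifest$hairpin_id, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    mu[, j] <- params$coverage * depth[j] * 2^(L[, sheet$arm[j]] * penetrance)
  }
  counts <- if (params$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / params$dispersion),
           nrow(mu), ncol(mu), dimnames = dimnames(mu))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu),
           nrow(mu), ncol(mu), dimnames = dimnames(mu))
  }
  storage.mode(counts) <- "integer"
  list(counts = counts,
       sheet = sheet,
       truth = list(gene_effects = truth_genes, hairpin_activity = activity,
                    depth_factors = depth),
       expected = mu)
}

#' Simulate a three-cell-line screen study
#'
#' Simulates the full cross-line design: all cell lines share one library
#' manifest and one set of hairpin activity multipliers (hairpin efficacy is
#' a property of the construct), genes in `planted_common_hits` are
#' sensitizers in every line, each line additionally carries its
#' `planted_private_hits`, and count noise is independent across lines.
#'
#' @param params a [screen_sim_params()] object
#' @param manifest optional manifest; built from `params` when NULL
#' @return list with `manifest`, `lines` (named list per cell line of
#'   `counts`, `sheet`, `expected`), and `truth` (combined gene-effect table
#'   over all lines + shared hairpin activity)
#' @export
simulate_three_line_study <- function(params = screen_sim_params(), manifest = NULL) {
  stopifnot(inherits(params, "screen_sim_params"))
  if (is.null(manifest)) manifest <- build_default_manifest(params)
  set.seed(params$seed)
  activity <- draw_hairpin_activity(manifest, params)
  lines <- list()
  gene_effects <- list()
  for (i in seq_along(params$cell_lines)) {
    cl <- params$cell_lines[i]
    sim <- simulate_screen(manifest, params, cell_line = cl,
                           seed = (params$seed + 7919L * i) %% .Machine$integer.max,
                           activity = activity)
    lines[[cl]] <- sim[c("counts", "sheet", "expected")]
    gene_effects[[cl]] <- sim$truth$gene_effects
  }
  list(manifest = manifest,
       lines = lines,
       truth = list(gene_effects = do.call(rbind, c(gene_effects, make.row.names = FALSE)),
                    hairpin_activity = activity))
}

#' Default planted-hit recovery scenario
#'
#' The study conditions used for recovery testing: one common sensitizer
#' planted in all three cell lines plus two private sensitizers per line,
#' all drawn (without replacement, seed-determined) from the targeting genes.
#'
#' @param seed integer seed (drives both the gene draw and the count noise)
#' @param ... overrides passed to [screen_sim_params()]
#' @return a [screen_sim_params()] object with planted hits set
#' @export
recovery_scenario_params <- function(seed = 1L, ...) {
  base <- screen_sim_params(seed = seed, ...)
  genes <- c(
    if (base$n_kinase_genes > 0L)
      paste0("KIN", formatC(seq_len(base$n_kinase_genes), width = 4L, flag = "0")),
    if (base$n_kinase_related > 0L)
      paste0("KRG", formatC(seq_len(base$n_kinase_related), width = 3L, flag = "0"))
  )
  n_lines <- length(base$cell_lines)
  if (length(genes) < 1L + 2L * n_lines) {
    abort_validation("too few targeting genes for the recovery scenario")
  }
  set.seed(seed)
  planted <- sample(genes, 1L + 2L * n_lines)
  private <- split(planted[-1L], rep(base$cell_lines, each = 2L))
  screen_sim_params(seed = seed, ...,
                    planted_common_hits = planted[1L],
                    planted_private_hits = private[base$cell_lines])
}
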