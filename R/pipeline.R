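LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

log_msg <- function(config_level, level, fmt, ...) {
  if (LOG_LEVELS[[level]] >= LOG_LEVELS[[config_level]]) {
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  }
}

#' Run configuration for a full screen analysis
#'
#' Bundles everything [run_screen_analysis()] needs: the input mode
#' (`simulate` draws a multi-line synthetic study; `files` ingests a
#' manifest plus per-line count matrices and sample sheets), the hit
#' thresholds, the output directory and the seed.
#'
#' @param mode "simulate" or "files"
#' @param sim_params [screen_sim_params()] object (simulate mode)
#' @param manifest_path path to the library manifest (files mode)
#' @param counts_paths,sheet_paths named character vectors
#'   (cell line -> path) of count matrices and sample sheets (files mode)
#' @param thresholds a [hit_thresholds()] object
#' @param out_dir output directory (created if absent); NULL to skip writing
#' @param seed integer seed; in simulate mode overrides `sim_params$seed`
#' @param log_level one of "debug", "info", "warn", "quiet"
#' @return object of class `run_config`
#' @export
run_config <- function(mode = c("simulate", "files"),
                       sim_params = NULL,
                       manifest_path = NULL, counts_paths = NULL, sheet_paths = NULL,
                       thresholds = hit_thresholds(),
                       out_dir = NULL, seed = NULL,
                       log_level = c("info", "debug", "warn", "quiet")) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  if (!inherits(thresholds, "hit_thresholds")) {
    abort_validation("thresholds must be a hit_thresholds() object")
  }
  if (mode == "simulate") {
    if (is.null(sim_params)) sim_params <- screen_sim_params()
    if (!inherits(sim_params, "screen_sim_params")) {
      abort_validation("sim_params must be a screen_sim_params() object")
    }
    if (!is.null(seed)) sim_params$seed <- as.integer(seed)
  } else {
    if (is.null(manifest_path) || is.null(counts_paths) || is.null(sheet_paths)) {
      abort_validation("files mode needs manifest_path, counts_paths and sheet_paths")
    }
    if (is.null(names(counts_paths)) || !identical(sort(names(counts_paths)),
                                                   sort(names(sheet_paths)))) {
      abort_validation("counts_paths and sheet_paths must be named by the same cell lines")
    }
  }
  structure(list(mode = mode, sim_params = sim_params,
                 manifest_path = manifest_path, counts_paths = counts_paths,
                 sheet_paths = sheet_paths, thresholds = thresholds,
                 out_dir = out_dir, seed = seed, log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; `thresholds` and `sim_params`
#' are nested maps passed to [hit_thresholds()] and [screen_sim_params()].
#' Arguments supplied directly override file values (call > file > defaults).
#'
#' @param path YAML file
#' @param ... overrides passed to [run_config()]
#' @return a `run_config` object
#' @export
read_run_config <- function(path, ...) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$thresholds)) args$thresholds <- do.call(hit_thresholds, raw$thresholds)
  if (!is.null(raw$sim_params)) args$sim_params <- do.call(screen_sim_params, raw$sim_params)
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}

analyze_one_line <- function(counts, sheet, manifest, thresholds, cell_line, cfg_log) {
  sf <- compute_size_factors(counts)
  disp <- estimate_dispersions(counts, groups = sheet$arm, sf = sf)
  res_tu <- test_contrast(counts, sheet, manifest, sf, disp,
                          reference_arm = "untreated", test_arm = "treated")
  res_t0 <- test_contrast(counts, sheet, manifest, sf, disp,
                          reference_arm = "t0", test_arm = "treated")
  primary <- call_hits_primary(res_tu, manifest, thresholds, cell_line = cell_line)
  calls <- call_hits_secondary(primary, res_t0, thresholds)
  log_msg(cfg_log, "info",
          "%s: %d/%d genes pass primary selection, %d survive the t0 filter",
          cell_line, sum(primary$is_hit), nrow(primary), sum(calls$is_hit))
  list(size_factors = sf, dispersions = disp,
       results_treated_vs_untreated = res_tu,
       results_treated_vs_t0 = res_t0,
       primary_calls = primary, calls = calls,
       volcano = volcano_table(res_tu, thresholds))
}

#' Screen-quality control separation diagnostic
#'
#' Essential-gene control hairpins should drop out of the population between
#' t=0 and the end of the screen while non-essential controls stay flat.
#' Reports median and interquartile range of the treated-vs-t0 log2 fold
#' change for each control class and their difference (essential minus
#' non-essential; negative in a healthy screen).
#'
#' @param results_t0 `hairpin_results` table for the treated-vs-t0 contrast
#' @param manifest validated library manifest
#' @return data frame with one row per control class plus a `difference`
#'   attribute; zero-row (with a warning) when the library has no controls
#' @export
summarize_controls <- function(results_t0, manifest) {
  cls <- manifest$hairpin_class[match(results_t0$hairpin_id, manifest$hairpin_id)]
  keep <- cls %in% c("essential_control", "nonessential_control")
  if (!any(keep)) {
    warning("no control hairpins in the manifest; control diagnostic unavailable")
    out <- data.frame(hairpin_class = character(0), n = integer(0),
                      median_log2fc = numeric(0), q25 = numeric(0), q75 = numeric(0))
    attr(out, "difference") <- NA_real_
    return(out)
  }
  lfc <- results_t0$log2fc[keep]
  cls <- cls[keep]
  stats_by <- function(x) c(stats::median(x), stats::quantile(x, c(0.25, 0.75)))
  tab <- t(vapply(split(lfc, cls), stats_by, numeric(3L)))
  out <- data.frame(hairpin_class = rownames(tab), n = as.integer(table(cls)[rownames(tab)]),
                    median_log2fc = tab[, 1L], q25 = tab[, 2L], q75 = tab[, 3L],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  diff <- if (all(c("essential_control", "nonessential_control") %in% out$hairpin_class)) {
    out$median_log2fc[out$hairpin_class == "essential_control"] -
      out$median_log2fc[out$hairpin_class == "nonessential_control"]
  } else NA_real_
  attr(out, "difference") <- diff
  out
}

recovery_metrics <- function(calls_by_line, truth) {
  ge <- truth$gene_effects
  per_line <- lapply(names(calls_by_line), function(cl) {
    planted <- ge$gene_symbol[ge$cell_line == cl & ge$lfc_treated_vs_untreated != 0]
    hits <- calls_by_line[[cl]]$gene_symbol[calls_by_line[[cl]]$is_hit]
    list(cell_line = cl,
         planted = sort(planted),
         recovered = sort(intersect(hits, planted)),
         missed = sort(setdiff(planted, hits)),
         spurious = sort(setdiff(hits, planted)))
  })
  names(per_line) <- names(calls_by_line)
  per_line
}

#' Run the full dropout-screen analysis
#'
#' End-to-end orchestration: obtain counts (synthetic study or files), then
#' per cell line compute size factors, dispersions, both contrasts
#' (treated-vs-untreated for hit criteria, treated-vs-t0 for the secondary
#' filter and control diagnostics), apply the two-step hit cascade, and
#' intersect hit sets across lines. When `out_dir` is set, writes per-line
#' result and gene-call tables, volcano tables, the control diagnostics, the
#' intersection report and a machine-readable JSON run report; in simulate
#' mode the report also carries planted-hit recovery metrics.
#'
#' @param config a [run_config()] object
#' @return list with `manifest`, `per_line` analysis objects, `calls_by_line`,
#'   `intersection`, `controls`, `report` (the JSON report as a list) and, in
#'   simulate mode, `truth`
#' @export
run_screen_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  lg <- config$log_level
  t_start <- Sys.time()

  if (config$mode == "simulate") {
    log_msg(lg, "info", "simulating %d-line study (seed %d)",
            length(config$sim_params$cell_lines), config$sim_params$seed)
    study <- simulate_three_line_study(config$sim_params)
    manifest <- study$manifest
    line_data <- lapply(study$lines, function(l) l[c("counts", "sheet")])
    truth <- study$truth
  } else {
    log_msg(lg, "info", "reading screen artifacts from files")
    manifest <- read_manifest(config$manifest_path)
    line_data <- lapply(names(config$counts_paths), function(cl) {
      sheet <- read_sample_sheet(config$sheet_paths[[cl]])
      list(counts = read_counts(config$counts_paths[[cl]], manifest, sheet),
           sheet = sheet)
    })
    names(line_data) <- names(config$counts_paths)
    truth <- NULL
  }

  per_line <- lapply(names(line_data), function(cl) {
    analyze_one_line(line_data[[cl]]$counts, line_data[[cl]]$sheet,
                     manifest, config$thresholds, cl, lg)
  })
  names(per_line) <- names(line_data)
  calls_by_line <- lapply(per_line, `[[`, "calls")

  intersection <- if (length(per_line) >= 2L) intersect_hits(calls_by_line) else NULL
  controls <- lapply(per_line, function(x) {
    summarize_controls(x$results_treated_vs_t0, manifest)
  })

  report <- list(
    package_version = as.character(utils::packageVersion("dropscreen")),
    mode = config$mode,
    seed = if (config$mode == "simulate") config$sim_params$seed else config$seed,
    thresholds = unclass(config$thresholds),
    cell_lines = names(line_data),
    n_hairpins = nrow(manifest),
    n_targeting_genes = length(unique(manifest$gene_symbol[manifest$hairpin_class == "targeting"])),
    hits_per_line = lapply(calls_by_line, function(gc) sort(gc$gene_symbol[gc$is_hit])),
    shared_hits = if (is.null(intersection)) NULL else intersection$shared_genes,
    control_separation = lapply(controls, function(x) attr(x, "difference"))
  )
  if (config$mode == "simulate") {
    report$sim_params <- unclass(config$sim_params)
    report$recovery <- recovery_metrics(calls_by_line, truth)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cl in names(per_line)) {
      x <- per_line[[cl]]
      write_results(x$results_treated_vs_untreated,
                    file.path(config$out_dir, paste0(cl, "_treated_vs_untreated.tsv")))
      write_results(x$results_treated_vs_t0,
                    file.path(config$out_dir, paste0(cl, "_treated_vs_t0.tsv")))
      write_results(x$calls, file.path(config$out_dir, paste0(cl, "_gene_calls.tsv")))
      write_results(x$volcano, file.path(config$out_dir, paste0(cl, "_volcano.tsv")))
      if (nrow(controls[[cl]]) > 0L) {
        write_results(controls[[cl]], file.path(config$out_dir, paste0(cl, "_controls.tsv")))
      }
    }
    if (!is.null(intersection)) {
      jsonlite::write_json(intersection, file.path(config$out_dir, "intersection.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_msg(lg, "info", "wrote outputs to %s", config$out_dir)
  }
  log_msg(lg, "info", "analysis finished in %.1f s",
          as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  out <- list(manifest = manifest, per_line = per_line, calls_by_line = calls_by_line,
              intersection = intersection, controls = controls, report = report)
  if (config$mode == "simulate") out$truth <- truth
  out
}
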