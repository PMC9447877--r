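#' @keywords internal
GENE_CLASSES <- c("kinase", "kinase_related", "control")

#' @keywords internal
HAIRPIN_CLASSES <- c("targeting", "essential_control", "nonessential_control")

#' @keywords internal
ARMS <- c("t0", "untreated", "treated")

abort_validation <- function(msg) {
  stop(structure(class = c("dropscreen_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_format <- function(msg) {
  stop(structure(class = c("dropscreen_format_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Read a delimited table, auto-detecting tab vs comma from the header line.
read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    stop(structure(class = c("dropscreen_io_error", "error", "condition"),
                   list(message = sprintf("file not found: %s", path), call = NULL)))
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort_format(sprintf("%s is missing required column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
}

#' Canonical hairpin ordering
#'
#' Hairpins are ordered by (gene_symbol, hairpin_id) so that all tabular
#' artifacts are deterministic regardless of input row order.
#' @param manifest a library manifest data frame
#' @return the manifest with rows in canonical order
#' @keywords internal
canonicalize_manifest <- function(manifest) {
  manifest[order(manifest$gene_symbol, manifest$hairpin_id), , drop = FALSE]
}

#' @keywords internal
canonicalize_sheet <- function(sheet) {
  arm_rank <- match(sheet$arm, ARMS)
  sheet[order(sheet$cell_line, arm_rank, sheet$replicate), , drop = FALSE]
}

#' Validate a hairpin library manifest
#'
#' Checks the invariants of the hairpin-to-gene map: unique hairpin ids,
#' one gene per hairpin, legal class labels, and the correspondence between
#' control hairpin classes and the `control` gene class (essential and
#' non-essential control hairpins are spike-in controls, never callable hits).
#'
#' @param manifest data frame with columns `hairpin_id`, `gene_symbol`,
#'   `gene_class` (kinase / kinase_related / control) and `hairpin_class`
#'   (targeting / essential_control / nonessential_control)
#' @return the validated manifest in canonical (gene, hairpin) order
#' @export
validate_manifest <- function(manifest) {
  require_columns(manifest, c("hairpin_id", "gene_symbol", "gene_class", "hairpin_class"),
                  "library manifest")
  manifest$hairpin_id <- as.character(manifest$hairpin_id)
  manifest$gene_symbol <- as.character(manifest$gene_symbol)
  dup <- unique(manifest$hairpin_id[duplicated(manifest$hairpin_id)])
  if (length(dup) > 0L) {
    abort_validation(sprintf("duplicate hairpin_id(s): %s", paste(dup, collapse = ", ")))
  }
  bad_gc <- setdiff(unique(manifest$gene_class), GENE_CLASSES)
  if (length(bad_gc) > 0L) {
    abort_validation(sprintf("unknown gene_class value(s): %s", paste(bad_gc, collapse = ", ")))
  }
  bad_hc <- setdiff(unique(manifest$hairpin_class), HAIRPIN_CLASSES)
  if (length(bad_hc) > 0L) {
    abort_validation(sprintf("unknown hairpin_class value(s): %s", paste(bad_hc, collapse = ", ")))
  }
  is_ctrl_hp <- manifest$hairpin_class %in% c("essential_control", "nonessential_control")
  is_ctrl_gene <- manifest$gene_class == "control"
  if (any(is_ctrl_hp != is_ctrl_gene)) {
    abort_validation("control hairpin classes must pair with gene_class 'control' and vice versa")
  }
  # a gene must not span multiple classes
  cls_per_gene <- tapply(manifest$gene_class, manifest$gene_symbol,
                         function(x) length(unique(x)))
  if (any(cls_per_gene > 1L)) {
    abort_validation(sprintf("gene(s) with conflicting gene_class: %s",
                             paste(names(cls_per_gene)[cls_per_gene > 1L], collapse = ", ")))
  }
  out <- canonicalize_manifest(manifest[, c("hairpin_id", "gene_symbol",
                                            "gene_class", "hairpin_class")])
  rownames(out) <- NULL
  out
}

#' Read a library manifest from a TSV/CSV file
#'
#' @param path path to a tab- or comma-separated file with header columns
#'   `hairpin_id`, `gene_symbol`, `gene_class`, `hairpin_class`
#' @return validated manifest data frame in canonical order
#' @seealso [validate_manifest()]
#' @export
read_manifest <- function(path) {
  validate_manifest(read_delim_auto(path))
}

#' Validate a screen sample sheet
#'
#' A sample sheet names the sequencing samples of a screen: the t=0 reference
#' arm collected at infection, and the untreated / treated end arms, with one
#' or more replicates each per cell line.
#'
#' @param sheet data frame with columns `sample_id`, `cell_line`, `arm`
#'   (t0 / untreated / treated), `replicate`
#' @return validated sheet in canonical (cell_line, arm, replicate) order
#' @export
validate_sample_sheet <- function(sheet) {
  require_columns(sheet, c("sample_id", "cell_line", "arm", "replicate"), "sample sheet")
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$cell_line <- as.character(sheet$cell_line)
  sheet$arm <- as.character(sheet$arm)
  dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
  if (length(dup) > 0L) {
    abort_validation(sprintf("duplicate sample_id(s): %s", paste(dup, collapse = ", ")))
  }
  bad_arm <- setdiff(unique(sheet$arm), ARMS)
  if (length(bad_arm) > 0L) {
    abort_validation(sprintf("unknown arm label(s): %s (allowed: %s)",
                             paste(bad_arm, collapse = ", "), paste(ARMS, collapse = ", ")))
  }
  rep_num <- suppressWarnings(as.integer(sheet$replicate))
  if (any(is.na(rep_num)) || any(rep_num < 1L)) {
    abort_validation("replicate must be a positive integer for every sample")
  }
  sheet$replicate <- rep_num
  out <- canonicalize_sheet(sheet[, c("sample_id", "cell_line", "arm", "replicate")])
  rownames(out) <- NULL
  out
}

#' Read a sample sheet from a TSV/CSV file
#' @param path path to a delimited file with header columns `sample_id`,
#'   `cell_line`, `arm`, `replicate`
#' @return validated sample sheet data frame
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(read_delim_auto(path))
}

#' Validate a hairpin count matrix against a manifest and sample sheet
#'
#' Counts must be non-negative integers (dropout screens report zero, never
#' missing) and the row/column label sets must match the manifest and sheet
#' exactly. Rows and columns are returned in canonical order.
#'
#' @param counts numeric matrix, hairpins x samples, with dimnames
#' @param manifest validated library manifest
#' @param sheet validated sample sheet
#' @return integer matrix aligned to the manifest and sheet order
#' @export
validate_count_matrix <- function(counts, manifest, sheet) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_validation("count matrix must have hairpin rownames and sample colnames")
  }
  extra_hp <- setdiff(rownames(counts), manifest$hairpin_id)
  if (length(extra_hp) > 0L) {
    abort_validation(sprintf("hairpin(s) not in manifest: %s",
                             paste(utils::head(extra_hp, 5L), collapse = ", ")))
  }
  missing_hp <- setdiff(manifest$hairpin_id, rownames(counts))
  if (length(missing_hp) > 0L) {
    abort_validation(sprintf("manifest hairpin(s) missing from counts: %s",
                             paste(utils::head(missing_hp, 5L), collapse = ", ")))
  }
  extra_s <- setdiff(colnames(counts), sheet$sample_id)
  if (length(extra_s) > 0L) {
    abort_validation(sprintf("sample(s) not in sheet: %s", paste(extra_s, collapse = ", ")))
  }
  missing_s <- setdiff(sheet$sample_id, colnames(counts))
  if (length(missing_s) > 0L) {
    abort_validation(sprintf("sheet sample(s) missing from counts: %s",
                             paste(missing_s, collapse = ", ")))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort_validation(sprintf(
      "counts must be non-negative integers; first offender at hairpin '%s', sample '%s'",
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  }
  out <- counts[manifest$hairpin_id, sheet$sample_id, drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Read a hairpin count matrix
#'
#' The file's first column must be `hairpin_id`; the remaining columns are
#' sample ids. Unknown hairpins or samples are rejected.
#'
#' @inheritParams validate_count_matrix
#' @param path path to a delimited count table
#' @return validated integer count matrix (hairpins x samples)
#' @export
read_counts <- function(path, manifest, sheet) {
  df <- read_delim_auto(path)
  if (names(df)[1L] != "hairpin_id") {
    abort_format("first column of a count table must be 'hairpin_id'")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df$hairpin_id)
  validate_count_matrix(m, manifest, sheet)
}

#' Write a results table to TSV
#'
#' Writes per-hairpin results or gene-call tables as tab-separated text with
#' a stable column order; numeric fields are rendered at full double
#' precision so that a write/read round trip preserves them to at least 12
#' significant digits.
#'
#' @param results non-empty data frame
#' @param path output path
#' @return invisibly, the path
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    abort_validation("results table must be a non-empty data frame")
  }
  con <- tryCatch(suppressWarnings(file(path, open = "wt")), error = function(e) {
    stop(structure(class = c("dropscreen_io_error", "error", "condition"),
                   list(message = sprintf("cannot write to '%s': %s", path,
                                          conditionMessage(e)), call = NULL)))
  })
  on.exit(close(con))
  out <- results
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15L, trim = TRUE,
                                                  scientific = FALSE))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path path to a TSV results table
#' @return data frame
#' @export
read_results <- function(path) {
  read_delim_auto(path)
}
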