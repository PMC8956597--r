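# The log2 feature x sample quantitative matrix and its normalization
# stages. Two routes mirror the two comparison modes:
#   group route:      log2 -> reference_subtract -> median_center ->
#                     batch_presence_filter -> impute_min -> combat_correct
#   individual route: log2 -> median centering of clinical channels only.

STAGES <- c("raw", "raw_log2", "ref_subtracted", "median_centered",
            "imputed", "batch_corrected")

new_quant_matrix <- function(values, design, stage) {
  stopifnot(is.matrix(values), ncol(values) == nrow(design),
            stage %in% STAGES)
  colnames(values) <- design$sample_id
  structure(list(values = values, design = design, stage = stage),
            class = "quant_matrix")
}

advance_stage <- function(qm, from, to) {
  if (!qm$stage %in% from)
    stopf("stage '%s' cannot follow '%s' (expected %s)",
          to, qm$stage, paste(from, collapse = " or "))
  qm$stage <- to
  qm
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d features x %d samples, stage '%s'\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Assemble a raw reporter-intensity matrix from a site or protein table
#'
#' Rows are features keyed by `gene_residuePosition` (see [site_key()]);
#' columns are the design samples (references included). Duplicate keys are
#' disambiguated with `make.unique()`.
#'
#' @param x a filtered `site_table` or `protein_table`.
#' @param design the `study_design`.
#' @return a `quant_matrix` at stage `"raw"` (linear intensities).
#' @export
build_quant_matrix <- function(x, design) {
  ch <- attr(x, "channels")
  keys <- if (!is.null(x$site_id))
    site_key(x$gene, x$residue, x$position, x$protein)
  else x$protein_group_id
  vals <- as.matrix(x[ch$col])
  rownames(vals) <- make.unique(keys, sep = ".dup")
  d <- design[match(ch$sample_id, design$sample_id), , drop = FALSE]
  rownames(d) <- NULL
  new_quant_matrix(vals, d, "raw")
}

#' Normalization steps
#'
#' `log2_transform()` log2-transforms positive intensities (missing stays
#' missing). `reference_subtract()` subtracts, per batch and feature, the
#' mean of the observed pooled-reference channels from every clinical
#' channel of that batch, then drops the reference channels; where no
#' reference value was observed the clinical values become missing (the
#' ratio is undefined). `median_center()` subtracts each column's observed
#' median. `batch_presence_filter()` keeps features quantified in at least
#' one sample of every batch. `impute_min()` replaces each remaining
#' missing cell by the feature's minimum observed value (left-censoring
#' surrogate).
#'
#' @param qm a `quant_matrix`.
#' @return the transformed `quant_matrix` with its stage tag advanced.
#' @name normalize_steps
NULL

#' @rdname normalize_steps
#' @export
log2_transform <- function(qm) {
  qm <- advance_stage(qm, "raw", "raw_log2")
  if (any(qm$values <= 0, na.rm = TRUE))
    stopf("log2_transform: non-positive intensity present")
  qm$values <- log2(qm$values)
  qm
}

#' @rdname normalize_steps
#' @export
reference_subtract <- function(qm) {
  qm <- advance_stage(qm, "raw_log2", "ref_subtracted")
  d <- qm$design
  if (!any(d$is_reference)) stopf("design has no reference channels")
  v <- qm$values
  out <- v[, !d$is_reference, drop = FALSE]
  for (b in unique(d$batch_id)) {
    refs <- which(d$is_reference & d$batch_id == b)
    if (!length(refs)) stopf("batch %s has no reference channel", b)
    ref_mean <- rowMeans(v[, refs, drop = FALSE], na.rm = TRUE)
    ref_mean[is.nan(ref_mean)] <- NA_real_
    cl <- which(d$batch_id[!d$is_reference] == b)
    out[, cl] <- out[, cl, drop = FALSE] - ref_mean
  }
  qm$design <- d[!d$is_reference, , drop = FALSE]
  rownames(qm$design) <- NULL
  qm$values <- out
  qm
}

#' @rdname normalize_steps
#' @export
median_center <- function(qm) {
  v <- qm$values
  for (j in seq_len(ncol(v))) {
    obs <- !is.na(v[, j])
    if (!any(obs)) {
      warnf("median_center: column '%s' has no observed values; left unchanged",
            colnames(v)[j])
      next
    }
    v[, j] <- v[, j] - stats::median(v[obs, j])
  }
  qm$values <- v
  qm <- advance_stage(qm, c("raw_log2", "ref_subtracted"), "median_centered")
  qm
}

#' @rdname normalize_steps
#' @export
batch_presence_filter <- function(qm) {
  d <- qm$design
  keep <- rep(TRUE, nrow(qm$values))
  for (b in unique(d$batch_id)) {
    cols <- d$batch_id == b
    keep <- keep & rowSums(!is.na(qm$values[, cols, drop = FALSE])) > 0
  }
  qm$values <- qm$values[keep, , drop = FALSE]
  qm
}

#' @rdname normalize_steps
#' @export
impute_min <- function(qm) {
  v <- qm$values
  na_rows <- which(rowSums(!is.na(v)) == 0L)
  if (length(na_rows)) {
    label <- if (is.null(rownames(v))) as.character(na_rows[1])
    else rownames(v)[na_rows[1]]
    stopf("impute_min: feature '%s' has no observed value; run batch_presence_filter first",
          label)
  }
  mins <- apply(v, 1L, min, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- mins[idx[, 1L]]
  qm$values <- v
  advance_stage(qm, c("median_centered", "ref_subtracted", "raw_log2"),
                "imputed")
}

#' Individual-comparison normalization
#'
#' The single-patient route: clinical channels only, median centering per
#' TMT channel — no reference subtraction, no imputation, no batch
#' correction.
#'
#' @param qm a `quant_matrix` at stage `raw_log2`.
#' @return a `quant_matrix` at stage `median_centered` over clinical
#'   samples only.
#' @export
normalize_for_individual <- function(qm) {
  stopifnot(qm$stage == "raw_log2")
  keep <- !qm$design$is_reference
  qm$values <- qm$values[, keep, drop = FALSE]
  qm$design <- qm$design[keep, , drop = FALSE]
  rownames(qm$design) <- NULL
  median_center(qm)
}

#' Group-comparison normalization route
#'
#' Convenience wrapper running the full group route on a raw
#' `quant_matrix`: log2, reference subtraction, per-channel median
#' centering, per-batch presence filter, minimum imputation, and
#' empirical-Bayes batch correction.
#'
#' @param qm a `quant_matrix` at stage `"raw"`.
#' @param eb use empirical-Bayes shrinkage in the batch correction.
#' @return list with `matrix` (stage `batch_corrected`) and `model`
#'   (the fitted [combat_correct()] `batch_model`).
#' @export
normalize_group_route <- function(qm, eb = TRUE) {
  qm <- log2_transform(qm)
  qm <- reference_subtract(qm)
  qm <- median_center(qm)
  qm <- batch_presence_filter(qm)
  qm <- impute_min(qm)
  combat_correct(qm, eb = eb)
}

#' Serialize / restore a quant_matrix
#'
#' Values go to a TSV (`feature` column + one column per sample); stage and
#' design travel in a JSON sidecar at `<path>.json`.
#'
#' @param qm a `quant_matrix`.
#' @param path TSV path.
#' @export
write_quant_matrix <- function(qm, path) {
  df <- data.frame(feature = rownames(qm$values), qm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  jsonlite::write_json(list(stage = qm$stage, design = qm$design),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_quant_matrix
#' @return `read_quant_matrix()`: the restored `quant_matrix`.
#' @export
read_quant_matrix <- function(path) {
  df <- read_tsv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$feature
  d <- as.data.frame(side$design, stringsAsFactors = FALSE)
  new_quant_matrix(v, d, side$stage)
}
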