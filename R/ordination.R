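# PCA quality control of the batch-corrected matrix (sample separation by
# group/treatment, as in the study's phosphoproteomic PCA panels).

#' Principal component analysis of a quant_matrix
#'
#' Samples are observations, features are variables; features are centered
#' but not scaled. Features with a missing value over the selected samples
#' are dropped (complete-case); the batch-corrected, imputed matrix is
#' complete by construction. Loading signs are fixed so each component's
#' largest-magnitude loading is positive.
#'
#' @param qm a `quant_matrix`.
#' @param samples optional character vector restricting to these sample
#'   ids (e.g. tumor samples only).
#' @param n_components number of components to keep (default: all
#'   `min(n_samples - 1, n_features)`).
#' @return list of class `pca_result`: `scores` (sample x component),
#'   `loadings` (feature x component, orthonormal), `explained`
#'   (variance fractions), `n_features`.
#' @export
pca_qc <- function(qm, samples = NULL, n_components = NULL) {
  v <- qm$values
  if (!is.null(samples)) {
    unknown <- setdiff(samples, colnames(v))
    if (length(unknown)) stopf("unknown sample id '%s'", unknown[1])
    v <- v[, samples, drop = FALSE]
  }
  if (ncol(v) < 2L) stopf("pca_qc: need at least 2 samples")
  v <- v[stats::complete.cases(v), , drop = FALSE]
  if (!nrow(v)) stopf("pca_qc: no complete-case feature")
  max_comp <- min(ncol(v) - 1L, nrow(v))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp)
    stopf("n_components (%d) exceeds min(n_samples - 1, n_features) = %d",
          n_components, max_comp)
  fit <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  scores <- fit$x[, keep, drop = FALSE]
  loadings <- fit$rotation[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in keep) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  explained <- (fit$sdev^2 / sum(fit$sdev^2))[keep]
  structure(list(scores = scores, loadings = loadings,
                 explained = explained, center = fit$center,
                 n_features = nrow(v)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d sample(s), %d feature(s); explained: %s\n",
              nrow(x$scores), x$n_features,
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = " ")))
  invisible(x)
}
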