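# Parametric empirical-Bayes location/scale batch correction for the
# imputed log2 matrix. Model per feature f, batch b, sample s:
#   x_fbs = alpha_f + gamma_bf + delta_bf * eps_fbs
# Features are standardized with the grand mean and pooled variance from an
# intercept-only model; per-batch location (gamma) and scale (delta^2)
# estimates are shrunk toward moment-matched priors (normal / inverse-gamma
# fitted across features within each batch) by iterated conditional
# posterior means, and the adjusted data are back-transformed.

row_group_means <- function(x, idx) rowMeans(x[, idx, drop = FALSE])

row_group_vars <- function(x, idx) {
  n <- length(idx)
  m <- rowMeans(x[, idx, drop = FALSE])
  (rowSums(x[, idx, drop = FALSE]^2) - n * m^2) / (n - 1)
}

#' Empirical-Bayes batch correction
#'
#' Removes per-batch additive and multiplicative effects from a complete
#' (imputed) log2 `quant_matrix`, with parametric empirical-Bayes shrinkage
#' of the per-batch per-feature location and scale estimates. With
#' `eb = FALSE` the raw per-batch estimates are used, which reduces to the
#' per-batch standardization closed form. A single-batch input is returned
#' unchanged with an identity model.
#'
#' @param qm a `quant_matrix` with no missing values (stage `imputed`, or
#'   any complete matrix).
#' @param eb apply empirical-Bayes shrinkage (default `TRUE`).
#' @param conv relative convergence tolerance of the EB iterations.
#' @param max_iter maximum EB iterations per batch.
#' @return list with `matrix` (the corrected `quant_matrix`, stage
#'   `batch_corrected`) and `model` (a `batch_model`: per-batch `gamma_hat`,
#'   `delta_hat`, posterior `gamma_star`, `delta_star`, `grand_mean`,
#'   `pooled_var`, and the fitted prior hyperparameters).
#' @export
combat_correct <- function(qm, eb = TRUE, conv = 1e-6, max_iter = 200L) {
  x <- qm$values
  if (anyNA(x)) stopf("combat_correct: matrix contains missing values; impute first")
  batch <- qm$design$batch_id
  blev <- unique(batch)
  nb <- length(blev)
  if (nb == 1L) {
    model <- structure(list(
      batches = blev, eb = eb,
      gamma_hat = matrix(0, nrow(x), 1, dimnames = list(rownames(x), blev)),
      delta_hat = matrix(1, nrow(x), 1, dimnames = list(rownames(x), blev)),
      gamma_star = matrix(0, nrow(x), 1, dimnames = list(rownames(x), blev)),
      delta_star = matrix(1, nrow(x), 1, dimnames = list(rownames(x), blev)),
      grand_mean = rowMeans(x), pooled_var = rep(1, nrow(x)),
      priors = NULL, iterations = integer(0)), class = "batch_model")
    qm$stage <- "batch_corrected"
    return(list(matrix = qm, model = model))
  }
  idx <- lapply(blev, function(b) which(batch == b))
  ns <- lengths(idx)
  if (any(ns < 2L))
    stopf("combat_correct: batch %s has fewer than 2 samples; scale not estimable",
          blev[ns < 2L][1])
  n <- ncol(x)

  # Intercept-only standardization: weighted grand mean + pooled variance.
  bhat <- vapply(idx, function(i) row_group_means(x, i), numeric(nrow(x)))
  grand <- as.vector(bhat %*% (ns / n))
  fitted <- bhat[, match(batch, blev), drop = FALSE]
  var_pooled <- rowSums((x - fitted)^2) / n
  if (any(var_pooled <= 0))
    stopf("combat_correct: feature '%s' has zero pooled variance",
          rownames(x)[var_pooled <= 0][1])
  sdat <- (x - grand) / sqrt(var_pooled)

  gamma_hat <- vapply(idx, function(i) row_group_means(sdat, i),
                      numeric(nrow(x)))
  delta_hat <- vapply(idx, function(i) row_group_vars(sdat, i),
                      numeric(nrow(x)))
  dimnames(gamma_hat) <- dimnames(delta_hat) <- list(rownames(x), blev)

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  priors <- NULL
  iters <- integer(nb)
  if (eb) {
    priors <- vector("list", nb)
    names(priors) <- blev
    for (k in seq_len(nb)) {
      g <- gamma_hat[, k]; d <- delta_hat[, k]
      gbar <- mean(g); t2 <- stats::var(g)
      m <- mean(d); s2 <- stats::var(d)
      a_pr <- (2 * s2 + m^2) / s2
      b_pr <- (m * s2 + m^3) / s2
      priors[[k]] <- list(gamma_bar = gbar, tau2 = t2,
                          a_prior = a_pr, b_prior = b_pr)
      sb <- sdat[, idx[[k]], drop = FALSE]
      nk <- ns[k]
      g_old <- g; d_old <- d
      it <- 0L
      repeat {
        it <- it + 1L
        g_new <- (t2 * nk * g + d_old * gbar) / (t2 * nk + d_old)
        sum2 <- rowSums((sb - g_new)^2)
        d_new <- (0.5 * sum2 + b_pr) / (nk / 2 + a_pr - 1)
        change <- max(abs((g_new - g_old) / g_old),
                      abs((d_new - d_old) / d_old))
        g_old <- g_new; d_old <- d_new
        if (change < conv) break
        if (it >= max_iter)
          stopf("combat_correct: EB iterations did not converge for batch %s (max change %.3g)",
                blev[k], change)
      }
      iters[k] <- it
      gamma_star[, k] <- g_old
      delta_star[, k] <- d_old
    }
  }

  adj <- sdat
  for (k in seq_len(nb)) {
    i <- idx[[k]]
    adj[, i] <- (sdat[, i, drop = FALSE] - gamma_star[, k]) /
      sqrt(delta_star[, k])
  }
  qm$values <- adj * sqrt(var_pooled) + grand
  qm$stage <- "batch_corrected"
  model <- structure(list(
    batches = blev, eb = eb, gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star, grand_mean = grand,
    pooled_var = var_pooled, priors = priors, iterations = iters),
    class = "batch_model")
  list(matrix = qm, model = model)
}

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("batch_model: %d batch(es), %d features, EB shrinkage %s\n",
              length(x$batches), length(x$grand_mean),
              if (isTRUE(x$eb)) "on" else "off"))
  invisible(x)
}

#' Per-feature batch R-squared
#'
#' Mean fraction of per-feature variance explained by the batch factor
#' (one-way ANOVA R^2), computed over observed values. Used to quantify
#' how much batch signal a correction removed.
#'
#' @param qm a `quant_matrix`.
#' @return mean R^2 across features with at least one observation per batch
#'   and non-zero total variance.
#' @export
batch_r2 <- function(qm) {
  x <- qm$values
  batch <- factor(qm$design$batch_id)
  r2 <- apply(x, 1L, function(v) {
    obs <- !is.na(v)
    if (length(unique(batch[obs])) < 2L) return(NA_real_)
    tot <- sum((v[obs] - mean(v[obs]))^2)
    if (tot == 0) return(NA_real_)
    gm <- tapply(v[obs], batch[obs], mean)
    within <- sum((v[obs] - gm[as.character(batch[obs])])^2)
    1 - within / tot
  })
  mean(r2, na.rm = TRUE)
}
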