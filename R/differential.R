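# Per-phosphosite contrasts: group-level Welch or paired t with the
# significance/tendency classification, single-patient fold-change-only
# comparisons, and pathway node-status overlays.

row_mean_var_n <- function(x) {
  obs <- !is.na(x)
  n <- rowSums(obs)
  m <- rowSums(x, na.rm = TRUE) / n
  v <- (rowSums(x^2, na.rm = TRUE) - n * m^2) / (n - 1)
  v[n < 2] <- NA_real_
  list(mean = m, var = pmax(v, 0), n = n)
}

#' Group-level differential phosphosite test
#'
#' Computes, per feature, `log2FC = mean(A) - mean(B)` and a two-sided
#' Welch t-test (Satterthwaite degrees of freedom) or paired t-test on
#' per-patient differences, then attaches significance classes via
#' [classify_sites()]. Paired mode matches samples 1-1 by `patient_id`
#' from the design. Features where both groups have zero variance report
#' `p = 1` when the means agree and are flagged `not_testable` otherwise.
#'
#' @param qm a batch-corrected `quant_matrix` (group route).
#' @param samplesA,samplesB character vectors of sample ids (group A and B).
#' @param mode `"welch"` or `"paired"`.
#' @param contrast optional contrast name stored as an attribute.
#' @param ... thresholds passed to [classify_sites()].
#' @return data.frame (class `comparison_result`) with `feature`, `log2FC`,
#'   `t`, `df`, `p`, `class`.
#' @export
group_compare <- function(qm, samplesA, samplesB,
                          mode = c("welch", "paired"), contrast = NULL, ...) {
  mode <- match.arg(mode)
  v <- qm$values
  missA <- setdiff(samplesA, colnames(v))
  missB <- setdiff(samplesB, colnames(v))
  if (length(missA) || length(missB))
    stopf("unknown sample id(s): %s",
          paste(c(missA, missB), collapse = ", "))
  A <- v[, samplesA, drop = FALSE]
  B <- v[, samplesB, drop = FALSE]
  eps <- .Machine$double.eps
  if (mode == "welch") {
    if (length(samplesA) < 2L || length(samplesB) < 2L)
      stopf("welch mode needs >= 2 samples per group")
    sa <- row_mean_var_n(A); sb <- row_mean_var_n(B)
    fc <- sa$mean - sb$mean
    se2 <- sa$var / sa$n + sb$var / sb$n
    tt <- fc / sqrt(se2)
    df <- se2^2 / ((sa$var / sa$n)^2 / (sa$n - 1) +
                   (sb$var / sb$n)^2 / (sb$n - 1))
    degen <- !is.na(se2) & se2 == 0
    p <- 2 * stats::pt(-abs(tt), df)
    tt[degen & abs(fc) < eps] <- 0
    p[degen & abs(fc) < eps] <- 1
    df[degen] <- NA_real_
    p[degen & abs(fc) >= eps] <- NA_real_
    tt[degen & abs(fc) >= eps] <- NA_real_
  } else {
    if (any(samplesA %in% samplesB))
      stopf("paired mode requires disjoint groups matched 1-1 by patient_id")
    d <- qm$design
    patA <- d$patient_id[match(samplesA, d$sample_id)]
    patB <- d$patient_id[match(samplesB, d$sample_id)]
    if (anyNA(patA) || anyNA(patB) || anyDuplicated(patA) ||
        anyDuplicated(patB) || !setequal(patA, patB))
      stopf("paired mode requires groups matched 1-1 by patient_id")
    if (length(samplesA) < 2L) stopf("paired mode needs >= 2 pairs")
    B <- B[, match(patA, patB), drop = FALSE]
    D <- A - B
    sd_ <- row_mean_var_n(D)
    fc <- sd_$mean
    tt <- fc / sqrt(sd_$var / sd_$n)
    df <- rep(length(samplesA) - 1, nrow(D))
    degen <- !is.na(sd_$var) & sd_$var == 0
    p <- 2 * stats::pt(-abs(tt), df)
    tt[degen & abs(fc) < eps] <- 0
    p[degen & abs(fc) < eps] <- 1
    df[degen] <- NA_real_
    p[degen & abs(fc) >= eps] <- NA_real_
    tt[degen & abs(fc) >= eps] <- NA_real_
  }
  res <- data.frame(feature = rownames(v), log2FC = fc, t = tt, df = df,
                    p = p, stringsAsFactors = FALSE, row.names = NULL)
  res <- classify_sites(res, ...)
  attr(res, "contrast") <- contrast
  attr(res, "mode") <- mode
  class(res) <- c("comparison_result", "data.frame")
  res
}

#' Classify differential phosphosites
#'
#' Applies the significance/tendency rule: a site is significant when
#' `|log2FC| > fc_cut` (strict) and `p < p_sig`; a tendency when
#' `|log2FC| > fc_cut` and `p_sig <= p < p_tend`; direction follows the
#' fold-change sign. Sites with no computable p are `not_testable`;
#' everything else is `ns`.
#'
#' @param res a comparison result data.frame with `log2FC` and `p`.
#' @param fc_cut absolute log2 fold-change cut-off (default 1).
#' @param p_sig significance p threshold (default 0.05).
#' @param p_tend tendency p upper bound (default 0.1).
#' @return `res` with the `class` column (re)computed.
#' @export
classify_sites <- function(res, fc_cut = 1, p_sig = 0.05, p_tend = 0.1) {
  stopifnot(fc_cut > 0, p_sig > 0, p_sig < p_tend, p_tend <= 1)
  cls <- rep("ns", nrow(res))
  big <- !is.na(res$log2FC) & abs(res$log2FC) > fc_cut
  sig <- big & !is.na(res$p) & res$p < p_sig
  tend <- big & !is.na(res$p) & res$p >= p_sig & res$p < p_tend
  up <- res$log2FC > 0
  cls[sig & up] <- "significant_up"
  cls[sig & !up] <- "significant_down"
  cls[tend & up] <- "tendency_up"
  cls[tend & !up] <- "tendency_down"
  cls[is.na(res$p)] <- "not_testable"
  res$class <- cls
  res
}

#' Single-patient comparison
#'
#' Fold-change-only contrast between two individual samples on the
#' individually normalized matrix: `log2FC = value(A) - value(B)` per site;
#' sites missing in either sample carry no quantitative value.
#'
#' @param qm the individually normalized `quant_matrix`
#'   (see [normalize_for_individual()]).
#' @param sampleA,sampleB sample ids.
#' @param fc_cut absolute log2FC flag threshold (default 1).
#' @return data.frame with `feature`, `log2FC` (`NA` when not
#'   co-quantified), `quantified`, `flagged`.
#' @export
individual_compare <- function(qm, sampleA, sampleB, fc_cut = 1) {
  v <- qm$values
  for (s in c(sampleA, sampleB))
    if (!s %in% colnames(v)) stopf("unknown sample id '%s'", s)
  fc <- v[, sampleA] - v[, sampleB]
  quantified <- !is.na(fc)
  data.frame(feature = rownames(v), log2FC = fc, quantified = quantified,
             flagged = quantified & abs(fc) > fc_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}

feature_gene <- function(feature) {
  sub("_[STY][0-9]+(\\.dup[0-9]*)?$", "", feature)
}

#' Pathway node-status overlay
#'
#' Annotates each pathway node gene with the strongest differential state
#' among its quantified phosphosites (precedence: significant > tendency >
#' quantified_only); nodes without any quantified site are
#' `not_quantified`. Accepts a group [group_compare()] result (class
#' column) or an [individual_compare()] table, where flagged sites
#' (`|log2FC|` above the cut) rank as significant.
#'
#' @param res a comparison result or individual comparison table.
#' @param pathway data.frame with columns `pathway_id` and `gene`, or a
#'   character vector of node genes (single unnamed pathway).
#' @return data.frame with `pathway_id`, `gene`, `state`, `n_sites`,
#'   `sites` (`;`-separated `key:log2FC` of quantified sites).
#' @export
pathway_overlay <- function(res, pathway) {
  if (is.character(pathway))
    pathway <- data.frame(pathway_id = "pathway", gene = pathway,
                          stringsAsFactors = FALSE)
  if (nrow(pathway) == 0L)
    return(data.frame(pathway_id = character(), gene = character(),
                      state = character(), n_sites = integer(),
                      sites = character(), stringsAsFactors = FALSE))
  if (!is.null(res$class)) {
    rank <- ifelse(res$class %in% c("significant_up", "significant_down"), 3L,
            ifelse(res$class %in% c("tendency_up", "tendency_down"), 2L, 1L))
    quant <- rep(TRUE, nrow(res))
  } else {
    rank <- ifelse(res$flagged, 3L, 1L)
    quant <- res$quantified
  }
  gene <- feature_gene(res$feature)
  out <- pathway
  out$state <- "not_quantified"
  out$n_sites <- 0L
  out$sites <- ""
  states <- c("quantified_only", "tendency", "significant")
  for (i in seq_len(nrow(out))) {
    hit <- which(gene == out$gene[i] & quant)
    if (!length(hit)) next
    out$state[i] <- states[max(rank[hit])]
    out$n_sites[i] <- length(hit)
    out$sites[i] <- paste0(res$feature[hit], ":",
                           signif(res$log2FC[hit], 6), collapse = ";")
  }
  out
}
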