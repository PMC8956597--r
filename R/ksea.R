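# Substrate-set kinase-activity inference (KSEA): a kinase's activity in a
# comparison is scored by the mean log2 fold-change of its quantified
# substrate phosphosites against the background of all quantified sites,
#   z = (mean_sub - mean_all) * sqrt(m) / sd_all,
# with a two-sided normal p. Kinases with fewer than `min_substrates`
# quantified substrate sites in a comparison are not scored.

#' Read a kinase-substrate relationship table
#'
#' TSV with one edge per row: kinase symbol, substrate gene symbol, and the
#' substrate site as residue + position (e.g. `S473`). Duplicate edges are
#' collapsed.
#'
#' @param path TSV file path.
#' @param col_map named list giving the `kinase`, `substrate_gene` and
#'   `site` column names.
#' @return data.frame of class `ks_network` with `kinase`,
#'   `substrate_gene`, `residue`, `position` and the derived `site_key`.
#' @export
read_ks_network <- function(path,
                            col_map = list(kinase = "kinase",
                                           substrate_gene = "substrate_gene",
                                           site = "site")) {
  raw <- read_tsv(path, colClasses = "character")
  miss <- setdiff(unlist(col_map), names(raw))
  if (length(miss))
    stopf("kinase-substrate table is missing column(s): %s",
          paste(miss, collapse = ", "))
  tok <- raw[[col_map$site]]
  ok <- grepl("^[STY][0-9]+$", tok)
  if (any(!ok))
    stopf("malformed site token '%s' at line %d", tok[!ok][1],
          which(!ok)[1] + 1L)
  net <- data.frame(
    kinase = toupper(raw[[col_map$kinase]]),
    substrate_gene = toupper(raw[[col_map$substrate_gene]]),
    residue = substring(tok, 1L, 1L),
    position = as.integer(substring(tok, 2L)),
    stringsAsFactors = FALSE
  )
  net <- unique(net)
  rownames(net) <- NULL
  net$site_key <- site_key(net$substrate_gene, net$residue, net$position)
  class(net) <- c("ks_network", "data.frame")
  net
}

#' Kinase activity scores for one comparison
#'
#' @param fc named numeric vector of per-site log2 fold-changes; names are
#'   site keys (`GENE_S123`, see [site_key()]). Non-finite entries are
#'   ignored.
#' @param network a `ks_network`.
#' @param min_substrates minimum number of quantified matched substrate
#'   sites for a kinase to be scored (default 2, i.e. more than one
#'   kinase-substrate relationship).
#' @param alpha significance threshold on the normal p (default 0.05).
#' @return data.frame of class `kinase_score_table`: `kinase`, `m`,
#'   `mean_sub`, `mean_all`, `sd_all`, `z`, `p`, `significant`,
#'   `substrates` (`;`-separated site keys).
#' @export
ksea_scores <- function(fc, network, min_substrates = 2, alpha = 0.05) {
  fc <- fc[is.finite(fc)]
  if (length(fc) < 2L) stopf("ksea_scores: need >= 2 finite fold-changes")
  mean_all <- mean(fc)
  sd_all <- stats::sd(fc)
  if (sd_all == 0) stopf("ksea_scores: degenerate background (sd = 0)")
  hit <- network[network$site_key %in% names(fc), , drop = FALSE]
  empty <- data.frame(kinase = character(), m = integer(),
                      mean_sub = numeric(), mean_all = numeric(),
                      sd_all = numeric(), z = numeric(), p = numeric(),
                      significant = logical(), substrates = character(),
                      stringsAsFactors = FALSE)
  if (nrow(hit) == 0L) {
    warnf("ksea_scores: no substrate site matched the fold-change vector")
    class(empty) <- c("kinase_score_table", "data.frame")
    return(empty)
  }
  hit <- unique(hit[c("kinase", "site_key")])
  by_kin <- split(hit$site_key, hit$kinase)
  by_kin <- by_kin[lengths(by_kin) >= min_substrates]
  if (!length(by_kin)) {
    class(empty) <- c("kinase_score_table", "data.frame")
    return(empty)
  }
  rows <- lapply(names(by_kin), function(k) {
    subs <- by_kin[[k]]
    m <- length(subs)
    mean_sub <- mean(fc[subs])
    z <- (mean_sub - mean_all) * sqrt(m) / sd_all
    data.frame(kinase = k, m = m, mean_sub = mean_sub, mean_all = mean_all,
               sd_all = sd_all, z = z, p = 2 * stats::pnorm(-abs(z)),
               significant = 2 * stats::pnorm(-abs(z)) < alpha,
               substrates = paste(sort(subs), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$kinase), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kinase_score_table", "data.frame")
  out
}

#' Build the fold-change vector for a contrast
#'
#' Individual contrasts difference two samples (co-quantified sites only);
#' group contrasts difference group means over observed values.
#'
#' @param qm a `quant_matrix` (individually normalized for individual
#'   contrasts; batch-corrected for group contrasts).
#' @param comparison list with `type` (`"individual"` or `"group"`) and
#'   `a`, `b` (sample id, or sample id vectors for group).
#' @return named numeric vector of log2 fold-changes.
#' @export
contrast_fc <- function(qm, comparison) {
  v <- qm$values
  if (identical(comparison$type, "group")) {
    fc <- rowMeans(v[, comparison$a, drop = FALSE], na.rm = TRUE) -
      rowMeans(v[, comparison$b, drop = FALSE], na.rm = TRUE)
  } else {
    fc <- v[, comparison$a] - v[, comparison$b]
  }
  fc
}

#' Kinase x comparison activity profile
#'
#' Scores every comparison with [ksea_scores()] and assembles the per-
#' patient kinome profile. Kinases not scorable in a comparison
#' (fewer than `min_substrates` co-quantified substrates) carry `NA`
#' ("no information") in that column.
#'
#' @param qm the `quant_matrix` the contrasts are drawn from.
#' @param comparisons named list of comparisons (see [contrast_fc()]).
#' @param network a `ks_network`.
#' @inheritParams ksea_scores
#' @return list of class `ksea_profile` with matrices `z`, `p`,
#'   `significant`, `m` (kinase x comparison) and `tables` (the per-
#'   comparison `kinase_score_table`s).
#' @export
ksea_profile <- function(qm, comparisons, network, min_substrates = 2,
                         alpha = 0.05) {
  if (is.null(names(comparisons)) || any(names(comparisons) == ""))
    stopf("ksea_profile: comparisons must be named")
  tables <- lapply(comparisons, function(cmp) {
    fc <- contrast_fc(qm, cmp)
    ksea_scores(fc, network, min_substrates = min_substrates, alpha = alpha)
  })
  kinases <- sort(unique(unlist(lapply(tables, `[[`, "kinase"))))
  shape <- function(col, default) {
    m <- matrix(default, length(kinases), length(tables),
                dimnames = list(kinases, names(tables)))
    for (j in seq_along(tables)) {
      tb <- tables[[j]]
      m[match(tb$kinase, kinases), j] <- tb[[col]]
    }
    m
  }
  structure(list(z = shape("z", NA_real_), p = shape("p", NA_real_),
                 significant = shape("significant", NA),
                 m = shape("m", NA_integer_), tables = tables),
            class = "ksea_profile")
}

#' @export
print.ksea_profile <- function(x, ...) {
  cat(sprintf("ksea_profile: %d kinase(s) x %d comparison(s)\n",
              nrow(x$z), ncol(x$z)))
  invisible(x)
}

#' Standard per-patient contrasts from a study design
#'
#' `"post_vs_pre_t"`: post- vs pre-treatment tumor per patient with both
#' timepoints (the treatment-response kinome profile). `"t_vs_nat"`:
#' tumor vs matched adjacent tissue per patient at one timepoint.
#'
#' @param design a `study_design` (clinical rows; references ignored).
#' @param type contrast family.
#' @param timepoint timepoint for `"t_vs_nat"` (default `"pre"`).
#' @param her2 optionally restrict to `"positive"` or `"negative"` patients.
#' @return named list of individual comparisons for [ksea_profile()].
#' @export
individual_contrasts <- function(design, type = c("post_vs_pre_t", "t_vs_nat"),
                                 timepoint = "pre", her2 = NULL) {
  type <- match.arg(type)
  d <- design[!design$is_reference, , drop = FALSE]
  if (!is.null(her2)) d <- d[d$her2 %in% her2, , drop = FALSE]
  out <- list()
  for (p in unique(stats::na.omit(d$patient_id))) {
    dp <- d[d$patient_id %in% p, , drop = FALSE]
    if (type == "post_vs_pre_t") {
      a <- dp$sample_id[dp$tissue == "T" & dp$timepoint == "post"]
      b <- dp$sample_id[dp$tissue == "T" & dp$timepoint == "pre"]
    } else {
      a <- dp$sample_id[dp$tissue == "T" & dp$timepoint == timepoint]
      b <- dp$sample_id[dp$tissue == "NAT" & dp$timepoint == timepoint]
    }
    if (length(a) == 1L && length(b) == 1L)
      out[[p]] <- list(type = "individual", a = a, b = b)
  }
  out
}
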