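# Ground-truthed simulator of a multi-batch TMT phosphoproteomics study:
# paired pre/post-treatment tumor and adjacent-tissue biopsies bridged
# across batches by pooled cell-line reference channels. Group and
# treatment effects are planted on dedicated site lists and on the
# substrate sets of "active" kinases; batches carry additive and
# multiplicative effects; missingness is left-censored (MNAR).

#' Simulation configuration
#'
#' Defaults emulate the clinical layout: 4 TMT 10-plex batches, each with
#' 2 pooled cell-line reference channels and 6 clinical channels; 4
#' HER2-positive patients contribute pre/post-treatment tumor (T) and
#' adjacent-tissue (NAT) biopsies (4 samples each), 4 HER2-negative
#' patients contribute pre-treatment T/NAT pairs; each patient's samples
#' share one batch.
#'
#' The signal model per log2 value is
#' `base_f + effect(f, s) + gamma_bf + delta_bf * N(0, noise_sd)`:
#' tumor/HER2/treatment effects of magnitude `group_effect` (random sign)
#' on disjoint site lists, plus shifts of `activity_delta` on the substrate
#' sets of the active kinases (tumor-active kinases shift in T samples,
#' treatment-active kinases in post-treatment HER2-positive T samples).
#' Reference channels carry only `base + gamma + delta * noise`.
#' Missingness is logistic left-censoring on the log2 value
#' (midpoint `miss_mid`, slope `miss_slope`); localization probabilities
#' are drawn so about `class1_rate` of sites pass the class-1 cut; small
#' fractions are flagged reverse/contaminant.
#'
#' @param n_features number of phosphosites.
#' @param n_batches,channels_per_batch,n_ref_per_batch TMT layout.
#' @param n_her2_pos,n_her2_neg patients per HER2 group.
#' @param base_mean,base_sd log2 base-abundance distribution.
#' @param noise_sd within-sample measurement noise sd (log2 units).
#' @param batch_tau sd of the additive batch effect gamma.
#' @param delta_range range of the multiplicative batch effect delta.
#' @param n_tumor_sites,n_her2_sites,n_treatment_sites planted
#'   differential-site counts per contrast.
#' @param group_effect |log2FC| of planted differential sites.
#' @param n_kinases network size; `n_active_kinases` per contrast family
#'   (tumor and treatment) are active with shift `activity_delta`;
#'   active kinases are given `active_substrates` substrate sites so
#'   activity inference is well-posed, inactive kinases draw substrate
#'   counts from a shifted geometric (min 1, success `substrate_geom_p`),
#'   covering the below-minimum exclusion path.
#' @param miss_mid,miss_slope left-censoring midpoint/slope (log2 units).
#' @param class1_rate fraction of sites with localization prob > 0.75.
#' @param reverse_rate,contaminant_rate artifact flag rates.
#' @param seed integer RNG seed; all draws come from this one stream.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_features = 3000, n_batches = 4,
                       channels_per_batch = 10, n_ref_per_batch = 2,
                       n_her2_pos = 4, n_her2_neg = 4,
                       base_mean = 23, base_sd = 2, noise_sd = 0.5,
                       batch_tau = 1, delta_range = c(0.7, 1.4),
                       n_tumor_sites = 300, n_her2_sites = 150,
                       n_treatment_sites = 150, group_effect = 1.5,
                       n_kinases = 40, n_active_kinases = 4,
                       activity_delta = 1, active_substrates = 12,
                       substrate_geom_p = 0.15,
                       miss_mid = 19, miss_slope = 1, class1_rate = 0.9,
                       reverse_rate = 0.01, contaminant_rate = 0.01,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$noise_sd > 0, cfg$base_sd > 0, cfg$batch_tau >= 0,
            all(cfg$delta_range > 0), cfg$miss_slope > 0,
            cfg$n_ref_per_batch >= 1)
  per_batch <- (4 * n_her2_pos + 2 * n_her2_neg) / n_batches
  if (per_batch != round(per_batch) ||
      per_batch + n_ref_per_batch > channels_per_batch)
    stopf("infeasible design: %s clinical + %d reference channels per batch exceed %d",
          format(per_batch), n_ref_per_batch, channels_per_batch)
  class(cfg) <- "sim_config"
  cfg
}

sim_design <- function(cfg) {
  rows <- list()
  batch_load <- integer(cfg$n_batches)  # clinical channels used so far
  add <- function(batch, sample_id, patient, tissue, her2, timepoint, ref) {
    rows[[length(rows) + 1L]] <<- data.frame(
      batch_id = paste0("B", batch), channel_id = NA_character_,
      sample_id = sample_id, patient_id = patient, tissue = tissue,
      her2 = her2, timepoint = timepoint, is_reference = ref,
      stringsAsFactors = FALSE)
  }
  for (b in seq_len(cfg$n_batches))
    for (r in seq_len(cfg$n_ref_per_batch))
      add(b, sprintf("REF_B%d_%d", b, r), NA, "REF", NA, NA, TRUE)
  pat <- 0L
  for (p in seq_len(cfg$n_her2_pos)) {
    pat <- pat + 1L
    b <- (pat - 1L) %% cfg$n_batches + 1L
    id <- paste0("P", pat)
    for (tp in c("pre", "post"))
      for (ts in c("T", "NAT"))
        add(b, paste(id, tp, ts, sep = "_"), id, ts, "positive", tp, FALSE)
  }
  for (p in seq_len(cfg$n_her2_neg)) {
    pat <- pat + 1L
    b <- (pat - 1L) %% cfg$n_batches + 1L
    id <- paste0("P", pat)
    for (ts in c("T", "NAT"))
      add(b, paste(id, "pre", ts, sep = "_"), id, ts, "negative", "pre", FALSE)
  }
  d <- do.call(rbind, rows)
  for (b in unique(d$batch_id)) {
    i <- which(d$batch_id == b)
    if (length(i) > cfg$channels_per_batch)
      stopf("infeasible design: batch %s needs %d channels, has %d",
            b, length(i), cfg$channels_per_batch)
    d$channel_id[i] <- paste0("C", seq_along(i))
  }
  validate_design(d)
  class(d) <- c("study_design", "data.frame")
  d
}

#' Generate a synthetic multi-batch study
#'
#' Writes the complete input bundle for the pipeline: phosphosite table,
#' protein-group table, study design, kinase-substrate network, a gene-set
#' collection (sets built around the planted signals plus random sets),
#' and the ground truth as JSON. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the written `paths` and the in-memory
#'   `truth`, `design` and `config`.
#' @export
simulate_study <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  design <- sim_design(cfg)
  clin <- design[!design$is_reference, , drop = FALSE]
  nf <- cfg$n_features

  # --- feature annotation -------------------------------------------------
  n_genes <- max(50L, ceiling(nf / 2.5))
  genes_all <- sprintf("GENE%04d", seq_len(n_genes))
  gene <- genes_all[sample.int(n_genes, nf, replace = TRUE)]
  residue <- sample(c("S", "T", "Y"), nf, replace = TRUE,
                    prob = c(0.825, 0.158, 0.017))
  position <- sample.int(4000L, nf, replace = TRUE)
  key <- site_key(gene, residue, position)
  while (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    position[dup] <- sample.int(4000L, length(dup), replace = TRUE)
    key <- site_key(gene, residue, position)
  }
  loc_prob <- ifelse(stats::runif(nf) < cfg$class1_rate,
                     stats::runif(nf, 0.7501, 1),
                     stats::runif(nf, 0, 0.75))
  is_rev <- stats::runif(nf) < cfg$reverse_rate
  is_con <- stats::runif(nf) < cfg$contaminant_rate

  # --- planted effects ----------------------------------------------------
  pool <- sample.int(nf)  # disjoint allocation of signal features
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  idx_tumor <- take(cfg$n_tumor_sites)
  idx_her2 <- take(cfg$n_her2_sites)
  idx_treat <- take(cfg$n_treatment_sites)
  eff_sign <- function(k) sample(c(-1, 1), k, replace = TRUE)
  e_tumor <- cfg$group_effect * eff_sign(cfg$n_tumor_sites)
  e_her2 <- cfg$group_effect * eff_sign(cfg$n_her2_sites)
  e_treat <- cfg$group_effect * eff_sign(cfg$n_treatment_sites)

  # --- kinase-substrate network ------------------------------------------
  kin_names <- sprintf("KIN%02d", seq_len(cfg$n_kinases))
  n_act <- cfg$n_active_kinases
  act_tumor <- kin_names[seq_len(n_act)]
  act_treat <- kin_names[n_act + seq_len(n_act)]
  dir_tumor <- eff_sign(n_act)
  dir_treat <- eff_sign(n_act)
  sub_idx <- vector("list", cfg$n_kinases)
  names(sub_idx) <- kin_names
  for (k in c(act_tumor, act_treat)) sub_idx[[k]] <- take(cfg$active_substrates)
  for (k in setdiff(kin_names, c(act_tumor, act_treat))) {
    cnt <- 1L + stats::rgeom(1L, cfg$substrate_geom_p)
    sub_idx[[k]] <- sample.int(nf, min(cnt, nf))
  }
  network <- do.call(rbind, lapply(kin_names, function(k)
    data.frame(kinase = k, substrate_gene = gene[sub_idx[[k]]],
               site = paste0(residue[sub_idx[[k]]], position[sub_idx[[k]]]),
               stringsAsFactors = FALSE)))

  # --- sample effect matrix ----------------------------------------------
  E <- matrix(0, nf, nrow(clin), dimnames = list(key, clin$sample_id))
  cols_T <- clin$tissue == "T"
  cols_her2T <- cols_T & clin$her2 %in% "positive"
  cols_postT <- cols_her2T & clin$timepoint %in% "post"
  E[idx_tumor, cols_T] <- E[idx_tumor, cols_T] + e_tumor
  E[idx_her2, cols_her2T] <- E[idx_her2, cols_her2T] + e_her2
  E[idx_treat, cols_postT] <- E[idx_treat, cols_postT] + e_treat
  for (i in seq_len(n_act)) {
    E[sub_idx[[act_tumor[i]]], cols_T] <-
      E[sub_idx[[act_tumor[i]]], cols_T] + dir_tumor[i] * cfg$activity_delta
    E[sub_idx[[act_treat[i]]], cols_postT] <-
      E[sub_idx[[act_treat[i]]], cols_postT] + dir_treat[i] * cfg$activity_delta
  }

  # --- values: base + effects + batch + noise, then left-censoring --------
  base <- stats::rnorm(nf, cfg$base_mean, cfg$base_sd)
  batches <- unique(design$batch_id)
  gamma <- matrix(stats::rnorm(nf * length(batches), 0, cfg$batch_tau),
                  nf, dimnames = list(key, batches))
  delta <- matrix(stats::runif(nf * length(batches), cfg$delta_range[1],
                               cfg$delta_range[2]),
                  nf, dimnames = list(key, batches))
  v <- matrix(NA_real_, nf, nrow(design),
              dimnames = list(key, design$sample_id))
  for (j in seq_len(nrow(design))) {
    b <- design$batch_id[j]
    eff <- if (design$is_reference[j]) 0 else E[, design$sample_id[j]]
    v[, j] <- base + eff + gamma[, b] + delta[, b] * stats::rnorm(nf, 0, cfg$noise_sd)
  }
  p_miss <- stats::plogis((cfg$miss_mid - v) / cfg$miss_slope)
  miss <- matrix(stats::runif(length(v)) < p_miss, nrow(v))
  intens <- round(2^v, 2)
  intens[miss] <- 0

  # --- write site table ---------------------------------------------------
  icols <- paste0("intensity.", design$batch_id, ".", design$channel_id)
  site_df <- data.frame(
    site_id = sprintf("site%05d", seq_len(nf)),
    protein = paste0("ACC_", gene), gene = gene, residue = residue,
    position = position, localization_prob = round(loc_prob, 4),
    reverse = ifelse(is_rev, "+", ""),
    contaminant = ifelse(is_con, "+", ""),
    stringsAsFactors = FALSE)
  site_df <- cbind(site_df, as.data.frame(`colnames<-`(intens, icols)))
  paths <- list(
    sites = file.path(outdir, "site_table.tsv"),
    proteins = file.path(outdir, "protein_table.tsv"),
    design = file.path(outdir, "design.tsv"),
    network = file.path(outdir, "ks_network.tsv"),
    gmt = file.path(outdir, "gene_sets.gmt"),
    truth = file.path(outdir, "truth.json"))
  write_tsv(site_df, paths$sites)

  # --- protein-group table ------------------------------------------------
  pbase <- stats::rnorm(n_genes, cfg$base_mean + 1, cfg$base_sd)
  pgamma <- matrix(stats::rnorm(n_genes * length(batches), 0, cfg$batch_tau),
                   n_genes)
  pv <- matrix(NA_real_, n_genes, nrow(design))
  for (j in seq_len(nrow(design))) {
    bi <- match(design$batch_id[j], batches)
    pv[, j] <- pbase + pgamma[, bi] + stats::rnorm(n_genes, 0, cfg$noise_sd)
  }
  pmiss <- matrix(stats::runif(length(pv)) <
                    stats::plogis((cfg$miss_mid - pv) / cfg$miss_slope),
                  nrow(pv))
  pint <- round(2^pv, 2)
  pint[pmiss] <- 0
  prot_df <- data.frame(
    protein_group_id = paste0("PG_", genes_all),
    accessions = paste0("ACC_", genes_all),
    peptide_count = 1L + stats::rpois(n_genes, 2.5),
    reverse = ifelse(stats::runif(n_genes) < cfg$reverse_rate, "+", ""),
    contaminant = ifelse(stats::runif(n_genes) < cfg$contaminant_rate, "+", ""),
    stringsAsFactors = FALSE)
  prot_df <- cbind(prot_df, as.data.frame(`colnames<-`(pint, icols)))
  write_tsv(prot_df, paths$proteins)

  # --- design, network ----------------------------------------------------
  ddf <- as.data.frame(design)
  ddf[is.na(ddf)] <- ""
  ddf$is_reference <- ifelse(design$is_reference, "TRUE", "FALSE")
  write_tsv(ddf, paths$design)
  write_tsv(network, paths$network)

  # --- gene sets: planted-signal sets + random sets -----------------------
  gmt <- c(
    sprintf("PATH_TUMOR\tplanted tumor sites\t%s",
            paste(unique(gene[idx_tumor]), collapse = "\t")),
    sprintf("PATH_HER2\tplanted HER2 sites\t%s",
            paste(unique(gene[idx_her2]), collapse = "\t")),
    sprintf("PATH_TREATMENT\tplanted treatment sites\t%s",
            paste(unique(gene[idx_treat]), collapse = "\t")),
    vapply(c(act_tumor, act_treat), function(k)
      sprintf("PATH_%s\tsubstrates of %s\t%s", k, k,
              paste(unique(c(gene[sub_idx[[k]]],
                             sample(genes_all, 10L))), collapse = "\t")),
      ""),
    vapply(seq_len(10L), function(i)
      sprintf("PATH_RND%02d\trandom set\t%s", i,
              paste(sample(genes_all, 20L + i), collapse = "\t")), ""))
  writeLines(gmt, paths$gmt)

  # --- truth --------------------------------------------------------------
  truth <- list(
    seed = cfg$seed,
    differential = list(
      tumor = data.frame(site = key[idx_tumor], effect = e_tumor,
                         stringsAsFactors = FALSE),
      her2 = data.frame(site = key[idx_her2], effect = e_her2,
                        stringsAsFactors = FALSE),
      treatment = data.frame(site = key[idx_treat], effect = e_treat,
                             stringsAsFactors = FALSE)),
    kinases = list(
      tumor = data.frame(kinase = act_tumor, direction = dir_tumor,
                         stringsAsFactors = FALSE),
      treatment = data.frame(kinase = act_treat, direction = dir_treat,
                             stringsAsFactors = FALSE)),
    batch = list(gamma = apply(gamma, 2, identity, simplify = FALSE),
                 delta = apply(delta, 2, identity, simplify = FALSE)),
    features = key)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = 8,
                       dataframe = "columns")
  invisible(list(paths = paths, truth = truth, design = design, config = cfg))
}

#' Recovery metrics against the simulation ground truth
#'
#' Compares pipeline outputs with the planted signals: differential-site
#' recall and precision per group contrast, kinase recovery (fraction of
#' active-kinase x patient cells called significant with the planted
#' direction) and sign agreement among strong calls (|z| > 2), and the
#' reduction of mean per-feature batch R-squared between two matrix stages
#' (raw log2 vs batch-corrected).
#'
#' @param truth the `truth` list from [simulate_study()] (or read back
#'   from `truth.json`).
#' @param group_results named list of [group_compare()] results; names
#'   must match truth contrasts (`her2`, `treatment`).
#' @param profiles named list of [ksea_profile()]s; names matching truth
#'   kinase families (`tumor`, `treatment`).
#' @param qm_before,qm_after optional `quant_matrix` pair for the batch-R2
#'   reduction (e.g. raw log2 vs batch-corrected).
#' @return list of metric lists.
#' @export
truth_report <- function(truth, group_results = list(), profiles = list(),
                         qm_before = NULL, qm_after = NULL) {
  out <- list(differential = list(), kinase = list(), batch = NULL)
  for (nm in names(group_results)) {
    res <- group_results[[nm]]
    tr <- truth$differential[[nm]]
    if (is.null(tr)) stopf("truth has no differential contrast '%s'", nm)
    tr <- as.data.frame(tr, stringsAsFactors = FALSE)
    tested <- intersect(tr$site, res$feature)
    called <- res$feature[res$class %in% c("significant_up",
                                           "significant_down")]
    tp <- length(intersect(called, tested))
    out$differential[[nm]] <- list(
      n_truth = nrow(tr), n_truth_tested = length(tested),
      n_called = length(called), recall = tp / max(1L, length(tested)),
      precision = if (length(called)) tp / length(called) else NA_real_)
  }
  agg <- list(hit = 0L, informative = 0L, strong = 0L, strong_ok = 0L)
  for (nm in names(profiles)) {
    pr <- profiles[[nm]]
    tr <- truth$kinases[[nm]]
    if (is.null(tr)) stopf("truth has no kinase family '%s'", nm)
    tr <- as.data.frame(tr, stringsAsFactors = FALSE)
    idx <- match(tr$kinase, rownames(pr$z))
    z <- pr$z[idx, , drop = FALSE]
    sig <- pr$significant[idx, , drop = FALSE]
    ok <- !is.na(z)
    hit <- ok & sig %in% TRUE & sign(z) == tr$direction
    strong <- ok & abs(z) > 2
    out$kinase[[nm]] <- list(
      n_cells = length(z), n_informative = sum(ok),
      recovery = sum(hit, na.rm = TRUE) / max(1L, sum(ok)),
      sign_agreement = if (any(strong))
        sum(sign(z[strong]) == tr$direction[row(z)[strong]]) / sum(strong)
      else NA_real_)
    agg$hit <- agg$hit + sum(hit, na.rm = TRUE)
    agg$informative <- agg$informative + sum(ok)
    agg$strong <- agg$strong + sum(strong)
    agg$strong_ok <- agg$strong_ok +
      sum(sign(z[strong]) == tr$direction[row(z)[strong]])
  }
  if (length(profiles))
    out$kinase$overall <- list(
      n_informative = agg$informative,
      recovery = agg$hit / max(1L, agg$informative),
      sign_agreement = if (agg$strong) agg$strong_ok / agg$strong
      else NA_real_)
  if (!is.null(qm_before) && !is.null(qm_after)) {
    shared <- intersect(rownames(qm_before$values), rownames(qm_after$values))
    qb <- qm_before; qb$values <- qb$values[shared, , drop = FALSE]
    qa <- qm_after; qa$values <- qa$values[shared, , drop = FALSE]
    r2b <- batch_r2(qb); r2a <- batch_r2(qa)
    out$batch <- list(r2_before = r2b, r2_after = r2a,
                      reduction = 1 - r2a / r2b)
  }
  out
}
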