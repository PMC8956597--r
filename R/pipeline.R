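# End-to-end orchestration: simulate -> normalize -> compare -> enrich ->
# ksea -> pca, each stage writing TSV/JSON artifacts and appending
# reproducible row-count lines to run.log.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every threshold at its
#' conventional default; override entries via the `config` argument of
#' [run_pipeline()] or a YAML file with the same structure.
#'
#' @param outdir output/working directory.
#' @return nested named list: `paths` (site/protein/design/network/gmt
#'   inputs; empty entries are filled by the simulate stage), `thresholds`
#'   (`class1_threshold` 0.75, `min_peptides` 2, `fc_cut` 1, `p_sig` 0.05,
#'   `p_tend` 0.1, `ksea_min_substrates` 2, `alpha` 0.05), `sim`
#'   (overrides for [sim_config()]), `simulate` (run the simulator when no
#'   site table is configured), `seed`.
#' @export
default_run_config <- function(outdir = "phoskit_run") {
  list(
    outdir = outdir,
    seed = 1,
    simulate = TRUE,
    paths = list(sites = NULL, proteins = NULL, design = NULL,
                 network = NULL, gmt = NULL, pathway = NULL),
    thresholds = list(class1_threshold = 0.75, min_peptides = 2,
                      fc_cut = 1, p_sig = 0.05, p_tend = 0.1,
                      ksea_min_substrates = 2, alpha = 0.05),
    sim = list()
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

pipeline_log <- function(state, fmt, ...) {
  line <- sprintf(fmt, ...)
  cat(line, "\n", sep = "", file = state$logfile, append = TRUE)
  message(line)
  invisible(line)
}

#' Run the analysis pipeline
#'
#' Executes one stage or the whole chain. Stages: `simulate` (generate the
#' synthetic study), `normalize` (read + filter tables, run both
#' normalization routes, write matrices and summaries), `compare` (group
#' contrasts: Welch pre-treatment HER2-positive T vs HER2-negative T;
#' paired post vs pre HER2-positive T), `enrich` (ORA of significant gene
#' lists against the GMT), `ksea` (per-patient kinome profiles: post vs
#' pre T, and T vs NAT), `pca` (tumor-sample ordination), `all`. Row
#' counts at every filter are appended to `<outdir>/run.log`; a failing
#' stage leaves a `FAILED` marker next to its partial artifacts.
#'
#' @param config a configuration list (see [default_run_config()]) or the
#'   path of a YAML file holding one.
#' @param subcommand one of `"simulate"`, `"normalize"`, `"compare"`,
#'   `"ksea"`, `"enrich"`, `"pca"`, `"all"`.
#' @return invisibly, the list of artifact paths written.
#' @export
run_pipeline <- function(config = list(),
                         subcommand = c("all", "simulate", "normalize",
                                        "compare", "ksea", "enrich", "pca")) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file '%s' does not exist", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_run_config(), config)
  for (nm in names(cfg$paths)) {
    p <- cfg$paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      stopf("configured path '%s' does not exist: %s", nm, p)
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  failed <- file.path(cfg$outdir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  state <- new.env(parent = emptyenv())
  state$logfile <- file.path(cfg$outdir, "run.log")
  if (file.exists(state$logfile)) unlink(state$logfile)
  state$artifacts <- character()
  cfg_path <- file.path(cfg$outdir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  pipeline_log(state, "phoskit %s | config md5 %s",
               as.character(utils::packageVersion("phoskit")),
               unname(tools::md5sum(cfg_path)))
  stages <- if (subcommand == "all") {
    c(if (isTRUE(cfg$simulate) && is.null(config$paths$sites)) "simulate",
      "normalize", "compare", "enrich", "ksea", "pca")
  } else subcommand
  tryCatch(
    for (st in stages) {
      pipeline_log(state, "stage %s: start", st)
      switch(st,
             simulate = stage_simulate(cfg, state),
             normalize = stage_normalize(cfg, state),
             compare = stage_compare(cfg, state),
             enrich = stage_enrich(cfg, state),
             ksea = stage_ksea(cfg, state),
             pca = stage_pca(cfg, state))
      pipeline_log(state, "stage %s: done", st)
    },
    error = function(e) {
      writeLines(conditionMessage(e), failed)
      stopf("pipeline stage failed: %s", conditionMessage(e))
    })
  invisible(state$artifacts)
}

keep_artifact <- function(state, path) {
  state$artifacts <- c(state$artifacts, path)
  path
}

stage_simulate <- function(cfg, state) {
  sc <- do.call(sim_config, merge_config(list(seed = cfg$seed), cfg$sim))
  sim <- simulate_study(sc, cfg$outdir)
  for (p in sim$paths) keep_artifact(state, p)
  pipeline_log(state, "simulate: %d features, %d design rows, %d network edges",
               sc$n_features, nrow(sim$design),
               nrow(read_tsv(sim$paths$network)))
  invisible(sim)
}

resolve_inputs <- function(cfg) {
  p <- cfg$paths
  def <- list(sites = "site_table.tsv", proteins = "protein_table.tsv",
              design = "design.tsv", network = "ks_network.tsv",
              gmt = "gene_sets.gmt", truth = "truth.json")
  for (nm in names(def)) {
    if (is.null(p[[nm]])) {
      cand <- file.path(cfg$outdir, def[[nm]])
      if (file.exists(cand)) p[[nm]] <- cand
    }
  }
  p
}

stage_normalize <- function(cfg, state) {
  p <- resolve_inputs(cfg)
  if (is.null(p$sites) || is.null(p$design))
    stopf("normalize: site table and design are required (configure paths or run simulate)")
  th <- cfg$thresholds
  design <- read_study_design(p$design)
  sites <- read_site_table(p$sites, design)
  pipeline_log(state, "sites read: %d", nrow(sites))
  sites <- filter_class1(sites, th$class1_threshold)
  pipeline_log(state, "sites class-1 (prob > %s): %d",
               format(th$class1_threshold), nrow(sites))
  sites <- filter_artifacts(sites)
  pipeline_log(state, "sites after reverse/contaminant removal: %d",
               nrow(sites))
  comp <- residue_composition(sites)
  qs <- quantified_summary(sites, design)
  jsonlite::write_json(
    list(residue_composition = comp, presence = qs),
    keep_artifact(state, file.path(cfg$outdir, "identification_summary.json")),
    auto_unbox = TRUE, digits = NA)
  write_site_table(sites,
                   keep_artifact(state, file.path(cfg$outdir,
                                                  "sites_filtered.tsv")))
  if (!is.null(p$proteins)) {
    prot <- read_protein_table(p$proteins, design)
    pipeline_log(state, "protein groups read: %d", nrow(prot))
    prot <- filter_artifacts(prot)
    prot <- filter_protein_groups(prot, th$min_peptides)
    pipeline_log(state, "protein groups kept (>= %d peptides, no artifacts): %d",
                 th$min_peptides, nrow(prot))
  }
  qm_raw <- build_quant_matrix(sites, design)
  qm_log <- log2_transform(qm_raw)
  write_quant_matrix(qm_log,
                     keep_artifact(state, file.path(cfg$outdir,
                                                    "matrix_raw_log2.tsv")))
  qm <- reference_subtract(qm_log)
  qm <- median_center(qm)
  qm <- batch_presence_filter(qm)
  pipeline_log(state, "sites present in every batch: %d", nrow(qm$values))
  qm <- impute_min(qm)
  corrected <- combat_correct(qm)
  write_quant_matrix(corrected$matrix,
                     keep_artifact(state, file.path(cfg$outdir,
                                                    "matrix_group.tsv")))
  jsonlite::write_json(
    list(batches = corrected$model$batches, eb = corrected$model$eb,
         iterations = corrected$model$iterations,
         priors = corrected$model$priors),
    keep_artifact(state, file.path(cfg$outdir, "batch_model.json")),
    auto_unbox = TRUE, digits = NA)
  qm_ind <- normalize_for_individual(log2_transform(build_quant_matrix(sites, design)))
  write_quant_matrix(qm_ind,
                     keep_artifact(state, file.path(cfg$outdir,
                                                    "matrix_individual.tsv")))
  invisible(NULL)
}

group_contrast_samples <- function(design) {
  d <- design[!design$is_reference, , drop = FALSE]
  list(
    her2 = list(
      mode = "welch",
      a = d$sample_id[d$tissue == "T" & d$her2 %in% "positive" &
                        d$timepoint %in% "pre"],
      b = d$sample_id[d$tissue == "T" & d$her2 %in% "negative"]),
    treatment = list(
      mode = "paired",
      a = d$sample_id[d$tissue == "T" & d$her2 %in% "positive" &
                        d$timepoint %in% "post"],
      b = d$sample_id[d$tissue == "T" & d$her2 %in% "positive" &
                        d$timepoint %in% "pre"]))
}

read_stage_matrix <- function(cfg, name) {
  path <- file.path(cfg$outdir, name)
  if (!file.exists(path))
    stopf("required artifact '%s' not found; run the normalize stage first",
          name)
  read_quant_matrix(path)
}

stage_compare <- function(cfg, state) {
  th <- cfg$thresholds
  qm <- read_stage_matrix(cfg, "matrix_group.tsv")
  contrasts <- group_contrast_samples(qm$design)
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    if (length(ct$a) < 2L || length(ct$b) < 2L) {
      pipeline_log(state, "compare %s: skipped (not enough samples)", nm)
      next
    }
    res <- group_compare(qm, ct$a, ct$b, mode = ct$mode, contrast = nm,
                         fc_cut = th$fc_cut, p_sig = th$p_sig,
                         p_tend = th$p_tend)
    write_tsv(res, keep_artifact(state,
                                 file.path(cfg$outdir,
                                           sprintf("compare_%s.tsv", nm))))
    tab <- table(res$class)
    pipeline_log(state, "compare %s (%s): %s", nm, ct$mode,
                 paste(names(tab), as.integer(tab), sep = "=",
                       collapse = " "))
    p <- resolve_inputs(cfg)
    if (!is.null(p$pathway)) {
      pw <- read_tsv(p$pathway, colClasses = "character")
      ov <- pathway_overlay(res, pw)
      write_tsv(ov, keep_artifact(state,
                                  file.path(cfg$outdir,
                                            sprintf("overlay_%s.tsv", nm))))
    }
  }
  invisible(NULL)
}

stage_enrich <- function(cfg, state) {
  p <- resolve_inputs(cfg)
  if (is.null(p$gmt)) {
    pipeline_log(state, "enrich: skipped (no gene-set collection configured)")
    return(invisible(NULL))
  }
  collection <- read_gmt(p$gmt)
  qm <- read_stage_matrix(cfg, "matrix_group.tsv")
  universe <- unique(feature_gene(rownames(qm$values)))
  for (nm in names(group_contrast_samples(qm$design))) {
    path <- file.path(cfg$outdir, sprintf("compare_%s.tsv", nm))
    if (!file.exists(path)) next
    res <- read_tsv(path)
    for (dirn in c("up", "down")) {
      cls <- paste0("significant_", dirn)
      hits <- unique(feature_gene(res$feature[res$class == cls]))
      if (!length(hits)) {
        pipeline_log(state, "enrich %s/%s: no significant genes", nm, dirn)
        next
      }
      enr <- ora(hits, universe, collection, alpha = cfg$thresholds$alpha)
      write_tsv(enr, keep_artifact(state,
                                   file.path(cfg$outdir,
                                             sprintf("ora_%s_%s.tsv",
                                                     nm, dirn))))
      pipeline_log(state, "enrich %s/%s: %d hit genes, %d significant set(s)",
                   nm, dirn, length(hits), sum(enr$significant))
    }
  }
  invisible(NULL)
}

stage_ksea <- function(cfg, state) {
  p <- resolve_inputs(cfg)
  if (is.null(p$network))
    stopf("ksea: kinase-substrate network path is required")
  th <- cfg$thresholds
  network <- read_ks_network(p$network)
  qm <- read_stage_matrix(cfg, "matrix_individual.tsv")
  profiles <- list(
    treatment = individual_contrasts(qm$design, "post_vs_pre_t",
                                     her2 = "positive"),
    tumor = individual_contrasts(qm$design, "t_vs_nat", timepoint = "pre"))
  out <- list()
  for (nm in names(profiles)) {
    cmp <- profiles[[nm]]
    if (!length(cmp)) {
      pipeline_log(state, "ksea %s: skipped (no resolvable comparison)", nm)
      next
    }
    pr <- ksea_profile(qm, cmp, network,
                       min_substrates = th$ksea_min_substrates,
                       alpha = th$alpha)
    out[[nm]] <- pr
    for (what in c("z", "p", "significant")) {
      df <- data.frame(kinase = rownames(pr$z), pr[[what]],
                       check.names = FALSE, stringsAsFactors = FALSE)
      write_tsv(df, keep_artifact(state,
                                  file.path(cfg$outdir,
                                            sprintf("ksea_%s_%s.tsv",
                                                    nm, what))))
    }
    pipeline_log(state, "ksea %s: %d kinase(s) x %d comparison(s), %d significant cell(s)",
                 nm, nrow(pr$z), ncol(pr$z),
                 sum(pr$significant, na.rm = TRUE))
  }
  # recovery metrics when the run came from the simulator
  if (!is.null(p$truth) && file.exists(file.path(cfg$outdir,
                                                 "compare_her2.tsv"))) {
    truth <- jsonlite::read_json(p$truth, simplifyVector = TRUE)
    gr <- list()
    for (nm in c("her2", "treatment")) {
      path <- file.path(cfg$outdir, sprintf("compare_%s.tsv", nm))
      if (file.exists(path)) gr[[nm]] <- read_tsv(path)
    }
    qm_before <- read_stage_matrix(cfg, "matrix_raw_log2.tsv")
    qm_after <- read_stage_matrix(cfg, "matrix_group.tsv")
    rep <- truth_report(truth, group_results = gr, profiles = out,
                        qm_before = qm_before, qm_after = qm_after)
    jsonlite::write_json(rep,
                         keep_artifact(state, file.path(cfg$outdir,
                                                        "recovery.json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
    pipeline_log(state, "recovery: kinase treatment %.3f, tumor %.3f; batch R2 reduction %.3f",
                 rep$kinase$treatment$recovery, rep$kinase$tumor$recovery,
                 rep$batch$reduction)
  }
  invisible(NULL)
}

stage_pca <- function(cfg, state) {
  qm <- read_stage_matrix(cfg, "matrix_group.tsv")
  d <- qm$design
  tumor <- d$sample_id[d$tissue == "T"]
  fit <- pca_qc(qm, samples = tumor,
                n_components = min(5L, length(tumor) - 1L))
  scores <- data.frame(sample_id = rownames(fit$scores), fit$scores,
                       check.names = FALSE)
  meta <- d[match(scores$sample_id, d$sample_id),
            c("her2", "timepoint", "tissue")]
  write_tsv(cbind(scores, meta),
            keep_artifact(state, file.path(cfg$outdir, "pca_scores.tsv")))
  write_tsv(data.frame(component = seq_along(fit$explained),
                       explained = fit$explained),
            keep_artifact(state, file.path(cfg$outdir,
                                           "pca_explained.tsv")))
  pipeline_log(state, "pca: %d tumor sample(s), PC1 %.1f%%",
               nrow(fit$scores), 100 * fit$explained[1])
  invisible(NULL)
}
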