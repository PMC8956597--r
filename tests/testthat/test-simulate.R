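small_cfg <- function(...) {
  sim_config(n_features = 400, n_tumor_sites = 40, n_her2_sites = 20,
             n_treatment_sites = 20, n_kinases = 10, n_active_kinases = 2,
             active_substrates = 8, ...)
}

test_that("the generated design matches the clinical layout", {
  cfg <- sim_config()
  d <- phoskit:::sim_design(cfg)
  expect_equal(nrow(d), 32L)                       # 8 refs + 24 clinical
  expect_equal(sum(d$is_reference), 8L)
  clin <- d[!d$is_reference, ]
  expect_equal(nrow(clin), 24L)
  expect_equal(sum(clin$her2 == "positive"), 16L)  # 4 patients x pre/post x T/NAT
  expect_equal(sum(clin$her2 == "negative"), 8L)
  for (b in unique(d$batch_id))
    expect_lte(sum(d$batch_id == b), cfg$channels_per_batch)
  # every patient's samples live in one batch
  bt <- tapply(clin$batch_id, clin$patient_id, function(x) length(unique(x)))
  expect_true(all(bt == 1L))
  expect_error(sim_config(channels_per_batch = 6), "infeasible")
})

test_that("generation is byte-deterministic given the seed", {
  cfg <- small_cfg(seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("generated files round-trip through the readers with zero loss", {
  cfg <- small_cfg(seed = 10)
  out <- tempfile()
  sim <- simulate_study(cfg, out)
  design <- read_study_design(sim$paths$design)
  expect_equal(design$sample_id, sim$design$sample_id)
  sites <- read_site_table(sim$paths$sites, design)
  expect_equal(nrow(sites), cfg$n_features)
  keys <- site_key(sites$gene, sites$residue, sites$position)
  expect_equal(keys, sim$truth$features)
  net <- read_ks_network(sim$paths$network)
  expect_true(all(net$site_key %in% keys))
  tr <- sim$truth$differential
  expect_true(all(unlist(lapply(tr, `[[`, "site")) %in% keys))
  prot <- read_protein_table(sim$paths$proteins, design)
  expect_gt(nrow(prot), 0L)
  col <- read_gmt(sim$paths$gmt)
  expect_gt(length(col$sets), 10L)
})

test_that("missingness is left-censored: rates fall with abundance decile", {
  cfg <- sim_config(seed = 11)
  out <- tempfile()
  sim <- simulate_study(cfg, out)
  design <- read_study_design(sim$paths$design)
  sites <- read_site_table(sim$paths$sites, design)
  m <- as.matrix(sites[phoskit:::intensity_cols(sites)])
  abund <- rowMeans(log2(m), na.rm = TRUE)
  keep <- is.finite(abund)
  dec <- cut(abund[keep], stats::quantile(abund[keep], 0:10 / 10),
             include.lowest = TRUE, labels = FALSE)
  rate <- tapply(rowMeans(is.na(m))[keep], dec, mean)
  expect_true(all(diff(rate) <= 0.01))   # non-increasing up to sampling noise
  expect_gt(rate[1], rate[10])
})

test_that("a null configuration yields false positives near alpha and small correction", {
  cfg <- small_cfg(seed = 12, batch_tau = 0, delta_range = c(1, 1),
                   group_effect = 0, activity_delta = 0)
  out <- tempfile()
  sim <- simulate_study(cfg, out)
  design <- read_study_design(sim$paths$design)
  sites <- filter_artifacts(filter_class1(read_site_table(sim$paths$sites,
                                                          design)))
  qm <- log2_transform(build_quant_matrix(sites, design))
  qm_g <- impute_min(batch_presence_filter(median_center(reference_subtract(qm))))
  corrected <- combat_correct(qm_g)
  # with no batch effect the adjustment is pure estimation noise, far below
  # the data sd, and leaves grand structure intact
  rms <- sqrt(mean((corrected$matrix$values - qm_g$values)^2))
  expect_lt(rms, 0.4)
  expect_lt(rms, 0.8 * stats::sd(qm_g$values))

  qm_i <- normalize_for_individual(log2_transform(build_quant_matrix(sites,
                                                                     design)))
  net <- read_ks_network(sim$paths$network)
  pr <- ksea_profile(qm_i,
                     c(individual_contrasts(design, "post_vs_pre_t"),
                       individual_contrasts(design, "t_vs_nat")),
                     net)
  sig_rate <- mean(pr$significant, na.rm = TRUE)
  expect_lt(sig_rate, 0.18)   # ~alpha with few cells
})

test_that("truth_report recovers planted effects on the default configuration", {
  cfg <- sim_config(seed = 1)
  out <- tempfile()
  sim <- simulate_study(cfg, out)
  design <- read_study_design(sim$paths$design)
  sites <- filter_artifacts(filter_class1(read_site_table(sim$paths$sites,
                                                          design)))
  qm_log <- log2_transform(build_quant_matrix(sites, design))
  route <- normalize_group_route(build_quant_matrix(sites, design))
  d <- design[!design$is_reference, ]
  her2 <- group_compare(route$matrix,
                        d$sample_id[d$tissue == "T" & d$her2 == "positive" &
                                      d$timepoint == "pre"],
                        d$sample_id[d$tissue == "T" & d$her2 == "negative"],
                        mode = "welch")
  qm_i <- normalize_for_individual(qm_log)
  net <- read_ks_network(sim$paths$network)
  profiles <- list(
    treatment = ksea_profile(qm_i,
                             individual_contrasts(design, "post_vs_pre_t",
                                                  her2 = "positive"), net),
    tumor = ksea_profile(qm_i, individual_contrasts(design, "t_vs_nat"), net))
  rep <- truth_report(sim$truth, group_results = list(her2 = her2),
                      profiles = profiles,
                      qm_before = qm_log, qm_after = route$matrix)
  expect_gt(rep$differential$her2$recall, 0.5)
  expect_gt(rep$differential$her2$precision, 0.5)
  expect_gte(rep$kinase$overall$recovery, 0.9)
  expect_gt(rep$kinase$treatment$recovery, 0.8)
  expect_gt(rep$kinase$tumor$recovery, 0.8)
  expect_equal(rep$kinase$overall$sign_agreement, 1)
  expect_gt(rep$batch$reduction, 0.8)
})
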