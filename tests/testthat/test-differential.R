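welch_qm <- function(A, B) {
  d <- bare_design(c(paste0("A", seq_along(A)), paste0("B", seq_along(B))))
  v <- matrix(c(A, B), nrow = 1,
              dimnames = list("G1_S1", d$sample_id))
  qm_of(v, d, stage = "batch_corrected")
}

paired_qm <- function(post, pre) {
  n <- length(post)
  d <- design_df(batch_id = "B1", channel_id = paste0("C", seq_len(2 * n)),
                 sample_id = c(paste0("post", 1:n), paste0("pre", 1:n)),
                 patient_id = rep(paste0("P", 1:n), 2),
                 tissue = "T", her2 = "positive",
                 timepoint = rep(c("post", "pre"), each = n))
  v <- matrix(c(post, pre), nrow = 1,
              dimnames = list("G1_S1", d$sample_id))
  qm_of(v, d, stage = "batch_corrected")
}

test_that("Welch statistics match the hand-derived oracle and t.test on random instances", {
  qm <- welch_qm(c(1, 2, 3), c(2, 4, 6))
  res <- group_compare(qm, paste0("A", 1:3), paste0("B", 1:3), mode = "welch")
  expect_equal(res$log2FC, -2)
  expect_equal(res$t, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(res$df, 50 / 17, tolerance = 1e-12)

  set.seed(20)
  for (i in 1:50) {
    nA <- sample(3:8, 1); nB <- sample(3:8, 1)
    A <- rnorm(nA, sd = runif(1, 0.5, 2)); B <- rnorm(nB, sd = runif(1, 0.5, 2))
    res <- group_compare(welch_qm(A, B), paste0("A", 1:nA), paste0("B", 1:nB),
                         mode = "welch")
    tt <- stats::t.test(A, B)
    expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("group comparison is antisymmetric and degenerate cases are flagged", {
  set.seed(21)
  d <- bare_design(paste0("S", 1:8))
  v <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("G", 1:5, "_S1"), NULL))
  v[4, ] <- 1                      # zero variance, equal means
  v[5, 1:4] <- 2; v[5, 5:8] <- 1   # zero variance, unequal means
  qm <- qm_of(v, d, stage = "batch_corrected")
  ab <- group_compare(qm, paste0("S", 1:4), paste0("S", 5:8), mode = "welch")
  ba <- group_compare(qm, paste0("S", 5:8), paste0("S", 1:4), mode = "welch")
  expect_equal(ab$log2FC[1:3], -ba$log2FC[1:3], tolerance = 1e-12)
  expect_equal(ab$t[1:3], -ba$t[1:3], tolerance = 1e-12)
  expect_equal(ab$p[1:3], ba$p[1:3], tolerance = 1e-12)
  expect_equal(ab$t[4], 0)
  expect_equal(ab$p[4], 1)
  expect_equal(ab$class[5], "not_testable")
  expect_true(is.na(ab$p[5]))
})

test_that("paired mode tests the per-patient differences", {
  qm <- paired_qm(post = c(2.1, 3.2, 1.3), pre = c(1.0, 2.0, 0.0))
  res <- group_compare(qm, paste0("post", 1:3), paste0("pre", 1:3),
                       mode = "paired")
  expect_equal(res$log2FC, 1.2)
  tt <- stats::t.test(c(1.1, 1.2, 1.3))
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_lt(res$p, 0.05)
  expect_equal(res$class, "significant_up")

  # unpairable groups are a design error
  expect_error(group_compare(qm, paste0("post", 1:3), paste0("post", 1:3),
                             mode = "paired"), "patient_id")
})

test_that("classification applies strict fold-change and the tendency band", {
  res <- data.frame(
    feature = paste0("f", 1:7),
    log2FC = c(1.2, 1.2, 1.0, -1.2, 1.2, 1.2, 0.2),
    p = c(0.03, 0.07, 0.001, 0.03, 0.05, 0.1, 0.001))
  out <- classify_sites(res)
  expect_equal(out$class,
               c("significant_up", "tendency_up", "ns", "significant_down",
                 "tendency_up", "ns", "ns"))
  # p = 0.05 is a tendency, not significant; FC = 1.0 exactly is excluded
  tab <- table(factor(out$class,
                      c("significant_up", "significant_down", "tendency_up",
                        "tendency_down", "ns", "not_testable")))
  expect_equal(sum(tab), nrow(res))
})

test_that("individual comparisons flag |log2FC| > 1 and mark unquantified sites", {
  d <- bare_design(c("A", "B"))
  v <- rbind(G1_S1 = c(3.0, 1.5), G2_S2 = c(2, 2), G3_S3 = c(1, NA))
  qm <- qm_of(v, d, stage = "median_centered")
  res <- individual_compare(qm, "A", "B")
  expect_equal(res$log2FC[1], 1.5)
  expect_true(res$flagged[1])
  expect_false(res$flagged[2])
  expect_false(res$quantified[3])
  expect_true(is.na(res$log2FC[3]))
  expect_error(individual_compare(qm, "A", "nope"), "unknown sample")
})

test_that("pathway overlay keeps the strongest state per node", {
  res <- data.frame(
    feature = c("EGFR_S695", "EGFR_T693", "MYC_S62", "JUN_S73"),
    log2FC = c(2, 0.1, 1.4, NA),
    p = c(0.01, 0.8, 0.07, NA),
    class = c("significant_up", "ns", "tendency_up", "not_testable"))
  pw <- data.frame(pathway_id = "erbb", gene = c("EGFR", "MYC", "JUN", "AKT1"))
  out <- pathway_overlay(res, pw)
  expect_equal(out$state, c("significant", "tendency", "quantified_only",
                            "not_quantified"))
  expect_equal(out$n_sites[1], 2L)
  expect_equal(nrow(pathway_overlay(res, pw[0, ])), 0L)

  ind <- data.frame(feature = c("EGFR_S695", "MYC_S62"),
                    log2FC = c(1.5, NA), quantified = c(TRUE, FALSE),
                    flagged = c(TRUE, FALSE))
  out2 <- pathway_overlay(ind, c("EGFR", "MYC"))
  expect_equal(out2$state, c("significant", "not_quantified"))
})
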