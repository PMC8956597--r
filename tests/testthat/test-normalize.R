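test_that("log2 transform handles missing values and rejects non-positive intensities", {
  design <- toy_design_1b()
  v <- matrix(c(8, 1, NA, 4, 2, 16), nrow = 2, byrow = TRUE)
  qm <- qm_of(v, design, stage = "raw")
  out <- log2_transform(qm)
  expect_equal(out$stage, "raw_log2")
  expect_equal(out$values[1, ], c(REF_B1_1 = 3, S1 = 0, S2 = NA))
  bad <- qm_of(matrix(c(-1, 2, 3), 1), design, stage = "raw")
  expect_error(log2_transform(bad), "non-positive")
})

test_that("reference subtraction uses the within-batch reference mean and drops reference channels", {
  d <- design_df(batch_id = rep("B1", 4), channel_id = paste0("C", 1:4),
                 sample_id = c("R1", "R2", "S1", "S2"),
                 tissue = c("REF", "REF", "T", "NAT"))
  v <- rbind(c(6, 7, 9.5, 6.5),     # refs 6,7 -> mean 6.5
             c(NA, NA, 5, 3),       # no observed reference
             c(4, 4, 4, NA))
  qm <- qm_of(v, d)
  out <- reference_subtract(qm)
  expect_equal(out$stage, "ref_subtracted")
  expect_equal(colnames(out$values), c("S1", "S2"))
  expect_equal(out$values[1, ], c(S1 = 3, S2 = 0))
  expect_true(all(is.na(out$values[2, ])))   # undefined ratio
  expect_equal(out$values[3, ], c(S1 = 0, S2 = NA))

  no_ref <- design_df(batch_id = "B1", channel_id = "C1",
                      sample_id = "S1", tissue = "T")
  expect_error(reference_subtract(qm_of(matrix(1), no_ref)),
               "no reference channel")
})

test_that("median centering zeroes each column's observed median, even counts included", {
  d <- bare_design(c("A", "B", "C"))
  v <- cbind(A = c(1, 2, 3, 4), B = c(1, NA, 3, NA), C = c(5, 5, 5, 5))
  qm <- qm_of(v, d)
  out <- median_center(qm)
  expect_equal(out$values[, "A"], c(1, 2, 3, 4) - 2.5)
  expect_equal(out$values[, "B"], c(-1, NA, 1, NA))
  for (j in 1:3) {
    col <- out$values[, j]
    expect_lt(abs(stats::median(col[!is.na(col)])), 1e-9)
  }
  empty_col <- qm_of(cbind(A = c(1, 2), B = c(NA_real_, NA_real_),
                           C = c(0, 0)), d)
  expect_warning(median_center(empty_col), "no observed values")
})

test_that("batch presence filter requires one observation per batch", {
  d <- design_df(batch_id = c("B1", "B1", "B2", "B2"),
                 channel_id = rep(c("C1", "C2"), 2),
                 sample_id = paste0("S", 1:4), tissue = "T")
  v <- rbind(all4 = c(1, 2, 3, 4),
             b1only = c(1, 2, NA, NA),
             sparse = c(NA, 5, 6, NA))
  qm <- qm_of(v, d)
  out <- batch_presence_filter(qm)
  expect_setequal(rownames(out$values), c("all4", "sparse"))

  single <- bare_design(paste0("S", 1:4))
  out1 <- batch_presence_filter(qm_of(v, single))
  expect_equal(nrow(out1$values), 3L)  # single batch: observed at least once
})

test_that("minimum imputation fills missing cells with the feature minimum and touches nothing else", {
  d <- bare_design(c("A", "B", "C"))
  v <- rbind(x = c(2, NA, 5), y = c(1, 2, 3), z = c(-1, NA, 4))
  qm <- qm_of(v, d, stage = "median_centered")
  out <- impute_min(qm)
  expect_false(anyNA(out$values))
  expect_equal(out$values["x", ], c(A = 2, B = 2, C = 5))
  expect_equal(out$values["y", ], c(A = 1, B = 2, C = 3))
  expect_equal(out$values["z", ], c(A = -1, B = -1, C = 4))
  # never increases a row minimum, never changes observed cells
  expect_equal(apply(out$values, 1, min), apply(v, 1, min, na.rm = TRUE))
  expect_equal(out$values[!is.na(v)], v[!is.na(v)])

  allna <- qm_of(rbind(c(NA_real_, NA_real_, NA_real_)), d,
                 stage = "median_centered")
  expect_error(impute_min(allna), "no observed value")
})

test_that("individual route keeps clinical channels only and centers them independently", {
  d <- design_df(batch_id = rep("B1", 3), channel_id = paste0("C", 1:3),
                 sample_id = c("R1", "S1", "S2"),
                 tissue = c("REF", "T", "NAT"))
  v <- rbind(c(10, 1, 4), c(10, 2, 5), c(10, 3, 9))
  qm <- qm_of(v, d, stage = "raw")
  out <- normalize_for_individual(log2_transform(qm_of(2^v, d, "raw")))
  expect_equal(colnames(out$values), c("S1", "S2"))
  expect_equal(out$values[, "S1"], c(-1, 0, 1))
  expect_equal(out$values[, "S2"], c(-1, 0, 4))
})

test_that("stage transitions are enforced in the declared order", {
  design <- toy_design_1b()
  qm <- qm_of(matrix(1:6, 2), design, stage = "raw")
  expect_error(reference_subtract(qm), "stage")
  expect_error(log2_transform(log2_transform(qm)), "stage")
})

test_that("quant matrices round-trip through TSV + JSON sidecar", {
  set.seed(8)
  d <- bare_design(c("A", "B"), batch_id = c("B1", "B2"))
  v <- matrix(rnorm(10), 5, 2,
              dimnames = list(paste0("G", 1:5, "_S", 1:5), NULL))
  v[2, 1] <- NA
  qm <- qm_of(v, d)
  path <- tempfile(fileext = ".tsv")
  write_quant_matrix(qm, path)
  back <- read_quant_matrix(path)
  expect_equal(back$values, qm$values)
  expect_equal(back$stage, qm$stage)
  expect_equal(back$design$sample_id, qm$design$sample_id)
})
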