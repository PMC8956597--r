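test_that("site table parsing maps channels through the design and treats zero as missing", {
  set.seed(1)
  design <- toy_design_1b()
  df <- toy_site_rows(3, design)
  df$intensity.B1.C2[2] <- 0
  path <- write_toy_sites(df, tempfile(fileext = ".tsv"))
  x <- read_site_table(path, design)
  expect_s3_class(x, "site_table")
  expect_equal(nrow(x), 3L)
  ch <- attr(x, "channels")
  expect_equal(nrow(ch), 3L)
  expect_setequal(ch$sample_id, design$sample_id)
  expect_true(is.na(x$intensity.B1.C2[2]))
  expect_false(anyNA(x$intensity.B1.C1))
})

test_that("malformed site tables fail with informative errors", {
  set.seed(1)
  design <- toy_design_1b()
  df <- toy_site_rows(2, design)
  no_prob <- df[setdiff(names(df), "localization_prob")]
  p1 <- write_toy_sites(no_prob, tempfile(fileext = ".tsv"))
  expect_error(read_site_table(p1, design), "localization_prob")

  stray <- df
  stray$intensity.B9.C1 <- 1000
  p2 <- write_toy_sites(stray, tempfile(fileext = ".tsv"))
  expect_error(read_site_table(p2, design), "absent from the study design")

  garbled <- df
  garbled$intensity.B1.C1 <- c("12,5", "100")
  p3 <- write_toy_sites(garbled, tempfile(fileext = ".tsv"))
  expect_error(read_site_table(p3, design), "unparseable intensity")
})

test_that("identification filters apply the strict class-1 cut and artifact removal", {
  design <- toy_design_1b()
  set.seed(2)
  df <- toy_site_rows(4, design)
  df$localization_prob <- c(0.76, 0.75, 0.5, 1.0)
  df$reverse <- c("", "", "", "+")
  path <- write_toy_sites(df, tempfile(fileext = ".tsv"))
  x <- read_site_table(path, design)

  cl1 <- filter_class1(x)
  expect_equal(cl1$site_id, c("s1", "s4"))  # 0.75 itself is excluded
  expect_equal(nrow(filter_class1(x, threshold = 0)), 4L)
  expect_equal(nrow(filter_class1(x[x$localization_prob == 0.5, ])), 0L)

  kept <- filter_artifacts(x)
  expect_equal(kept$site_id, c("s1", "s2", "s3"))
  expect_equal(nrow(filter_artifacts(x[0, ])), 0L)

  # order of the two filters does not matter
  a <- filter_artifacts(filter_class1(x))
  b <- filter_class1(filter_artifacts(x))
  expect_equal(a$site_id, b$site_id)
})

test_that("protein groups are filtered on razor+unique peptide evidence", {
  set.seed(3)
  design <- toy_design_1b()
  df <- data.frame(protein_group_id = c("PG1", "PG2", "PG3"),
                   accessions = c("A1", "A2;A2b", "A3"),
                   peptide_count = c(2L, 1L, 5L),
                   reverse = "", contaminant = "",
                   stringsAsFactors = FALSE)
  for (ic in paste0("intensity.", design$batch_id, ".", design$channel_id))
    df[[ic]] <- c(1e6, 2e6, 3e6)
  path <- write_toy_sites(df, tempfile(fileext = ".tsv"))
  x <- read_protein_table(path, design)
  expect_equal(filter_protein_groups(x)$protein_group_id, c("PG1", "PG3"))
  expect_equal(nrow(filter_protein_groups(x, min_peptides = 1)), 3L)
  expect_equal(nrow(filter_protein_groups(x[0, ])), 0L)
})

test_that("residue composition reproduces published-style percentages with half-up rounding", {
  # published identification counts as a worked example
  comp <- residue_composition(c(S = 12059, T = 2307, Y = 256))
  expect_equal(comp$n_class1, 14622)
  expect_equal(comp$pct_S, 82.5)
  expect_equal(comp$pct_T, 15.8)
  expect_equal(comp$pct_Y, 1.8)
  expect_lt(abs(comp$pct_S + comp$pct_T + comp$pct_Y - 100), 0.2)

  expect_equal(residue_composition(c(S = 1, T = 0, Y = 0))$pct_S, 100.0)
  forced <- residue_composition(c(S = 1, T = 1, Y = 2))
  expect_equal(c(forced$pct_S, forced$pct_T, forced$pct_Y), c(25, 25, 50))
  expect_error(residue_composition(data.frame()[0, ]), "empty")
})

test_that("presence summary classifies features over the three groups", {
  design <- toy_design_1b()
  set.seed(4)
  df <- toy_site_rows(4, design)
  # s1: all three; s2: REF only; s3: T+NAT only; s4: absent everywhere
  df$intensity.B1.C2[c(2, 4)] <- 0   # T
  df$intensity.B1.C3[c(2, 4)] <- 0   # NAT
  df$intensity.B1.C1[c(3, 4)] <- 0   # REF
  path <- write_toy_sites(df, tempfile(fileext = ".tsv"))
  x <- read_site_table(path, design)
  qs <- quantified_summary(x, design)
  expect_equal(qs$n_quantified, 3L)
  expect_equal(qs$pct_quantified, 75.0)
  expect_equal(qs$pct_all_three, 33.3)
  expect_equal(qs$pct_ref_only, 33.3)
  expect_equal(qs$pct_other, 33.3)
})

test_that("a written site table round-trips records and missingness exactly", {
  set.seed(5)
  design <- toy_design_1b()
  df <- toy_site_rows(5, design)
  df$intensity.B1.C1[c(1, 3)] <- 0
  p1 <- write_toy_sites(df, tempfile(fileext = ".tsv"))
  x <- read_site_table(p1, design)
  p2 <- tempfile(fileext = ".tsv")
  write_site_table(x, p2)
  y <- read_site_table(p2, design)
  expect_equal(y, x, ignore_attr = TRUE)
  expect_identical(is.na(y$intensity.B1.C1), is.na(x$intensity.B1.C1))
})
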