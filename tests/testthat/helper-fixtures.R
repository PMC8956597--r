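# Fixtures are built in code; oracles here are independent of the
# implementation paths they check.

design_df <- function(batch_id, channel_id, sample_id,
                      patient_id = NA_character_, tissue,
                      her2 = NA_character_, timepoint = NA_character_) {
  d <- data.frame(batch_id = batch_id, channel_id = channel_id,
                  sample_id = sample_id,
                  patient_id = as.character(patient_id), tissue = tissue,
                  her2 = as.character(her2),
                  timepoint = as.character(timepoint),
                  is_reference = tissue == "REF", stringsAsFactors = FALSE)
  class(d) <- c("study_design", "data.frame")
  d
}

# one batch, one reference + two clinical channels
toy_design_1b <- function() {
  design_df(batch_id = c("B1", "B1", "B1"),
            channel_id = c("C1", "C2", "C3"),
            sample_id = c("REF_B1_1", "S1", "S2"),
            patient_id = c(NA, "P1", "P1"),
            tissue = c("REF", "T", "NAT"))
}

qm_of <- function(values, design, stage = "raw_log2") {
  phoskit:::new_quant_matrix(values, design, stage)
}

# plain design (no reference) for matrix-level statistics
bare_design <- function(sample_id, batch_id = "B1",
                        patient_id = NA_character_, tissue = "T",
                        her2 = NA_character_, timepoint = NA_character_) {
  design_df(batch_id = rep_len(batch_id, length(sample_id)),
            channel_id = paste0("C", seq_along(sample_id)),
            sample_id = sample_id,
            patient_id = rep_len(as.character(patient_id), length(sample_id)),
            tissue = rep_len(tissue, length(sample_id)),
            her2 = rep_len(as.character(her2), length(sample_id)),
            timepoint = rep_len(as.character(timepoint), length(sample_id)))
}

write_toy_sites <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_site_rows <- function(n = 3, design = toy_design_1b(), gene = NULL) {
  icols <- paste0("intensity.", design$batch_id, ".", design$channel_id)
  df <- data.frame(
    site_id = paste0("s", seq_len(n)),
    protein = paste0("ACC", seq_len(n)),
    gene = if (is.null(gene)) paste0("G", seq_len(n)) else gene,
    residue = rep_len(c("S", "T", "Y"), n),
    position = seq_len(n) * 10L,
    localization_prob = rep_len(c(0.99, 0.8, 0.95), n),
    reverse = "", contaminant = "",
    stringsAsFactors = FALSE)
  for (ic in icols) df[[ic]] <- round(stats::runif(n, 1e5, 1e7), 1)
  df
}

# --- independent oracles --------------------------------------------------

# per-batch standardization closed form (non-EB adjustment), written
# directly from the location/scale definition
combat_noeb_oracle <- function(x, batch) {
  blev <- unique(batch)
  ns <- vapply(blev, function(b) sum(batch == b), 0L)
  bhat <- vapply(blev, function(b) rowMeans(x[, batch == b, drop = FALSE]),
                 numeric(nrow(x)))
  grand <- as.vector(bhat %*% (ns / ncol(x)))
  varp <- rowSums((x - bhat[, match(batch, blev)])^2) / ncol(x)
  out <- x
  for (b in blev) {
    i <- batch == b
    m <- rowMeans(x[, i, drop = FALSE])
    s <- apply(x[, i, drop = FALSE], 1, stats::sd)
    out[, i] <- (x[, i] - m) / s * sqrt(varp) + grand
  }
  out
}

# upper-tail hypergeometric by exhaustive enumeration of all draws of n
# elements from a universe of N with m marked, falling back to an explicit
# combinatorial sum when enumeration is too large
hyper_upper_oracle <- function(N, m, n, k) {
  if (choose(N, n) <= 2e5) {
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= m)  # elements 1..m are the marked ones
    return(sum(hits >= k) / ncol(draws))
  }
  j <- k:min(m, n)
  sum(choose(m, j) * choose(N - m, n - j)) / choose(N, n)
}

# permutation p for a substrate set: redraw m sites from the fold-change
# background and compare the mean shift
ksea_perm_p <- function(fc, m, mean_sub, B = 1e5) {
  obs <- abs(mean_sub - mean(fc))
  perm <- vapply(seq_len(B),
                 function(i) mean(fc[sample.int(length(fc), m)]), 0)
  (1 + sum(abs(perm - mean(fc)) >= obs)) / (B + 1)
}
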