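# Reading and filtering of search-engine phosphosite/protein-group exports
# and the study-design table that maps (batch, channel) to samples.

#' Column map for site/protein table dialects
#'
#' Search-engine exports differ in column naming; a column map declares where
#' each mandatory field lives and how per-channel reporter-intensity columns
#' are named. Intensity columns are `<prefix><batch_id>.<channel_id>`
#' (e.g. `intensity.B1.C3`). Flag columns use the `"+"` marker dialect:
#' a cell equal to `flag_marker` means the flag is set.
#'
#' @param site_id,protein,gene,residue,position,localization_prob,reverse,contaminant
#'   column names for the annotation fields.
#' @param intensity_prefix prefix identifying reporter-intensity columns.
#' @param flag_marker string marking a set flag (default `"+"`).
#' @return named list usable as `col_map` in [read_site_table()].
#' @export
site_col_map <- function(site_id = "site_id", protein = "protein",
                         gene = "gene", residue = "residue",
                         position = "position",
                         localization_prob = "localization_prob",
                         reverse = "reverse", contaminant = "contaminant",
                         intensity_prefix = "intensity.",
                         flag_marker = "+") {
  list(site_id = site_id, protein = protein, gene = gene, residue = residue,
       position = position, localization_prob = localization_prob,
       reverse = reverse, contaminant = contaminant,
       intensity_prefix = intensity_prefix, flag_marker = flag_marker)
}

#' @rdname site_col_map
#' @param protein_group_id,accessions,peptide_count column names for the
#'   protein-group table fields.
#' @export
protein_col_map <- function(protein_group_id = "protein_group_id",
                            accessions = "accessions",
                            peptide_count = "peptide_count",
                            reverse = "reverse", contaminant = "contaminant",
                            intensity_prefix = "intensity.",
                            flag_marker = "+") {
  list(protein_group_id = protein_group_id, accessions = accessions,
       peptide_count = peptide_count, reverse = reverse,
       contaminant = contaminant, intensity_prefix = intensity_prefix,
       flag_marker = flag_marker)
}

#' Read a study-design table
#'
#' The design maps every used TMT channel to its sample: batch, channel,
#' sample id, patient, tissue (`T`, `NAT` or `REF` for the pooled cell-line
#' reference), HER2 status, timepoint and a reference flag. Empty
#' `patient_id`, `her2` or `timepoint` cells become `NA` (references and,
#' e.g., HER2-negative patients have no timepoint pairing).
#'
#' @param path TSV file with columns `batch_id`, `channel_id`, `sample_id`,
#'   `patient_id`, `tissue`, `her2`, `timepoint`, `is_reference`.
#' @return data.frame of class `study_design`.
#' @export
read_study_design <- function(path) {
  d <- read_tsv(path, colClasses = "character")
  needed <- c("batch_id", "channel_id", "sample_id", "patient_id", "tissue",
              "her2", "timepoint", "is_reference")
  miss <- setdiff(needed, names(d))
  if (length(miss))
    stopf("study design is missing column(s): %s", paste(miss, collapse = ", "))
  d <- d[needed]
  d$is_reference <- toupper(d$is_reference) %in% c("TRUE", "T", "1", "YES")
  for (col in c("patient_id", "her2", "timepoint"))
    d[[col]][d[[col]] == "" | is.na(d[[col]])] <- NA_character_
  validate_design(d)
  class(d) <- c("study_design", "data.frame")
  d
}

validate_design <- function(d) {
  key <- paste(d$batch_id, d$channel_id)
  if (anyDuplicated(key))
    stopf("duplicated (batch, channel) in design: %s", key[duplicated(key)][1])
  bad <- d$is_reference != (d$tissue == "REF")
  if (any(bad))
    stopf("is_reference must hold exactly for tissue REF (sample %s)",
          d$sample_id[bad][1])
  no_ref <- setdiff(unique(d$batch_id), unique(d$batch_id[d$is_reference]))
  if (length(no_ref))
    stopf("batch %s has no reference channel", no_ref[1])
  if (anyDuplicated(d$sample_id))
    stopf("duplicated sample_id in design: %s",
          d$sample_id[duplicated(d$sample_id)][1])
  invisible(d)
}

# Locate and validate intensity columns against the design.
# Returns data.frame(col, batch_id, channel_id, sample_id).
match_intensity_cols <- function(cols, design, prefix) {
  icols <- cols[startsWith(cols, prefix)]
  if (!length(icols)) stopf("no intensity columns with prefix '%s'", prefix)
  body <- substring(icols, nchar(prefix) + 1L)
  parts <- regmatches(body, regexpr("\\.", body), invert = TRUE)
  ok <- lengths(parts) == 2L
  if (any(!ok)) stopf("cannot parse intensity column '%s'", icols[!ok][1])
  bt <- vapply(parts, `[`, "", 1L)
  ch <- vapply(parts, `[`, "", 2L)
  dkey <- paste(design$batch_id, design$channel_id)
  fkey <- paste(bt, ch)
  unknown <- !(fkey %in% dkey)
  if (any(unknown))
    stopf("intensity column for (batch %s, channel %s) is absent from the study design",
          bt[unknown][1], ch[unknown][1])
  data.frame(col = icols, batch_id = bt, channel_id = ch,
             sample_id = design$sample_id[match(fkey, dkey)],
             stringsAsFactors = FALSE)
}

parse_intensities <- function(raw, channels) {
  m <- as.matrix(raw[channels$col])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))
  bad <- is.na(num) & !(is.na(m) | m == "" | toupper(m) == "NA")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stopf("unparseable intensity cell '%s' (row %d, column %s)",
          m[bad][1], idx[1], channels$col[idx[2]])
  }
  if (any(num < 0, na.rm = TRUE)) stopf("negative reporter intensity found")
  num[!is.na(num) & num == 0] <- NA_real_  # zero means not quantified
  num
}

#' Read a phosphosite table
#'
#' Parses a tab-separated search-engine site export, converts per-channel
#' reporter intensities to numeric (zero intensities become missing), and
#' validates annotations. Every intensity column must correspond to a
#' (batch, channel) present in the study design.
#'
#' @param path TSV file path.
#' @param design a `study_design` from [read_study_design()].
#' @param col_map column map from [site_col_map()].
#' @return data.frame of class `site_table`: annotation columns `site_id`,
#'   `protein`, `gene`, `residue`, `position`, `localization_prob`,
#'   `is_reverse`, `is_contaminant`, then one numeric column per design
#'   channel named `intensity.<batch>.<channel>`; attribute `"channels"`
#'   maps those columns to the design.
#' @export
read_site_table <- function(path, design, col_map = site_col_map()) {
  raw <- read_tsv(path, colClasses = "character")
  needed <- unlist(col_map[c("site_id", "protein", "gene", "residue",
                             "position", "localization_prob",
                             "reverse", "contaminant")])
  miss <- setdiff(needed, names(raw))
  if (length(miss))
    stopf("site table is missing mandatory column(s): %s",
          paste(miss, collapse = ", "))
  channels <- match_intensity_cols(names(raw), design, col_map$intensity_prefix)
  x <- data.frame(
    site_id = raw[[col_map$site_id]],
    protein = raw[[col_map$protein]],
    gene = raw[[col_map$gene]],
    residue = raw[[col_map$residue]],
    position = as.integer(raw[[col_map$position]]),
    localization_prob = as.numeric(raw[[col_map$localization_prob]]),
    is_reverse = raw[[col_map$reverse]] == col_map$flag_marker,
    is_contaminant = raw[[col_map$contaminant]] == col_map$flag_marker,
    stringsAsFactors = FALSE
  )
  if (any(!x$residue %in% c("S", "T", "Y")))
    stopf("residue must be one of S/T/Y (site %s)",
          x$site_id[!x$residue %in% c("S", "T", "Y")][1])
  if (any(x$position < 1L, na.rm = TRUE)) stopf("position must be >= 1")
  if (any(x$localization_prob < 0 | x$localization_prob > 1, na.rm = TRUE))
    stopf("localization_prob must lie in [0, 1]")
  ints <- parse_intensities(raw, channels)
  colnames(ints) <- paste0("intensity.", channels$batch_id, ".",
                           channels$channel_id)
  x <- cbind(x, as.data.frame(ints))
  attr(x, "channels") <- transform(channels, col = colnames(ints))
  class(x) <- c("site_table", "data.frame")
  x
}

#' Read a protein-group table
#'
#' @inheritParams read_site_table
#' @param col_map column map from [protein_col_map()].
#' @return data.frame of class `protein_table` with `protein_group_id`,
#'   `accessions` (`;`-separated), `peptide_count` (razor + unique),
#'   flags, and intensity columns as in [read_site_table()].
#' @export
read_protein_table <- function(path, design, col_map = protein_col_map()) {
  raw <- read_tsv(path, colClasses = "character")
  needed <- unlist(col_map[c("protein_group_id", "accessions",
                             "peptide_count", "reverse", "contaminant")])
  miss <- setdiff(needed, names(raw))
  if (length(miss))
    stopf("protein table is missing mandatory column(s): %s",
          paste(miss, collapse = ", "))
  channels <- match_intensity_cols(names(raw), design, col_map$intensity_prefix)
  x <- data.frame(
    protein_group_id = raw[[col_map$protein_group_id]],
    accessions = raw[[col_map$accessions]],
    peptide_count = as.integer(raw[[col_map$peptide_count]]),
    is_reverse = raw[[col_map$reverse]] == col_map$flag_marker,
    is_contaminant = raw[[col_map$contaminant]] == col_map$flag_marker,
    stringsAsFactors = FALSE
  )
  if (any(x$peptide_count < 0L, na.rm = TRUE))
    stopf("peptide_count must be non-negative")
  ints <- parse_intensities(raw, channels)
  colnames(ints) <- paste0("intensity.", channels$batch_id, ".",
                           channels$channel_id)
  x <- cbind(x, as.data.frame(ints))
  attr(x, "channels") <- transform(channels, col = colnames(ints))
  class(x) <- c("protein_table", "data.frame")
  x
}

#' Write a site table back to TSV
#'
#' Inverse of [read_site_table()]: missing intensities are written as `0`
#' and flags in the `"+"` marker dialect, so a written table re-reads to
#' identical records and missingness pattern.
#'
#' @param x a `site_table`.
#' @param path output TSV path.
#' @export
write_site_table <- function(x, path) {
  ann <- data.frame(
    site_id = x$site_id, protein = x$protein, gene = x$gene,
    residue = x$residue, position = x$position,
    localization_prob = x$localization_prob,
    reverse = ifelse(x$is_reverse, "+", ""),
    contaminant = ifelse(x$is_contaminant, "+", ""),
    stringsAsFactors = FALSE
  )
  ints <- as.matrix(x[intensity_cols(x)])
  ints[is.na(ints)] <- 0
  write_tsv(cbind(ann, as.data.frame(ints)), path)
}

intensity_cols <- function(x) {
  ch <- attr(x, "channels")
  if (is.null(ch)) grep("^intensity\\.", names(x), value = TRUE) else ch$col
}

#' Identification filters
#'
#' `filter_class1()` keeps class-1 sites, i.e. localization probability
#' strictly greater than the threshold (default 0.75). `filter_artifacts()`
#' drops reverse-database and potential-contaminant hits (site or protein
#' tables). `filter_protein_groups()` keeps protein groups identified with
#' at least `min_peptides` razor + unique peptides.
#'
#' @param x a `site_table` or `protein_table`.
#' @param threshold localization-probability cut-off in `[0, 1]`.
#' @return the filtered table, row order preserved.
#' @export
filter_class1 <- function(x, threshold = 0.75) {
  stopifnot(threshold >= 0, threshold <= 1)
  x[!is.na(x$localization_prob) & x$localization_prob > threshold, ,
    drop = FALSE]
}

#' @rdname filter_class1
#' @export
filter_artifacts <- function(x) {
  x[!(x$is_reverse | x$is_contaminant), , drop = FALSE]
}

#' @rdname filter_class1
#' @param min_peptides minimum razor + unique peptide count (>= 1).
#' @export
filter_protein_groups <- function(x, min_peptides = 2) {
  stopifnot(min_peptides >= 1)
  x[x$peptide_count >= min_peptides, , drop = FALSE]
}

#' Residue composition of a set of phosphosites
#'
#' Counts phospho-serine/-threonine/-tyrosine sites and reports their
#' proportions as percentages to one decimal (half-up rounding).
#'
#' @param x a (typically class-1 filtered) `site_table`, or a named count
#'   vector/list with elements `S`, `T`, `Y` for worked examples on
#'   published counts.
#' @return list with `n_class1`, `n_S`, `n_T`, `n_Y`, `pct_S`, `pct_T`,
#'   `pct_Y`.
#' @export
residue_composition <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0L) stopf("residue_composition: empty site table")
    counts <- c(S = sum(x$residue == "S"), T = sum(x$residue == "T"),
                Y = sum(x$residue == "Y"))
  } else {
    counts <- c(S = as.numeric(x[["S"]]), T = as.numeric(x[["T"]]),
                Y = as.numeric(x[["Y"]]))
    if (anyNA(counts)) stopf("residue_composition: need counts S, T and Y")
    if (sum(counts) == 0) stopf("residue_composition: empty site table")
  }
  total <- sum(counts)
  pct <- round_half_up(100 * counts / total, 1)
  list(n_class1 = total, n_S = unname(counts["S"]), n_T = unname(counts["T"]),
       n_Y = unname(counts["Y"]), pct_S = unname(pct["S"]),
       pct_T = unname(pct["T"]), pct_Y = unname(pct["Y"]))
}

#' Presence summary over the three sample groups
#'
#' Classifies each quantified feature (observed in at least one channel) by
#' which of the three groups it was observed in: the pooled cell-line
#' reference (`REF`), tumor (`T`) and adjacent non-tumor tissue (`NAT`).
#'
#' @param x a `site_table` or `protein_table`.
#' @param design the `study_design`.
#' @return list with `n_total` (rows in `x`), `n_quantified` (observed in at
#'   least one sample), `pct_quantified`, and — over quantified features —
#'   `pct_all_three`, `pct_ref_only`, `pct_other` (percentages, one decimal).
#' @export
quantified_summary <- function(x, design) {
  ch <- attr(x, "channels")
  tissue <- design$tissue[match(ch$sample_id, design$sample_id)]
  m <- !is.na(as.matrix(x[ch$col]))
  in_grp <- sapply(c("REF", "T", "NAT"),
                   function(g) rowSums(m[, tissue == g, drop = FALSE]) > 0)
  quantified <- rowSums(m) > 0
  g <- in_grp[quantified, , drop = FALSE]
  all_three <- rowSums(g) == 3L
  ref_only <- g[, "REF"] & rowSums(g) == 1L
  nq <- sum(quantified)
  list(
    n_total = nrow(x),
    n_quantified = nq,
    pct_quantified = round_half_up(100 * nq / nrow(x), 1),
    pct_all_three = round_half_up(100 * sum(all_three) / nq, 1),
    pct_ref_only = round_half_up(100 * sum(ref_only) / nq, 1),
    pct_other = round_half_up(100 * sum(!all_three & !ref_only) / nq, 1)
  )
}
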