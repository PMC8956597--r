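# Small shared helpers.

#' Round half away from zero
#'
#' Decimal rounding where ties go up (0.05 -> 0.1), matching the common
#' reporting convention for percentages, rather than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Build the canonical phosphosite key
#'
#' Cross-table joins (site table, kinase-substrate edges, overlays) are keyed
#' by gene symbol plus residue and position, e.g. `"GSK3B_S9"`. When the gene
#' symbol is absent the protein accession is used as fallback.
#'
#' @param gene gene symbol (may be `NA` or `""`).
#' @param residue one of `"S"`, `"T"`, `"Y"`.
#' @param position 1-based integer residue position.
#' @param protein accession string, used when `gene` is missing.
#' @return character vector of site keys.
#' @export
site_key <- function(gene, residue, position, protein = NA_character_) {
  stem <- ifelse(is.na(gene) | gene == "", protein, gene)
  paste0(stem, "_", residue, position)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# TSV writer used for every artifact so outputs are byte-reproducible.
write_tsv <- function(df, path, rownames = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = rownames, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
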