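# Local hypergeometric over-representation analysis of differential gene
# lists against GMT gene-set collections.

#' Read a GMT gene-set collection
#'
#' Standard GMT lines: `set_id <tab> description <tab> gene1 <tab> ...`.
#' Gene symbols are upper-cased and deduplicated within each set.
#'
#' @param path GMT file path.
#' @return list of class `gene_set_collection`: `sets` (named list of
#'   character vectors), `names` (named description vector), `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warnf("read_gmt: '%s' contains no gene sets", path)
    return(structure(list(sets = list(), names = character(),
                          source = basename(path)),
                     class = "gene_set_collection"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short))
    stopf("read_gmt: line %d has fewer than 3 fields", which(short)[1])
  ids <- vapply(parts, `[`, "", 1L)
  desc <- vapply(parts, `[`, "", 2L)
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- ids
  names(desc) <- ids
  structure(list(sets = sets, names = desc, source = basename(path)),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, counts the overlap `k` between the hit list and the
#' set (both restricted to the universe) and computes the upper-tail
#' hypergeometric probability `P(X >= k)` of observing at least `k`
#' overlapping genes when `n = |hits|` genes are drawn from a universe of
#' `N` genes containing `m = |set in universe|` set members.
#'
#' @param hits character vector of hit genes (must be within `universe`).
#' @param universe character vector, the background gene universe
#'   (conventionally: all genes with at least one quantified phosphosite).
#' @param collection a `gene_set_collection` from [read_gmt()].
#' @param alpha significance threshold on the raw p (default 0.05).
#' @return data.frame sorted by p with `set_id`, `name`, `k`, `m`, `n`,
#'   `N`, `p`, `significant`, `genes` (`;`-separated overlap).
#' @export
ora <- function(hits, universe, collection, alpha = 0.05) {
  hits <- unique(toupper(hits))
  universe <- unique(toupper(universe))
  stray <- setdiff(hits, universe)
  if (length(stray))
    stopf("ora: hit gene(s) outside the universe: %s",
          paste(utils::head(stray, 5), collapse = ", "))
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(collection$sets), function(id) {
    set_u <- intersect(collection$sets[[id]], universe)
    m <- length(set_u)
    overlap <- intersect(hits, set_u)
    k <- length(overlap)
    p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(set_id = id, name = unname(collection$names[id]),
               k = k, m = m, n = n, N = N, p = p,
               significant = p < alpha,
               genes = paste(sort(overlap), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$set_id), , drop = FALSE]
}
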