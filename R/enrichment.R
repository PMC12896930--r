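#' Read / write gene sets in GMT format
#'
#' One set per line: `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT path.
#' @return named list of character vectors (set id -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    abort("each GMT line needs a set id, a description and at least one gene.",
          class = "mirstage_format_error")
  }
  ids <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(ids)) abort("duplicate set ids in GMT.", class = "mirstage_format_error")
  setNames(lapply(fields, function(f) unique(f[-(1:2)])), ids)
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @param descriptions optional named descriptions (defaults to the id).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% setNames(names(sets), names(sets))
  writeLines(vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query (e.g. the strongly regulated
#' genes of one contrast) overlaps the set more than expected when drawing
#' `n = |query|` genes without replacement from the universe. The p-value is
#' the exact upper tail P(X >= k); BH adjustment runs across sets, and a set
#' is called enriched when the adjusted p is below `alpha`.
#'
#' @param query character vector of genes; must lie within `universe`.
#' @param sets named list of gene sets (intersected with the universe).
#' @param universe character vector of background genes; defaults in the
#'   pipeline to all target genes of the interaction file.
#' @param alpha significance threshold on the adjusted p.
#' @return tibble: `set_id`, `k` (overlap), `K` (set size in universe),
#'   `N` (universe), `n` (query), `p`, `adj_p`, `enriched`.
#' @export
ora_test <- function(query, sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe) || !length(query)) {
    abort("query and universe must be non-empty.", class = "mirstage_schema_error")
  }
  if (!all(query %in% universe)) {
    abort("query genes must be contained in the universe.",
          class = "mirstage_schema_error")
  }
  res <- purrr::imap_dfr(sets, function(genes, id) {
    genes <- intersect(unique(genes), universe)
    k <- length(intersect(genes, query))
    tibble::tibble(set_id = id, k = k, K = length(genes),
                   N = length(universe), n = length(query),
                   p = phyper(k - 1, length(genes),
                              length(universe) - length(genes),
                              length(query), lower.tail = FALSE))
  })
  res$adj_p <- bh_adjust(res$p)
  res$enriched <- res$adj_p < alpha
  dplyr::arrange(res, .data$p)
}
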