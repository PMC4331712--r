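# Over-representation analysis: one-sided Fisher's exact test
# (hypergeometric upper tail) of a query gene list against gene sets.

#' One-sided Fisher over-representation p-value
#'
#' Computes the hypergeometric upper-tail probability
#' `P(X >= overlap)` of drawing at least the observed overlap when
#' `|query|` genes are drawn from the universe without replacement and
#' `|set|` of the universe genes belong to the set.  The gene set is
#' intersected with the universe first; the query must be a subset of the
#' universe.
#'
#' @param query character vector of query gene ids.
#' @param gene_set character vector of set member ids.
#' @param universe character vector of background gene ids.
#' @return The p-value (in `(0, 1]`).
#' @examples
#' fisher_ora(letters[1:5], letters[1:5], letters[1:20])  # 1/choose(20,5)
#' @export
fisher_ora <- function(query, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) abort_validation("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) {
    abort_validation("query contains genes outside the universe")
  }
  set_in <- unique(intersect(gene_set, universe))
  k <- length(intersect(query, set_in))
  # P(X >= k), X ~ Hypergeometric(|set|, N - |set|, |query|)
  stats::phyper(k - 1L, length(set_in), length(universe) - length(set_in),
                length(query), lower.tail = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name`, `description`, members...
#'
#' @param path GMT file path.
#' @return Named list of character vectors (unique members), with set
#'   descriptions in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    abort_validation("malformed GMT line ", bad[1L], " in ", path,
                     " (need name, description and >= 1 member)")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Run over-representation analysis across a gene-set collection
#'
#' Tests the query against every set with [fisher_ora()].  The
#' significance flag uses the raw p-value at `alpha` (fold-change-era
#' convention); a Benjamini-Hochberg adjusted column is reported alongside
#' for reference but does not drive the flag.
#'
#' @param query character vector of query gene ids.
#' @param collection named list of gene sets (e.g. [read_gmt()]).
#' @param universe character vector of background gene ids.
#' @param alpha raw-p significance threshold (default 0.05).
#' @return data.frame sorted by p-value with columns `set`, `overlap`,
#'   `query_size`, `set_size`, `universe_size`, `p`, `padj`,
#'   `significant`.
#' @export
run_collection <- function(query, collection, universe, alpha = 0.05) {
  if (!length(collection)) {
    abort_validation("empty gene-set collection")
  }
  if (is.null(names(collection)) || any(!nzchar(names(collection)))) {
    abort_validation("gene sets must be named")
  }
  universe <- unique(universe)
  query <- unique(query)
  res <- lapply(names(collection), function(nm) {
    set_in <- unique(intersect(collection[[nm]], universe))
    data.frame(set = nm,
               overlap = length(intersect(query, set_in)),
               query_size = length(query),
               set_size = length(set_in),
               universe_size = length(universe),
               p = fisher_ora(query, collection[[nm]], universe))
  })
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
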