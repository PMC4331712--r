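# Results-level network statistics: hubs, combinatorial regulation,
# co-targeting of a reference miRNA's target set, chromosomal clustering,
# and DEG coverage.

#' Find hub nodes by degree
#'
#' Reports the maximal degree on one side of a (sub)network together with
#' the complete tie-set of nodes attaining it (no arbitrary single
#' winner).  For miRNA-target networks the `subnetwork` argument restricts
#' edges to those whose regulator miRNA is up- or down-regulated.
#'
#' @param network a [regnet()].
#' @param side `"regulator"` (out-degree of edge sources) or `"target"`
#'   (in-degree of edge destinations).
#' @param subnetwork `"all"`, `"up"` or `"down"`: filter edges by the
#'   direction of the source (regulator) node.
#' @param kind restrict to edges of this kind (`"mti"`, `"tf_mirna"` or
#'   `"all"`).
#' @return A list of class `hub_report`: `side`, `subnetwork`,
#'   `max_degree`, `hubs` (tie-set of ids), `degrees` (full table sorted
#'   decreasingly), `empty` flag.
#' @export
find_hubs <- function(network, side = c("regulator", "target"),
                      subnetwork = c("all", "up", "down"), kind = "all") {
  stopifnot(inherits(network, "regnet"))
  side <- match.arg(side)
  subnetwork <- match.arg(subnetwork)
  ed <- network$edges
  if (kind != "all") ed <- ed[ed$kind == kind, , drop = FALSE]
  if (subnetwork != "all") {
    src_dir <- network$nodes$direction[match(ed$from, network$nodes$id)]
    ed <- ed[src_dir == subnetwork, , drop = FALSE]
  }
  ids <- if (side == "regulator") ed$from else ed$to
  hub_report_from_degrees(table(ids), side, subnetwork)
}

#' Hub report from a per-miRNA target-count table
#'
#' Convenience wrapper applying the hub definition directly to a
#' per-miRNA statistics table (columns `mirna`, `direction`,
#' `n_de_targets`), e.g. [per_mirna_target_counts()] output or the
#' bundled [fixture_mti_stats()] (whose `category` column is accepted as
#' the direction).
#'
#' @param stats_tbl the statistics table.
#' @param subnetwork `"all"`, `"up"` or `"down"`.
#' @return A `hub_report` (see [find_hubs()]).
#' @export
hubs_from_counts <- function(stats_tbl, subnetwork = c("all", "up", "down")) {
  subnetwork <- match.arg(subnetwork)
  dir_col <- if (!is.null(stats_tbl$direction)) stats_tbl$direction else stats_tbl$category
  stopifnot_cols(stats_tbl, c("mirna", "n_de_targets"), "statistics table")
  if (subnetwork != "all") {
    stats_tbl <- stats_tbl[dir_col == subnetwork, , drop = FALSE]
  }
  deg <- stats::setNames(stats_tbl$n_de_targets, stats_tbl$mirna)
  hub_report_from_degrees(deg, "regulator", subnetwork)
}

hub_report_from_degrees <- function(deg, side, subnetwork) {
  deg <- deg[deg > 0]
  if (!length(deg)) {
    return(structure(list(side = side, subnetwork = subnetwork,
                          max_degree = 0L, hubs = character(),
                          degrees = data.frame(id = character(),
                                               degree = integer()),
                          empty = TRUE),
                     class = "hub_report"))
  }
  deg <- sort(deg, decreasing = TRUE)
  mx <- max(deg)
  structure(list(side = side, subnetwork = subnetwork,
                 max_degree = as.integer(mx),
                 hubs = sort(names(deg)[deg == mx]),
                 degrees = data.frame(id = names(deg),
                                      degree = as.integer(deg)),
                 empty = FALSE),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("hub report (%s side, %s subnetwork): ", x$side, x$subnetwork))
  if (x$empty) cat("empty\n") else
    cat(sprintf("max degree %d (%s)\n", x$max_degree,
                paste(x$hubs, collapse = ", ")))
  invisible(x)
}

#' Combinatorial TF-miRNA regulation
#'
#' From a TF-miRNA network, derives the per-miRNA TF sets, per-TF miRNA
#' sets, and for every unordered TF pair the set of miRNAs regulated by
#' both (a symmetric relation reported in long format).
#'
#' @param tf_network a [regnet()] of TF->miRNA edges.
#' @return A list: `per_mirna` (data.frame `mirna`, `n_tfs`, `tfs`),
#'   `per_tf` (data.frame `tf`, `n_mirnas`, `mirnas`), `pairs`
#'   (data.frame `tf1`, `tf2`, `n_shared`, `mirnas` for pairs with
#'   `n_shared >= 1`).
#' @export
combinatorial_regulation <- function(tf_network) {
  stopifnot(inherits(tf_network, "regnet"))
  ed <- tf_network$edges[tf_network$edges$kind == "tf_mirna", , drop = FALSE]
  by_tf <- split(ed$to, ed$from)
  by_mir <- split(ed$from, ed$to)
  per_tf <- data.frame(tf = names(by_tf),
                       n_mirnas = lengths(by_tf),
                       mirnas = vapply(by_tf, function(x)
                         paste(sort(unique(x)), collapse = ","), character(1)))
  per_mirna <- data.frame(mirna = names(by_mir),
                          n_tfs = lengths(by_mir),
                          tfs = vapply(by_mir, function(x)
                            paste(sort(unique(x)), collapse = ","), character(1)))
  tfs <- sort(names(by_tf))
  pairs <- list()
  if (length(tfs) >= 2L) {
    cmb <- utils::combn(tfs, 2L)
    shared <- lapply(seq_len(ncol(cmb)), function(j) {
      sort(intersect(by_tf[[cmb[1L, j]]], by_tf[[cmb[2L, j]]]))
    })
    keep <- lengths(shared) > 0L
    pairs <- data.frame(tf1 = cmb[1L, keep], tf2 = cmb[2L, keep],
                        n_shared = lengths(shared)[keep],
                        mirnas = vapply(shared[keep], paste,
                                        character(1), collapse = ","))
  } else {
    pairs <- data.frame(tf1 = character(), tf2 = character(),
                        n_shared = integer(), mirnas = character())
  }
  rownames(per_tf) <- rownames(per_mirna) <- rownames(pairs) <- NULL
  list(per_mirna = per_mirna, per_tf = per_tf, pairs = pairs)
}

#' Co-targeting of a reference miRNA's target set
#'
#' For every DEmiR, intersects its curated target genes with the reference
#' target set (e.g. the validated targets of miR-122) and reports the
#' miRNAs sharing at least one gene, plus the union of shared genes.
#'
#' @param mti_records interaction records (kind `"mti"`).
#' @param reference character vector of reference target gene ids.
#' @param demirs data.frame (`mirna`, `direction`).
#' @param de_genes optional character vector; when supplied, curated
#'   targets are first restricted to these (DE) genes before
#'   intersecting.
#' @return data.frame (`mirna`, `direction`, `n_shared`, `shared`) for
#'   miRNAs with non-empty intersection, sorted by decreasing `n_shared`;
#'   the union of shared genes is in attribute `"union"`.
#' @export
co_targeting <- function(mti_records, reference, demirs, de_genes = NULL) {
  if (!length(reference)) abort_validation("empty reference target set")
  stopifnot_cols(demirs, c("mirna", "direction"), "DEmiR table")
  rec <- mti_records[mti_records$kind == "mti" &
                       mti_records$from %in% demirs$mirna, , drop = FALSE]
  if (!is.null(de_genes)) rec <- rec[rec$to %in% de_genes, , drop = FALSE]
  by_mir <- split(rec$to, rec$from)
  shared <- lapply(by_mir, function(g) sort(intersect(unique(g), reference)))
  keep <- lengths(shared) > 0L
  out <- data.frame(mirna = names(by_mir)[keep],
                    direction = demirs$direction[match(names(by_mir)[keep],
                                                       demirs$mirna)],
                    n_shared = lengths(shared)[keep],
                    shared = vapply(shared[keep], paste, character(1),
                                    collapse = ","))
  out <- out[order(-out$n_shared, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "union") <- sort(unique(unlist(shared[keep])))
  out
}

#' Chromosomal clustering of DEmiRs
#'
#' Counts DEmiRs per genomic region and direction.  Membership is decided
#' by the locus start coordinate (whole-chromosome regions, i.e. regions
#' with missing start/end, count every locus on that chromosome).
#' Optionally computes a hypergeometric enrichment p-value of region
#' membership among up-regulated DEmiRs relative to all DEmiRs.
#'
#' @param demir_loci data.frame with `mirna`, `direction`, `chrom`,
#'   `start` (e.g. [fixture_demir_table()]).
#' @param regions data.frame with `label`, `chrom` and optional `start`,
#'   `end` (NA = whole chromosome).
#' @param enrich compute the enrichment p-value per region?
#' @return data.frame with one row per region: `label`, `n_up`, `n_down`,
#'   `n_total`, and when `enrich = TRUE` a column `p_up` (upper-tail
#'   hypergeometric probability of at least `n_up` up-regulated members).
#' @export
chromosomal_clustering <- function(demir_loci, regions, enrich = FALSE) {
  stopifnot_cols(demir_loci, c("mirna", "direction", "chrom", "start"),
                 "DEmiR locus table")
  stopifnot_cols(regions, c("label", "chrom"), "region table")
  dir_col <- demir_loci$direction
  if (!nrow(regions)) {
    return(data.frame(label = character(), n_up = integer(),
                      n_down = integer(), n_total = integer()))
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    if (!r$chrom %in% demir_loci$chrom) {
      warning("region '", r$label, "': chromosome ", r$chrom,
              " absent from the locus table")
    }
    inside <- demir_loci$chrom == r$chrom
    if (!is.null(r$start) && !is.na(r$start)) {
      inside <- inside & demir_loci$start >= r$start & demir_loci$start <= r$end
    }
    n_up <- sum(inside & dir_col == "up")
    n_down <- sum(inside & dir_col == "down")
    out <- data.frame(label = r$label, n_up = n_up, n_down = n_down,
                      n_total = sum(inside))
    if (enrich) {
      # P(X >= n_up) drawing |UPmiRs| of the DEmiRs, n_total in the region
      n_up_all <- sum(dir_col == "up")
      out$p_up <- stats::phyper(n_up - 1L, sum(inside), nrow(demir_loci) -
                                  sum(inside), n_up_all, lower.tail = FALSE)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coverage of a reference DEG list by network targets
#'
#' Fraction of a reference differentially-expressed-gene list that appears
#' as a target in the (inverse-filtered) network.
#'
#' @param network a [regnet()] with mti edges, or a character vector of
#'   targeted gene ids.
#' @param reference character vector of reference DEG ids.
#' @return A list: `n_targeted` (overlap), `n_reference`, `fraction`.
#' @export
deg_coverage <- function(network, reference) {
  if (!length(reference)) abort_validation("empty reference DEG list")
  targeted <- if (inherits(network, "regnet")) {
    unique(network$edges$to[network$edges$kind == "mti"])
  } else {
    unique(as.character(network))
  }
  n <- length(intersect(targeted, reference))
  list(n_targeted = n, n_reference = length(reference),
       fraction = n / length(reference))
}
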