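# Regulatory-network assembly: active-node projection of curated
# interactions onto DE results and the inverse-expression filter.

#' Construct a regulatory network object
#'
#' The container used throughout the package: a typed node table
#' (`id`, `type` in TF/miRNA/gene, `direction` in up/down/none, flags) and
#' a directed edge table (`from`, `to`, `kind`, `evidence`).  miRNA->gene
#' (`mti`) edges are repressive by construction (sign -1), TF->miRNA edges
#' carry sign 0 (unknown).  Nodes not touching any edge are pruned.
#'
#' @param nodes data.frame with at least `id`, `type`, `direction`.
#' @param edges data.frame with `from`, `to`, `kind`, `evidence`.
#' @return An object of class `regnet`.
#' @export
regnet <- function(nodes, edges) {
  stopifnot_cols(nodes, c("id", "type", "direction"), "node table")
  stopifnot_cols(edges, c("from", "to", "kind", "evidence"), "edge table")
  if (anyDuplicated(nodes$id)) abort_validation("duplicate node ids")
  if (!all(nodes$type %in% c("TF", "miRNA", "gene"))) {
    abort_validation("node type must be TF, miRNA or gene")
  }
  if (!all(nodes$direction %in% c("up", "down", "none"))) {
    abort_validation("node direction must be up, down or none")
  }
  key <- paste(edges$from, edges$to, edges$kind)
  if (anyDuplicated(key)) abort_validation("duplicate edges")
  if (!all(c(edges$from, edges$to) %in% nodes$id)) {
    abort_validation("edge endpoints missing from node table")
  }
  if (is.null(nodes$is_mir122_target)) {
    nodes$is_mir122_target <- rep(FALSE, nrow(nodes))
  }
  if (is.null(nodes$chrom)) nodes$chrom <- rep(NA_character_, nrow(nodes))
  touched <- nodes$id %in% c(edges$from, edges$to)
  nodes <- nodes[touched, , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  cat("regulatory network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$nodes)) print(table(x$nodes$type, x$nodes$direction))
  invisible(x)
}

#' Build the TF-miRNA regulatory network
#'
#' Restricts curated TF->miRNA records to the high-confidence DEmiRs and
#' annotates nodes: miRNAs carry their DE direction, TFs carry an
#' expression direction when one is supplied (TFs without differential
#' expression are retained with direction `"none"`), and TFs in
#' `mir122_targets` are flagged.
#'
#' @param tf_records interaction records with kind `"tf_mirna"`.
#' @param demirs data.frame of high-confidence DEmiRs (`mirna`,
#'   `direction`), e.g. from [intersect_platforms()].
#' @param tf_expression optional data.frame (`id`, `direction`) of TF DE
#'   calls.
#' @param mir122_targets character vector of TF ids that are targets of
#'   the reference miRNA (flagged on the nodes).
#' @return A [regnet()].
#' @export
build_tf_mirna_network <- function(tf_records, demirs, tf_expression = NULL,
                                   mir122_targets = character()) {
  stopifnot_cols(demirs, c("mirna", "direction"), "DEmiR table")
  rec <- tf_records[tf_records$kind == "tf_mirna", , drop = FALSE]
  rec <- rec[rec$to %in% demirs$mirna, , drop = FALSE]
  tfs <- unique(rec$from)
  tf_dir <- rep("none", length(tfs))
  if (!is.null(tf_expression)) {
    stopifnot_cols(tf_expression, c("id", "direction"), "TF expression table")
    idx <- match(tfs, tf_expression$id)
    tf_dir[!is.na(idx)] <- tf_expression$direction[idx[!is.na(idx)]]
  }
  mir_idx <- match(unique(rec$to), demirs$mirna)
  nodes <- rbind(
    data.frame(id = tfs, type = rep("TF", length(tfs)), direction = tf_dir,
               is_mir122_target = tfs %in% mir122_targets),
    data.frame(id = demirs$mirna[mir_idx],
               type = rep("miRNA", length(mir_idx)),
               direction = demirs$direction[mir_idx],
               is_mir122_target = rep(FALSE, length(mir_idx))))
  regnet(nodes, rec)
}

#' Build the inverse-filtered miRNA-target network
#'
#' Keeps a curated miRNA-target edge only when the miRNA is a
#' high-confidence DEmiR, the gene is differentially expressed, and their
#' directions are opposite (repression: an up-regulated miRNA can explain
#' a down-regulated target and vice versa).  All non-mapping nodes are
#' removed.
#'
#' @param mti_records interaction records with kind `"mti"`.
#' @param demirs data.frame (`mirna`, `direction`).
#' @param gene_calls gene DE calls (`id`, `direction`), e.g. from
#'   [call_de_genes()]; genes with direction `"none"` are excluded.
#' @return A [regnet()].
#' @export
build_mti_network <- function(mti_records, demirs, gene_calls) {
  stopifnot_cols(demirs, c("mirna", "direction"), "DEmiR table")
  stopifnot_cols(gene_calls, c("id", "direction"), "gene DE calls")
  rec <- mti_records[mti_records$kind == "mti", , drop = FALSE]
  mir_dir <- demirs$direction[match(rec$from, demirs$mirna)]
  gene_dir <- gene_calls$direction[match(rec$to, gene_calls$id)]
  keep <- !is.na(mir_dir) & !is.na(gene_dir) &
    mir_dir %in% c("up", "down") & gene_dir %in% c("up", "down") &
    mir_dir != gene_dir
  rec <- rec[keep, , drop = FALSE]
  mirnas <- unique(rec$from); genes <- unique(rec$to)
  nodes <- rbind(
    data.frame(id = mirnas, type = rep("miRNA", length(mirnas)),
               direction = demirs$direction[match(mirnas, demirs$mirna)]),
    data.frame(id = genes, type = rep("gene", length(genes)),
               direction = gene_calls$direction[match(genes, gene_calls$id)]))
  regnet(nodes, rec)
}

#' Per-miRNA curated and DE target counts
#'
#' For every DEmiR reports the number of unique curated target genes in
#' the merged interaction database and its degree in the inverse-filtered
#' network (0 when absent).  The DE-target column sums to the network
#' edge count.
#'
#' @param mti_records merged interaction records (kind `"mti"`).
#' @param network the [regnet()] built from the same records.
#' @param demirs data.frame (`mirna`, `direction`).
#' @return data.frame with columns `mirna`, `direction`, `n_curated`,
#'   `n_de_targets`.
#' @export
per_mirna_target_counts <- function(mti_records, network, demirs) {
  stopifnot(inherits(network, "regnet"))
  rec <- mti_records[mti_records$kind == "mti", , drop = FALSE]
  cur <- table(factor(rec$from[!duplicated(paste(rec$from, rec$to))],
                      levels = demirs$mirna))
  mti_edges <- network$edges[network$edges$kind == "mti", , drop = FALSE]
  de <- table(factor(mti_edges$from, levels = demirs$mirna))
  data.frame(mirna = demirs$mirna,
             direction = demirs$direction,
             n_curated = as.integer(cur),
             n_de_targets = as.integer(de))
}

#' Export and import a regulatory network
#'
#' `export_network()` writes GraphML (node attributes `type`, `direction`,
#' `is_mir122_target`, `chrom`; edge attributes `kind`, `evidence`) and
#' optionally a flat edge TSV.  `import_network()` reads the GraphML back
#' into an equivalent [regnet()], so export/import round-trips losslessly.
#'
#' @param network a [regnet()].
#' @param graphml output GraphML path.
#' @param edge_tsv optional output TSV path (columns `src`, `dst`, `kind`,
#'   `evidence`).
#' @return `export_network()` the GraphML path, invisibly;
#'   `import_network()` a [regnet()].
#' @export
export_network <- function(network, graphml, edge_tsv = NULL) {
  stopifnot(inherits(network, "regnet"))
  nd <- network$nodes
  g <- igraph::graph_from_data_frame(
    d = if (nrow(network$edges)) {
      data.frame(from = network$edges$from, to = network$edges$to,
                 kind = network$edges$kind, evidence = network$edges$evidence)
    } else {
      data.frame(from = character(), to = character(),
                 kind = character(), evidence = character())
    },
    directed = TRUE,
    vertices = data.frame(name = nd$id, type = nd$type,
                          direction = nd$direction,
                          is_mir122_target = as.character(nd$is_mir122_target),
                          chrom = ifelse(is.na(nd$chrom), "", nd$chrom)))
  igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(edge_tsv)) {
    write_tsv_file(data.frame(src = network$edges$from,
                              dst = network$edges$to,
                              kind = network$edges$kind,
                              evidence = network$edges$evidence), edge_tsv)
  }
  invisible(graphml)
}

#' @rdname export_network
#' @param path GraphML path to read.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  nodes <- data.frame(id = va$name, type = va$type, direction = va$direction,
                      is_mir122_target = va$is_mir122_target == "TRUE",
                      chrom = ifelse(nzchar(va$chrom), va$chrom, NA_character_))
  el <- igraph::as_edgelist(g, names = TRUE)
  ea <- igraph::edge_attr(g)
  edges <- data.frame(from = el[, 1L], to = el[, 2L],
                      kind = if (!is.null(ea$kind)) ea$kind else character(0),
                      evidence = if (!is.null(ea$evidence)) ea$evidence else character(0))
  regnet(nodes, edges)
}
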