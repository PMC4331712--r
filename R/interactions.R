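# Curated interaction tables: parsing, peak-based TF-miRNA inference,
# source merging and name normalization.

#' Read interaction tables
#'
#' `read_tf_mirna_tsv()` reads a TransmiR-style table with columns
#' `tf`, `mirna`, `source`; `read_mti_tsv()` reads a miRTarBase-style table
#' with columns `mirna`, `gene`, `source` and optional `evidence` assay
#' tags.  Both return interaction records in the internal long format
#' (`from`, `to`, `kind`, `evidence`).
#'
#' @param path file path to a tab-separated table.
#' @return A data.frame of interaction records.
#' @export
read_tf_mirna_tsv <- function(path) {
  df <- read_tsv_file(path)
  stopifnot_cols(df, c("tf", "mirna", "source"), "TF-miRNA table")
  interaction_records(df$tf, df$mirna, kind = "tf_mirna", evidence = df$source)
}

#' @rdname read_tf_mirna_tsv
#' @export
read_mti_tsv <- function(path) {
  df <- read_tsv_file(path)
  stopifnot_cols(df, c("mirna", "gene", "source"), "MTI table")
  interaction_records(df$mirna, df$gene, kind = "mti", evidence = df$source)
}

#' Construct interaction records
#'
#' Builds the internal record format for curated directed interactions:
#' one row per unique (from, to, kind) with a comma-joined, sorted evidence
#' set.  Self-edges are rejected.
#'
#' @param from,to character vectors of node identifiers.
#' @param kind `"tf_mirna"` or `"mti"` (recycled).
#' @param evidence character vector of evidence source tags (must be
#'   non-empty strings).
#' @return A data.frame with columns `from`, `to`, `kind`, `evidence`.
#' @export
interaction_records <- function(from, to, kind, evidence) {
  n <- max(length(from), length(to))
  if (length(from) == 0L || length(to) == 0L) n <- 0L
  from <- rep_len(from, n)
  to <- rep_len(to, n)
  kind <- rep_len(kind, n)
  evidence <- rep_len(as.character(evidence), n)
  if (!all(kind %in% c("tf_mirna", "mti"))) {
    abort_validation("interaction kind must be 'tf_mirna' or 'mti'")
  }
  if (any(!nzchar(evidence))) {
    abort_validation("interaction records require a non-empty evidence tag")
  }
  if (any(from == to)) {
    abort_validation("self-edges are not allowed in interaction records: ",
                     from[from == to][1L])
  }
  df <- data.frame(from = from, to = to, kind = kind, evidence = evidence)
  merge_sources(df)
}

#' Merge interaction records from multiple sources
#'
#' Deduplicates by (from, to, kind) with union of the evidence sets, so the
#' operation is idempotent and order-independent.
#'
#' @param ... interaction-record data.frames (columns `from`, `to`, `kind`,
#'   `evidence`).
#' @return A single merged data.frame, with a summary of unique node and
#'   pair counts attached as attribute `"summary"` (see
#'   [interaction_summary()]).
#' @examples
#' a <- data.frame(from = "Tf1", to = "miR-1", kind = "tf_mirna",
#'                 evidence = "transmir")
#' b <- data.frame(from = "Tf1", to = "miR-1", kind = "tf_mirna",
#'                 evidence = "chipbase")
#' merge_sources(a, b)$evidence  # "chipbase,transmir"
#' @export
merge_sources <- function(...) {
  dfs <- list(...)
  df <- do.call(rbind, lapply(dfs, function(d) {
    stopifnot_cols(d, c("from", "to", "kind", "evidence"), "interaction table")
    d[c("from", "to", "kind", "evidence")]
  }))
  # split every evidence string into tags, then re-aggregate per pair
  key <- paste(df$from, df$to, df$kind, sep = "\r")
  ev <- tapply(df$evidence, key,
               function(e) evidence_join(unlist(evidence_split(e))))
  first <- !duplicated(key)
  out <- df[first, c("from", "to", "kind")]
  out$evidence <- unname(ev[key[first]])
  out <- out[order(out$kind, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- interaction_summary(out)
  out
}

#' Summarize an interaction-record table
#'
#' @param records interaction records (`from`, `to`, `kind`, `evidence`).
#' @return A list with unique TF / miRNA / gene / pair counts per kind.
#' @export
interaction_summary <- function(records) {
  tf <- records[records$kind == "tf_mirna", , drop = FALSE]
  mti <- records[records$kind == "mti", , drop = FALSE]
  list(
    n_tf_mirna_pairs = nrow(tf),
    n_tfs = length(unique(tf$from)),
    n_tf_mirnas = length(unique(tf$to)),
    n_mti_pairs = nrow(mti),
    n_mti_mirnas = length(unique(mti$from)),
    n_mti_genes = length(unique(mti$to))
  )
}

#' Infer TF-miRNA interactions from ChIP-Seq peaks
#'
#' Emits a (TF, miRNA) edge whenever one of the TF's peaks overlaps the
#' miRNA's promoter window by at least one base.  Multiple peaks of one TF
#' in one window collapse to a single record with evidence `"chip"`.
#'
#' Peaks may be supplied as a `GRanges` (e.g. from
#' `rtracklayer::import(..., format = "bed")`, with the TF name in the
#' `name` column) or as a data.frame with columns `chrom`, `start`, `end`
#' (1-based closed) and `tf`.  BED files on disk are 0-based half-open and
#' are converted at import; all internal coordinates are 1-based closed.
#'
#' @param peaks ChIP-Seq peaks (see Details).
#' @param loci miRNA loci data.frame (`mirna`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param cfg a [promoter_config()].
#' @param min_score optional numeric; when given and the peaks carry a
#'   `score` column, peaks below the cutoff are ignored.
#' @return Interaction records (`from` = TF, `to` = miRNA, kind
#'   `"tf_mirna"`, evidence `"chip"`).
#' @export
infer_tf_mirna_from_peaks <- function(peaks, loci, cfg = promoter_config(),
                                      min_score = NULL) {
  if (methods::is(peaks, "GRanges")) {
    nm <- if (!is.null(peaks$name)) peaks$name else peaks$tf
    if (is.null(nm)) abort_validation("peak GRanges must carry TF names ('name' column)")
    pk <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                     start = GenomicRanges::start(peaks),
                     end = GenomicRanges::end(peaks),
                     tf = nm)
    if (!is.null(peaks$score)) pk$score <- peaks$score
  } else {
    stopifnot_cols(peaks, c("chrom", "start", "end", "tf"), "peak table")
    pk <- peaks
  }
  stopifnot_cols(loci, c("mirna", "chrom", "start", "end", "strand"), "miRNA loci")
  if (!is.null(min_score) && !is.null(pk$score)) {
    pk <- pk[pk$score >= min_score, , drop = FALSE]
  }
  if (nrow(pk) && nrow(loci) &&
      !length(intersect(unique(pk$chrom), unique(loci$chrom)))) {
    stripped <- intersect(sub("^chr", "", unique(pk$chrom)),
                          sub("^chr", "", unique(loci$chrom)))
    hint <- if (length(stripped)) {
      " (hint: one input uses 'chr12'-style names and the other '12'-style)"
    } else ""
    abort_validation("no shared chromosome names between peaks and loci", hint)
  }
  win <- promoter_window(loci, cfg)
  win_gr <- loci_to_granges(win)
  pk_gr <- loci_to_granges(pk)
  hits <- GenomicRanges::findOverlaps(pk_gr, win_gr, minoverlap = 1L)
  if (!length(hits)) {
    return(interaction_records(character(), character(), "tf_mirna", character()))
  }
  pairs <- unique(data.frame(
    from = pk$tf[S4Vectors::queryHits(hits)],
    to = win$mirna[S4Vectors::subjectHits(hits)]))
  interaction_records(pairs$from, pairs$to, kind = "tf_mirna", evidence = "chip")
}

#' Normalize miRNA names against an alias table
#'
#' Strips species prefixes (`mmu-`, `hsa-`, ...), normalizes the `miR` /
#' `let` capitalization, and then applies an optional alias table mapping
#' old names to canonical (miRBase-style) names.  Unmapped names pass
#' through unchanged and are flagged.
#'
#' @param name character vector of miRNA names.
#' @param alias optional data.frame with columns `alias`, `canonical`.
#' @param warn emit a warning listing unmapped aliases? (only names that
#'   look like aliases, i.e. appear in neither column, stay silent).
#' @return Character vector of normalized names, with a logical attribute
#'   `"unmapped"` marking names not found in the alias table.
#' @examples
#' normalize_mirna_name("mmu-miR-122-5p")
#' @export
normalize_mirna_name <- function(name, alias = NULL, warn = FALSE) {
  x <- trimws(name)
  x <- sub("^[A-Za-z]{3,4}-(?=(mir|miR|let|Mir|MIR))", "", x, perl = TRUE)
  x <- sub("^(mir|Mir|MIR)", "miR", x)
  x <- sub("^(Let|LET)", "let", x)
  unmapped <- rep(FALSE, length(x))
  if (!is.null(alias)) {
    stopifnot_cols(alias, c("alias", "canonical"), "alias table")
    idx <- match(tolower(x), tolower(alias$alias))
    hit <- !is.na(idx)
    x[hit] <- alias$canonical[idx[hit]]
    unmapped <- !hit & !(x %in% alias$canonical)
    if (warn && any(unmapped)) {
      warning("unmapped miRNA name(s): ",
              paste(unique(name[unmapped]), collapse = ", "))
    }
  }
  attr(x, "unmapped") <- unmapped
  x
}

#' Normalize gene identifiers
#'
#' Gene symbols are matched case-insensitively across resources; the
#' canonical form used internally is upper case.
#'
#' @param gene character vector of gene symbols.
#' @return Upper-cased character vector.
#' @export
normalize_gene_name <- function(gene) {
  toupper(trimws(gene))
}

#' Read ChIP-Seq peaks from a BED file
#'
#' Imports a BED6 file (0-based half-open on disk) into the internal
#' 1-based closed peak table, taking the TF identity from the BED `name`
#' column.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`, `tf` and, when present,
#'   `score`.
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$name)) abort_validation("peak BED file lacks a name (TF) column: ", path)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    tf = gr$name)
  if (!is.null(gr$score)) out$score <- gr$score
  out
}
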