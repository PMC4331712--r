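# Desk-scale small-RNA read preprocessing and miRNA counting:
# adapter trimming, 3' quality trimming, length filtering, and
# Hamming-distance assignment to mature reference sequences.

#' Small-RNA quantification configuration
#'
#' Defaults follow standard Illumina small-RNA practice: the TruSeq 3'
#' adapter, Phred 20 quality cutoff, an inclusive 18-30 nt length window,
#' at most 2 mismatches against the reference, and discarding of reads
#' mapping to more than 20 genomic locations.
#'
#' @param adapter 3' adapter sequence (ACGTN alphabet).
#' @param min_quality Phred cutoff for 3' quality trimming.
#' @param min_len,max_len inclusive read-length window after trimming.
#' @param max_mismatches maximum Hamming distance to a reference.
#' @param max_loci maximum total genomic locus count of a read's matched
#'   references before the read is discarded as multi-mapped.
#' @param min_adapter_overlap minimum adapter prefix length matched at the
#'   read 3' end.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(adapter = "TGGAATTCTCGGGTGCCAAGG",
                         min_quality = 20L, min_len = 18L, max_len = 30L,
                         max_mismatches = 2L, max_loci = 20L,
                         min_adapter_overlap = 7L) {
  if (min_len > max_len) abort_validation("need min_len <= max_len")
  if (max_mismatches < 0) abort_validation("max_mismatches must be >= 0")
  if (!grepl("^[ACGTN]+$", adapter)) {
    abort_validation("adapter must be over the ACGTN alphabet")
  }
  structure(list(adapter = adapter, min_quality = as.integer(min_quality),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 max_mismatches = as.integer(max_mismatches),
                 max_loci = as.integer(max_loci),
                 min_adapter_overlap = as.integer(min_adapter_overlap)),
            class = "quant_config")
}

#' Read and write FASTQ files
#'
#' Thin wrappers around Biostrings' FASTQ support (Phred+33), exchanging a
#' plain data.frame with columns `id`, `seq`, `qual`.
#'
#' @param path FASTQ file path.
#' @return `read_fastq()`: data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' @rdname read_fastq
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot_cols(reads, c("id", "seq", "qual"), "read table")
  if (!nrow(reads)) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual))
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

# Leftmost adapter start position in one sequence, or NA.  A match is a
# prefix of the adapter of length >= min_overlap aligned at position p,
# allowing floor(overlap/10) mismatches ("1 mismatch per 10 adapter
# bases").  Returns the position of the first adapter base.
adapter_match_pos <- function(seq, adapter_int, min_overlap) {
  n <- nchar(seq)
  s <- utf8ToInt(seq)
  la <- length(adapter_int)
  last_p <- n - min_overlap + 1L
  if (last_p < 1L) return(NA_integer_)
  for (p in seq_len(last_p)) {
    o <- min(la, n - p + 1L)
    allowed <- o %/% 10L
    mism <- sum(s[p:(p + o - 1L)] != adapter_int[seq_len(o)])
    if (mism <= allowed) return(p)
  }
  NA_integer_
}

#' Trim the 3' adapter from reads
#'
#' Truncates each read (sequence and quality identically) at the leftmost
#' position where a prefix of the adapter matches: full-adapter internal
#' matches, or a >= `min_adapter_overlap` nt adapter prefix running off
#' the 3' end, tolerating one mismatch per 10 aligned adapter bases.
#' Reads without any adapter match are kept unmodified.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param cfg a [quant_config()].
#' @return The read table with trimmed `seq`/`qual` and a logical column
#'   `adapter_found`.
#' @export
trim_adapter <- function(reads, cfg = quant_config()) {
  stopifnot_cols(reads, c("id", "seq", "qual"), "read table")
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    abort_validation("malformed read record: sequence/quality length mismatch")
  }
  ad_int <- utf8ToInt(cfg$adapter)
  useq <- unique(reads$seq)
  pos <- vapply(useq, adapter_match_pos, integer(1),
                adapter_int = ad_int, min_overlap = cfg$min_adapter_overlap)
  p <- pos[match(reads$seq, useq)]
  found <- !is.na(p)
  keep_len <- ifelse(found, p - 1L, nchar(reads$seq))
  reads$seq <- substr(reads$seq, 1L, keep_len)
  reads$qual <- substr(reads$qual, 1L, keep_len)
  reads$adapter_found <- found
  reads
}

#' Quality-trim reads from the 3' end
#'
#' Removes bases from the 3' end until the terminal base has a Phred score
#' of at least `min_quality` (FASTX-style 3' trimming; no sliding window).
#'
#' @inheritParams trim_adapter
#' @return The read table with trimmed `seq`/`qual`.
#' @export
quality_trim <- function(reads, cfg = quant_config()) {
  stopifnot_cols(reads, c("id", "seq", "qual"), "read table")
  uq <- unique(reads$qual)
  keep <- vapply(uq, function(q) {
    phred <- utf8ToInt(q) - 33L
    ok <- which(phred >= cfg$min_quality)
    if (length(ok)) max(ok) else 0L
  }, integer(1))
  k <- keep[match(reads$qual, uq)]
  reads$seq <- substr(reads$seq, 1L, k)
  reads$qual <- substr(reads$qual, 1L, k)
  reads
}

#' Filter reads by length
#'
#' Keeps reads whose trimmed length lies in the inclusive window
#' `[min_len, max_len]`.
#'
#' @inheritParams trim_adapter
#' @return The retained rows of the read table.
#' @export
length_filter <- function(reads, cfg = quant_config()) {
  len <- nchar(reads$seq)
  reads[len >= cfg$min_len & len <= cfg$max_len, , drop = FALSE]
}

# Best sliding Hamming distance of `read` against one reference (read as a
# substring of the reference, or exact-length comparison).  Inf when the
# read is longer than the reference.
best_hamming <- function(read_int, ref_int) {
  lr <- length(read_int); lf <- length(ref_int)
  if (lr > lf) return(Inf)
  best <- Inf
  for (off in 0:(lf - lr)) {
    d <- sum(read_int != ref_int[(off + 1L):(off + lr)])
    if (d < best) best <- d
    if (best == 0L) break
  }
  best
}

#' Assign reads to mature miRNA sequences and count
#'
#' Each read is compared against every mature reference sequence; a read
#' matches a reference when its best sliding Hamming distance (read as a
#' substring of the reference) is at most `max_mismatches`.  A read whose
#' matched references together are annotated at more than `max_loci`
#' genomic locations is discarded as multi-mapped.  A kept read matching
#' k references at the best distance contributes 1/k to each.
#'
#' @param reads data.frame with column `seq` (post-trimming).
#' @param mature named character vector of mature miRNA sequences
#'   (ACGT/U; U is converted to T).
#' @param loci_per_seq optional named integer vector giving the number of
#'   annotated genomic loci per mature sequence (default 1 each).
#' @param cfg a [quant_config()].
#' @return A list of class `quant_report`: `counts` (named numeric,
#'   fractional), `n_input`, `n_kept`, `n_assigned_reads`,
#'   `discarded` (named integer by reason), `assignments` per unique
#'   sequence.
#' @export
match_and_count <- function(reads, mature, loci_per_seq = NULL,
                            cfg = quant_config()) {
  if (!length(mature)) abort_validation("empty mature reference set")
  if (is.null(names(mature)) || any(!nzchar(names(mature)))) {
    abort_validation("mature references must be named")
  }
  mature <- toupper(chartr("U", "T", mature))
  if (any(!grepl("^[ACGTN]+$", mature))) {
    abort_validation("mature reference sequences must be over ACGTN")
  }
  if (is.null(loci_per_seq)) {
    loci_per_seq <- stats::setNames(rep(1L, length(mature)), names(mature))
  }
  ref_int <- lapply(mature, utf8ToInt)
  useq <- unique(reads$seq)
  counts <- stats::setNames(numeric(length(mature)), names(mature))
  n_multi <- 0L; n_unassigned <- 0L; n_assigned <- 0L
  assign_list <- vector("list", length(useq))
  tab <- table(factor(reads$seq, levels = useq))
  for (i in seq_along(useq)) {
    ri <- utf8ToInt(useq[i])
    d <- vapply(ref_int, best_hamming, numeric(1), read_int = ri)
    best <- min(d)
    n_reads <- as.integer(tab[[i]])
    if (!is.finite(best) || best > cfg$max_mismatches) {
      n_unassigned <- n_unassigned + n_reads
      next
    }
    hits <- names(mature)[d == best]
    total_loci <- sum(loci_per_seq[hits])
    if (total_loci > cfg$max_loci) {
      n_multi <- n_multi + n_reads
      next
    }
    counts[hits] <- counts[hits] + n_reads / length(hits)
    n_assigned <- n_assigned + n_reads
    assign_list[[i]] <- hits
  }
  structure(list(counts = counts,
                 n_input = nrow(reads),
                 n_kept = n_assigned + n_unassigned,
                 n_assigned_reads = n_assigned,
                 discarded = c(multimapped = n_multi),
                 assignments = stats::setNames(assign_list, useq)),
            class = "quant_report")
}

#' Fraction of kept reads assigned to miRNAs
#'
#' @param report a `quant_report` from [match_and_count()] or
#'   [quantify_reads()].
#' @return Assigned-read mass divided by kept-read count, in `[0, 1]`;
#'   `NA` with a warning when no reads were kept.
#' @export
mirna_fraction <- function(report) {
  stopifnot(inherits(report, "quant_report"))
  if (report$n_kept == 0L) {
    warning("no kept reads; miRNA fraction undefined")
    return(NA_real_)
  }
  report$n_assigned_reads / report$n_kept
}

#' Full read-quantification pipeline
#'
#' Runs adapter trimming, 3' quality trimming, length filtering and
#' reference assignment, and tallies every read's fate exactly once
#' (kept-and-assigned, kept-unassigned, or discarded by reason).
#'
#' @param reads data.frame with `id`, `seq`, `qual` (e.g. [read_fastq()]).
#' @param mature named character vector of mature sequences.
#' @param loci_per_seq optional named integer vector (see
#'   [match_and_count()]).
#' @param cfg a [quant_config()].
#' @return A `quant_report` whose `discarded` vector also counts
#'   length-filtered reads; `counts` is the per-miRNA fractional count
#'   vector.
#' @export
quantify_reads <- function(reads, mature, loci_per_seq = NULL,
                           cfg = quant_config()) {
  n_input <- nrow(reads)
  reads <- trim_adapter(reads, cfg)
  reads <- quality_trim(reads, cfg)
  kept <- length_filter(reads, cfg)
  n_length <- n_input - nrow(kept)
  rep <- match_and_count(kept, mature, loci_per_seq, cfg)
  rep$n_input <- n_input
  rep$discarded <- c(length = n_length, rep$discarded)
  rep
}

#' @export
print.quant_report <- function(x, ...) {
  cat("small-RNA quantification report\n")
  cat("  input reads:    ", x$n_input, "\n")
  cat("  kept reads:     ", x$n_kept, "\n")
  cat("  assigned reads: ", x$n_assigned_reads, "\n")
  cat("  discarded:      ",
      paste(sprintf("%s=%d", names(x$discarded), x$discarded), collapse = ", "),
      "\n")
  frac <- if (x$n_kept > 0) x$n_assigned_reads / x$n_kept else NA
  cat("  miRNA fraction: ", round(frac, 4), "\n")
  invisible(x)
}

#' Write a per-miRNA count table
#'
#' @param report a `quant_report`.
#' @param path output TSV path (columns `mirna`, `count`).
#' @export
write_counts_tsv <- function(report, path) {
  write_tsv_file(data.frame(mirna = names(report$counts),
                            count = unname(report$counts)), path)
}
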