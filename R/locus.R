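#' Parse miRNA locus strings
#'
#' Parses locus strings of the form `"chr12:109592846-109592915:+"` into
#' chromosome, 1-based closed interval and strand.  Whitespace around the
#' tokens is tolerated (printed tables often contain `"chr12: 109..."`).
#'
#' @param s character vector of locus strings.
#' @return A data.frame with columns `chrom`, `start`, `end` (integer,
#'   1-based closed) and `strand` (`"+"` or `"-"`).
#' @examples
#' parse_locus_string("chr12:109592846-109592915:+")
#' parse_locus_string("chr4:88910557-88910662:-")
#' @export
parse_locus_string <- function(s) {
  stopifnot(is.character(s))
  pat <- "^\\s*([A-Za-z0-9_.]+)\\s*:\\s*([0-9,]+)\\s*-\\s*([0-9,]+)\\s*:\\s*([+-])\\s*$"
  ok <- grepl(pat, s)
  if (any(!ok)) {
    abort_validation("malformed locus string: '", s[!ok][1L], "'")
  }
  chrom <- sub(pat, "\\1", s)
  start <- as.numeric(gsub(",", "", sub(pat, "\\2", s), fixed = TRUE))
  end <- as.numeric(gsub(",", "", sub(pat, "\\3", s), fixed = TRUE))
  strand <- sub(pat, "\\4", s)
  bad <- start > end
  if (any(bad)) {
    abort_validation("invalid locus (start > end): '", s[bad][1L], "'")
  }
  data.frame(chrom = chrom, start = start, end = end, strand = strand)
}

#' Promoter window configuration
#'
#' The miRNA promoter region is defined as a fixed window around the 5' end
#' of the annotated (precursor) locus: `upstream_bp` upstream and
#' `downstream_bp` downstream, strand-aware.  Defaults follow common
#' curated-TFBS practice for miRNA genes: 5 kb upstream, 1 kb downstream.
#'
#' @param upstream_bp non-negative integer, bases upstream of the 5' end.
#' @param downstream_bp non-negative integer, bases downstream.
#' @return An object of class `promoter_config`.
#' @export
promoter_config <- function(upstream_bp = 5000L, downstream_bp = 1000L) {
  if (upstream_bp < 0 || downstream_bp < 0) {
    abort_validation("promoter window sizes must be >= 0")
  }
  structure(list(upstream_bp = as.integer(upstream_bp),
                 downstream_bp = as.integer(downstream_bp)),
            class = "promoter_config")
}

#' Compute strand-aware promoter windows for miRNA loci
#'
#' For a plus-strand locus the window is
#' `[start - upstream_bp, start + downstream_bp]`; for a minus-strand locus
#' the 5' end is the interval end, so the window is
#' `[end - downstream_bp, end + upstream_bp]`.  Windows are clipped at
#' coordinate 1.  Window width is always `upstream + downstream + 1`
#' (before clipping).
#'
#' @param loci data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (1-based closed coordinates), e.g. from [parse_locus_string()].
#' @param cfg a [promoter_config()].
#' @return A data.frame with `chrom`, `start`, `end` (1-based closed) and
#'   any identifier columns (`mirna`) carried through.
#' @examples
#' loc <- parse_locus_string("chr12:109592846-109592915:+")
#' promoter_window(loc)  # [109587846, 109593846]
#' @export
promoter_window <- function(loci, cfg = promoter_config()) {
  stopifnot_cols(loci, c("chrom", "start", "end", "strand"))
  stopifnot(inherits(cfg, "promoter_config"))
  plus <- loci$strand == "+"
  anchor <- ifelse(plus, loci$start, loci$end)
  win_start <- ifelse(plus, anchor - cfg$upstream_bp, anchor - cfg$downstream_bp)
  win_end <- ifelse(plus, anchor + cfg$downstream_bp, anchor + cfg$upstream_bp)
  out <- data.frame(chrom = loci$chrom,
                    start = pmax(1, win_start),
                    end = pmax(1, win_end))
  if (!is.null(loci$mirna)) out <- cbind(mirna = loci$mirna, out)
  out
}

# Convert a 1-based closed loci data.frame to GRanges.
loci_to_granges <- function(loci) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = if (!is.null(loci$strand)) loci$strand else "*")
  if (!is.null(loci$mirna)) gr$mirna <- loci$mirna
  gr
}
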