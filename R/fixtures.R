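#' Bundled reference tables from a Mir122a knockout mouse liver study
#'
#' Two plain-text tables from a published profiling experiment on
#' \emph{Mir122a^-/-} versus wild-type mouse liver ship with the package:
#' the list of 65 differentially expressed miRNAs called concordantly on
#' both profiling platforms (small RNA-Seq and a qPCR OpenArray panel),
#' and the per-miRNA statistics of curated miRNA-target interactions after
#' inverse-expression filtering.
#'
#' `fixture_demir_table()` returns one row per DEmiR with the printed locus
#' string and per-platform fold changes, plus parsed numeric fold-change and
#' locus columns (fold changes are stored with the exact printed strings,
#' scientific notation included; parsing normalizes them to numerics).
#'
#' `fixture_mti_stats()` returns one row per DEmiR with the number of
#' curated target genes and the number of differentially expressed target
#' genes surviving the inverse-expression filter.
#'
#' Both loaders verify the structural integrity of the fixture (row count
#' 65, 48 up-regulated and 17 down-regulated rows) and fail with an
#' integrity error if the packaged file was altered.
#'
#' @return A data.frame; see Details.
#' @examples
#' t1 <- fixture_demir_table()
#' table(t1$category)
#' t2 <- fixture_mti_stats()
#' sum(t2$n_de_targets)
#' @export
fixture_demir_table <- function() {
  path <- system.file("extdata", "mir122ko_demir_table.tsv", package = "miremap",
                      mustWork = TRUE)
  df <- read_tsv_file(path, colClasses = list(character = c("fc_seq", "fc_array")))
  check_fixture_integrity(df, "DEmiR table")
  df$fc_seq_num <- as.numeric(df$fc_seq)
  df$fc_array_num <- as.numeric(df$fc_array)
  loc <- parse_locus_string(df$locus)
  df$chrom <- loc$chrom
  df$start <- loc$start
  df$end <- loc$end
  df$strand <- loc$strand
  df
}

#' @rdname fixture_demir_table
#' @export
fixture_mti_stats <- function() {
  path <- system.file("extdata", "mir122ko_mti_stats.tsv", package = "miremap",
                      mustWork = TRUE)
  df <- read_tsv_file(path)
  check_fixture_integrity(df, "MTI statistics table")
  df$n_curated <- as.integer(df$n_curated)
  df$n_de_targets <- as.integer(df$n_de_targets)
  df
}

check_fixture_integrity <- function(df, what) {
  n_up <- sum(df$category == "up")
  n_down <- sum(df$category == "down")
  if (nrow(df) != 65L || n_up != 48L || n_down != 17L ||
      anyDuplicated(df$mirna)) {
    stop(errorCondition(
      sprintf("fixture integrity check failed for the %s: expected 65 rows (48 up, 17 down), got %d (%d up, %d down)",
              what, nrow(df), n_up, n_down),
      class = c("miremap_integrity_error", "error")))
  }
  invisible(df)
}
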