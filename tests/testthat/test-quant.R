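# Small-RNA quantification: adapter trimming, quality trimming, length
# filtering, Hamming assignment, conservation.

ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

mk_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  data.frame(id = paste0("r", seq_along(seqs)), seq = seqs, qual = quals)
}

test_that("adapter trimming cuts at the leftmost adapter match", {
  insert <- "ACGTACGTACGTACGTACGTAC"  # 22 nt
  # full adapter plus padding
  full <- paste0(insert, ADAPTER, "CCCCCCC")
  out <- trim_adapter(mk_reads(full))
  expect_equal(out$seq, insert)
  expect_equal(nchar(out$qual), nchar(insert))
  expect_true(out$adapter_found)

  # no adapter anywhere: unchanged
  clean <- strrep("AC", 25)
  out2 <- trim_adapter(mk_reads(clean))
  expect_equal(out2$seq, clean)
  expect_false(out2$adapter_found)

  # only the first 7 adapter bases at the read end
  tail7 <- paste0(insert, substr(ADAPTER, 1, 7))
  out3 <- trim_adapter(mk_reads(tail7))
  expect_equal(out3$seq, insert)
  # 6 bases are below the minimum overlap: kept
  tail6 <- paste0(insert, substr(ADAPTER, 1, 6))
  expect_equal(trim_adapter(mk_reads(tail6))$seq, tail6)
})

test_that("adapter trimming agrees with a brute-force overlap oracle", {
  # oracle: leftmost position p where a >= 7 nt adapter prefix matches
  # with at most floor(overlap/10) mismatches
  oracle_trim <- function(seq, adapter, min_ov = 7L) {
    n <- nchar(seq)
    for (p in seq_len(max(0, n - min_ov + 1L))) {
      o <- min(nchar(adapter), n - p + 1L)
      a <- strsplit(substr(seq, p, p + o - 1L), "")[[1]]
      b <- strsplit(substr(adapter, 1, o), "")[[1]]
      if (sum(a != b) <= o %/% 10L) return(substr(seq, 1, p - 1L))
    }
    seq
  }
  set.seed(5)
  for (i in 1:40) {
    ins_len <- sample(10:30, 1)
    ins <- paste(sample(c("A", "C", "G", "T"), ins_len, TRUE), collapse = "")
    keep <- sample(0:21, 1)
    seq <- substr(paste0(ins, substr(ADAPTER, 1, keep), "GACTGACTGACT"),
                  1, sample(20:50, 1))
    expect_equal(trim_adapter(mk_reads(seq))$seq, oracle_trim(seq, ADAPTER),
                 info = seq)
  }
})

test_that("quality trimming removes the 3' low-quality run", {
  q <- function(phred) intToUtf8(phred + 33, multiple = FALSE)
  r <- mk_reads("ACGTG", q(c(40, 40, 40, 10, 10)))
  expect_equal(quality_trim(r)$seq, "ACG")
  # all high quality: unchanged
  expect_equal(quality_trim(mk_reads("ACGTG"))$seq, "ACGTG")
  # all low quality: empty read (removed later by the length filter)
  r3 <- quality_trim(mk_reads("ACGTG", q(rep(10, 5))))
  expect_equal(nchar(r3$seq), 0L)
})

test_that("length filter keeps the inclusive [18, 30] window", {
  reads <- mk_reads(c(strrep("A", 17), strrep("A", 18), strrep("A", 25),
                      strrep("A", 30), strrep("A", 31)))
  kept <- length_filter(reads)
  expect_equal(nchar(kept$seq), c(18L, 25L, 30L))
})

test_that("match_and_count applies the distance and locus rules", {
  mature <- c(mirX = "ACGTACGTACGTACGTACGTAC",
              mirY = "TTGGCCAATTGGCCAATTGGCC")
  # exact match
  rep1 <- match_and_count(mk_reads(mature[["mirX"]]), mature)
  expect_equal(rep1$counts[["mirX"]], 1)
  # three mismatches: unassigned
  bad <- sub("^ACG", "TTT", mature[["mirX"]])
  rep2 <- match_and_count(mk_reads(bad), mature)
  expect_equal(sum(rep2$counts), 0)
  expect_equal(rep2$n_kept, 1L)
  # reference annotated at 21 genomic loci: read discarded
  rep3 <- match_and_count(mk_reads(mature[["mirX"]]), mature,
                          loci_per_seq = c(mirX = 21L, mirY = 1L))
  expect_equal(sum(rep3$counts), 0)
  expect_equal(rep3$discarded[["multimapped"]], 1L)
  # equidistant references share the read fractionally
  twins <- c(a = "ACGTACGTACGTACGTACGT", b = "ACGTACGTACGTACGTACGA")
  rep4 <- match_and_count(mk_reads("ACGTACGTACGTACGTACGC"), twins,
                          cfg = quant_config(max_mismatches = 2))
  expect_equal(unname(rep4$counts), c(0.5, 0.5))
  expect_error(match_and_count(mk_reads("ACGT"), c(x = "ACXT")), "ACGTN")
})

test_that("match_and_count equals the exhaustive all-pairs oracle", {
  set.seed(9)
  for (rep in 1:5) {
    n_ref <- sample(5:20, 1)
    mature <- stats::setNames(
      vapply(sample(18:26, n_ref, TRUE), function(l)
        paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
        character(1)),
      paste0("mir", seq_len(n_ref)))
    # reads: mostly mutated copies of references, some random
    seqs <- c(
      vapply(sample(mature, 30, TRUE), function(s) {
        k <- sample(0:3, 1)
        if (k > 0) {
          pos <- sample(nchar(s), k)
          ch <- strsplit(s, "")[[1]]
          ch[pos] <- sample(c("A", "C", "G", "T"), k, TRUE)
          s <- paste(ch, collapse = "")
        }
        s
      }, character(1)),
      vapply(rep(20, 10), function(l)
        paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
        character(1)))
    loci <- stats::setNames(sample(c(1L, 1L, 1L, 25L), n_ref, TRUE),
                            names(mature))
    got <- match_and_count(mk_reads(seqs), mature, loci_per_seq = loci)
    want <- oracle_match_counts(seqs, mature, loci)
    expect_equal(got$counts, want$counts)
    expect_equal(got$n_assigned_reads, sum(want$fates == "assigned"))
    expect_equal(got$discarded[["multimapped"]],
                 sum(want$fates == "multimapped"))
  }
})

test_that("every read has exactly one fate (conservation)", {
  set.seed(17)
  mature <- c(m1 = "ACGTACGTACGTACGTACGTAC", m2 = "GGCCTTAAGGCCTTAAGGCC")
  for (i in 1:20) {
    n <- sample(5:40, 1)
    seqs <- vapply(sample(10:45, n, TRUE), function(l)
      paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
      character(1))
    # splice in some real inserts with adapters
    real <- sample(n, min(n, 5))
    seqs[real] <- substr(paste0(sample(mature, length(real), TRUE), ADAPTER,
                                strrep("A", 50)), 1, 50)
    rep <- quantify_reads(mk_reads(seqs), mature)
    expect_equal(rep$n_input, n)
    expect_equal(rep$n_kept + sum(rep$discarded), n)
    expect_lte(sum(rep$counts), rep$n_kept + 1e-9)
  }
})

test_that("mirna_fraction reports assigned mass over kept reads", {
  fake <- structure(list(counts = c(a = 650), n_input = 1200L,
                         n_kept = 1000L, n_assigned_reads = 650L,
                         discarded = c(length = 200L)),
                    class = "quant_report")
  expect_equal(mirna_fraction(fake), 0.65)
  fake$n_assigned_reads <- 0L
  expect_equal(mirna_fraction(fake), 0)
  fake$n_kept <- 0L
  expect_warning(out <- mirna_fraction(fake), "undefined")
  expect_true(is.na(out))
})

test_that("error-free synthetic reads round-trip to exact counts", {
  cfg <- small_world()
  tr <- generate_truth(cfg)
  ann <- generate_mirna_annotation(cfg, tr)
  cnt <- data.frame(mirna = names(ann$mature)[1:20], count = 1:20)
  reads <- generate_reads(cnt, ann$mature, cfg)
  expect_equal(nrow(reads), sum(1:20))
  rep <- quantify_reads(reads, ann$mature)
  expect_equal(unname(rep$counts[cnt$mirna]), as.numeric(cnt$count))
  expect_equal(mirna_fraction(rep), 1.0)
})
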