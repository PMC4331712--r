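# Locus parsing, promoter windows, peak-based inference, source merging,
# name normalization.

test_that("parse_locus_string handles printed formats and rejects bad input", {
  loc <- parse_locus_string("chr12:109592846-109592915:+")
  expect_equal(loc$chrom, "chr12")
  expect_equal(loc$start, 109592846)
  expect_equal(loc$end, 109592915)
  expect_equal(loc$strand, "+")

  # whitespace after the chromosome (as printed in some tables)
  loc2 <- parse_locus_string("chr12: 109571990-109572080:+")
  expect_equal(loc2$start, 109571990)

  expect_equal(parse_locus_string("chr4:88910557-88910662:-")$strand, "-")
  expect_error(parse_locus_string("chr1:10-5:+"), "start > end")
  expect_error(parse_locus_string("chr1:ten-20:+"), "malformed")
})

test_that("promoter_window is strand-aware with the documented arithmetic", {
  plus <- data.frame(chrom = "chr12", start = 109592846, end = 109592915,
                     strand = "+")
  w <- promoter_window(plus)
  expect_equal(c(w$start, w$end), c(109587846, 109593846))

  minus <- data.frame(chrom = "chr4", start = 156053905, end = 156053987,
                      strand = "-")
  w2 <- promoter_window(minus)
  expect_equal(c(w2$start, w2$end), c(156052987, 156058987))

  # zero-width config collapses to the 5' anchor base
  w3 <- promoter_window(plus, promoter_config(0, 0))
  expect_equal(w3$start, w3$end)
  expect_equal(w3$start, 109592846)

  # width invariant over random loci
  set.seed(1)
  for (i in 1:20) {
    up <- sample(0:5000, 1); dn <- sample(0:2000, 1)
    loc <- data.frame(chrom = "chrX", start = sample(1e5:1e6, 1),
                      end = NA, strand = sample(c("+", "-"), 1))
    loc$end <- loc$start + sample(50:100, 1)
    w <- promoter_window(loc, promoter_config(up, dn))
    expect_equal(w$end - w$start + 1, up + dn + 1)
  }
})

test_that("peak-promoter inference matches the per-base oracle", {
  loci <- data.frame(mirna = "m1", chrom = "chr1", start = 7000, end = 7080,
                     strand = "+")
  cfg <- promoter_config()
  # peak covering exactly the window's 5' anchor base
  expect_equal(nrow(infer_tf_mirna_from_peaks(
    data.frame(chrom = "chr1", start = 1, end = 2000, tf = "T"), loci, cfg)), 1L)
  # window is [2000, 8000]; a peak ending 1 bp before it gives no edge
  expect_equal(nrow(infer_tf_mirna_from_peaks(
    data.frame(chrom = "chr1", start = 1500, end = 1999, tf = "T"), loci, cfg)), 0L)
  # two peaks of one TF in one window collapse to one edge
  two <- data.frame(chrom = "chr1", start = c(3000, 4000),
                    end = c(3100, 4100), tf = "T")
  expect_equal(nrow(infer_tf_mirna_from_peaks(two, loci, cfg)), 1L)

  # randomized agreement with an exhaustive per-base scan
  set.seed(42)
  for (rep in 1:5) {
    loci_r <- data.frame(mirna = paste0("m", 1:8),
                         chrom = sample(c("chr1", "chr2"), 8, replace = TRUE),
                         start = sample(5000:900000, 8),
                         strand = sample(c("+", "-"), 8, replace = TRUE))
    loci_r$end <- loci_r$start + sample(60:100, 8, replace = TRUE)
    peaks_r <- data.frame(chrom = sample(c("chr1", "chr2"), 12, replace = TRUE),
                          start = sample(1:900000, 12),
                          tf = sample(paste0("T", 1:3), 12, replace = TRUE))
    peaks_r$end <- peaks_r$start + sample(100:500, 12, replace = TRUE)
    got <- infer_tf_mirna_from_peaks(peaks_r, loci_r)
    expect_equal(sort(paste(got$from, got$to)),
                 oracle_peak_edges(peaks_r, loci_r))
  }
})

test_that("chromosome naming mismatches give a hard error with a hint", {
  loci <- data.frame(mirna = "m1", chrom = "1", start = 7000, end = 7080,
                     strand = "+")
  peaks <- data.frame(chrom = "chr1", start = 1, end = 2000, tf = "T")
  expect_error(infer_tf_mirna_from_peaks(peaks, loci), "chr12")
})

test_that("merge_sources has set semantics", {
  a <- data.frame(from = "T1", to = "miR-1", kind = "tf_mirna",
                  evidence = "transmir")
  b <- data.frame(from = "T1", to = "miR-1", kind = "tf_mirna",
                  evidence = "chipbase")
  m <- merge_sources(a, b)
  expect_equal(nrow(m), 1L)
  expect_equal(m$evidence, "chipbase,transmir")

  # disjoint tables concatenate
  d1 <- data.frame(from = paste0("T", 1:3), to = paste0("m", 1:3),
                   kind = "tf_mirna", evidence = "x")
  d2 <- data.frame(from = paste0("T", 4:7), to = paste0("m", 4:7),
                   kind = "tf_mirna", evidence = "y")
  expect_equal(nrow(merge_sources(d1, d2)), 7L)

  # |A union B| = |A| + |B| - |overlap|
  set.seed(7)
  A <- data.frame(from = paste0("m", 1:30), to = paste0("g", 1:30),
                  kind = "mti", evidence = "a")
  B <- rbind(A[1:10, ], data.frame(from = paste0("m", 31:50),
                                   to = paste0("g", 31:50), kind = "mti",
                                   evidence = "b"))
  expect_equal(nrow(merge_sources(A, B)), 30 + 30 - 10)

  # idempotent and order-independent
  m1 <- merge_sources(a, b); m2 <- merge_sources(b, a)
  expect_equal(m1$evidence, m2$evidence)
  expect_equal(merge_sources(m1, m1)$evidence, m1$evidence)
})

test_that("interaction records reject self-edges and empty evidence", {
  expect_error(interaction_records("x", "x", "mti", "src"), "self-edge")
  expect_error(interaction_records("a", "b", "mti", ""), "evidence")
})

test_that("miRNA name normalization strips species prefixes and maps aliases", {
  expect_equal(as.character(normalize_mirna_name("mmu-miR-122-5p")),
               "miR-122-5p")
  alias <- data.frame(alias = c("miR-122-5p", "mir-122"),
                      canonical = "miR-122-5p")
  out <- normalize_mirna_name(c("mmu-miR-122-5p", "HSA-MIR-122",
                                "miR-999-3p"), alias)
  expect_equal(as.character(out)[1:2], rep("miR-122-5p", 2))
  expect_equal(as.character(out)[3], "miR-999-3p")
  expect_equal(attr(out, "unmapped"), c(FALSE, FALSE, TRUE))
  # idempotence: re-normalizing the output is a no-op
  again <- normalize_mirna_name(as.character(out), alias)
  expect_equal(as.character(again), as.character(out))
})
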