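# Network statistics: hubs, combinatorial regulation, co-targeting,
# chromosomal clustering, DEG coverage.

mk_mti_net <- function(edges_df, demirs, gene_calls) {
  rec <- interaction_records(edges_df$from, edges_df$to, "mti", "src")
  build_mti_network(rec, demirs, gene_calls)
}

test_that("find_hubs reports the full tie-set at maximal degree", {
  demirs <- data.frame(mirna = c("a", "b", "c"), direction = "up")
  genes <- data.frame(id = paste0("g", 1:13), direction = "down")
  edges <- data.frame(
    from = c(rep("a", 3), rep("b", 5), rep("c", 5)),
    to = paste0("g", 1:13))
  net <- mk_mti_net(edges, demirs, genes)
  h <- find_hubs(net, "regulator", "up")
  expect_equal(h$max_degree, 5L)
  expect_equal(h$hubs, c("b", "c"))
  expect_equal(sum(h$degrees$degree), nrow(net$edges))

  # empty subnetwork is flagged, not an error
  h0 <- find_hubs(net, "regulator", "down")
  expect_true(h0$empty)
  expect_equal(h0$max_degree, 0L)
})

test_that("fixture statistics give the published hubs", {
  t2 <- fixture_mti_stats()
  up <- hubs_from_counts(t2, "up")
  expect_equal(up$hubs, "miR-381-3p")
  expect_equal(up$max_degree, 45L)
  down <- hubs_from_counts(t2, "down")
  expect_equal(down$hubs, "miR-17-5p")
  expect_equal(down$max_degree, 115L)
})

test_that("combinatorial regulation reports pairwise shared miRNAs", {
  demirs <- data.frame(mirna = paste0("m", 1:3), direction = "up")
  rec <- interaction_records(c("T1", "T1", "T2", "T2"),
                             c("m1", "m2", "m2", "m3"),
                             "tf_mirna", "transmir")
  net <- build_tf_mirna_network(rec, demirs)
  cr <- combinatorial_regulation(net)
  pair <- cr$pairs[cr$pairs$tf1 == "T1" & cr$pairs$tf2 == "T2", ]
  expect_equal(pair$n_shared, 1L)
  expect_equal(pair$mirnas, "m2")
  expect_equal(cr$per_mirna$tfs[cr$per_mirna$mirna == "m2"], "T1,T2")

  # disjoint TF target sets produce no pair rows
  rec2 <- interaction_records(c("T1", "T2"), c("m1", "m2"), "tf_mirna", "x")
  cr2 <- combinatorial_regulation(build_tf_mirna_network(rec2, demirs))
  expect_equal(nrow(cr2$pairs), 0L)
})

test_that("co-targeting intersects curated targets with the reference set", {
  demirs <- data.frame(mirna = c("m1", "m2"), direction = "down")
  rec <- interaction_records(c("m1", "m1", "m1", "m2"),
                             c("g2", "g3", "g9", "g8"), "mti", "src")
  ct <- co_targeting(rec, c("g1", "g2", "g3"), demirs)
  expect_equal(nrow(ct), 1L)  # m2 shares nothing and is omitted
  expect_equal(ct$n_shared, 2L)
  expect_equal(ct$shared, "g2,g3")
  expect_equal(attr(ct, "union"), c("g2", "g3"))

  # several miRNAs sharing one reference gene are all reported
  mir5 <- c("miR-17-5p", "miR-31", "miR-19a", "miR-93-5p", "miR-144-3p")
  demirs5 <- data.frame(mirna = mir5, direction = "down")
  rec5 <- interaction_records(mir5, "Klf6", "mti", "src")
  ct5 <- co_targeting(rec5, "Klf6", demirs5)
  expect_equal(nrow(ct5), 5L)
  expect_equal(attr(ct5, "union"), "Klf6")

  # reference = all genes reproduces curated target counts
  cfg <- small_world(seed = 31)
  tr <- generate_truth(cfg)
  inter <- generate_interactions(cfg, tr)
  rec_all <- interaction_records(inter$mti$mirna, inter$mti$gene, "mti",
                                 inter$mti$source)
  demirs_all <- tr$mirna[tr$mirna$direction != "none",
                         c("mirna", "direction")]
  ct_all <- co_targeting(rec_all, tr$gene$gene, demirs_all)
  dedup <- rec_all[rec_all$from %in% demirs_all$mirna, ]
  want <- table(dedup$from)
  expect_equal(ct_all$n_shared[match(names(want), ct_all$mirna)],
               unname(as.integer(want)))

  expect_error(co_targeting(rec, character(), demirs),
               class = "miremap_validation_error")
})

test_that("chromosomal clustering reproduces the fixture's chr12 split", {
  t1 <- fixture_demir_table()
  loci <- data.frame(mirna = t1$mirna, direction = t1$category,
                     chrom = t1$chrom, start = t1$start)
  regions <- data.frame(label = "chr12", chrom = "chr12",
                        start = NA, end = NA)
  out <- chromosomal_clustering(loci, regions)
  expect_equal(out$n_up, 41L)
  expect_equal(out$n_down, 1L)

  # empty region list: empty report
  out0 <- chromosomal_clustering(loci, regions[0, ])
  expect_equal(nrow(out0), 0L)

  # absent chromosome: zero counts plus a warning
  expect_warning(
    outx <- chromosomal_clustering(loci, data.frame(label = "x",
                                                    chrom = "chr99",
                                                    start = NA, end = NA)),
    "absent")
  expect_equal(outx$n_total, 0L)

  # bounded region counts by locus start
  reg2 <- data.frame(label = "mid", chrom = "chr12",
                     start = 109700000, end = 109760000)
  out2 <- chromosomal_clustering(loci, reg2)
  expect_equal(out2$n_total,
               sum(t1$chrom == "chr12" & t1$start >= 109700000 &
                     t1$start <= 109760000))
})

test_that("cluster enrichment p matches brute-force enumeration", {
  set.seed(13)
  for (i in 1:5) {
    n <- sample(8:12, 1)
    n_up <- sample(3:(n - 2), 1)
    in_region <- sample(c(TRUE, FALSE), n, replace = TRUE)
    loci <- data.frame(mirna = paste0("m", 1:n),
                       direction = c(rep("up", n_up), rep("down", n - n_up)),
                       chrom = ifelse(in_region, "chr12", "chr1"),
                       start = seq_len(n) * 1000)
    reg <- data.frame(label = "r", chrom = "chr12", start = NA, end = NA)
    out <- chromosomal_clustering(loci, reg, enrich = TRUE)
    want <- oracle_hyper_upper(out$n_up, sum(in_region), n, n_up)
    expect_equal(out$p_up, want, tolerance = 1e-12)
  }
})

test_that("deg_coverage reports the overlap fraction", {
  expect_equal(deg_coverage(c("g1", "g2"), paste0("g", 1:4))$fraction, 0.5)
  expect_equal(deg_coverage(c("x1"), paste0("g", 1:4))$fraction, 0)
  # the published ratio arithmetic: 499 of 886 is 56%
  cov <- deg_coverage(paste0("g", 1:499), paste0("g", 1:886))
  expect_equal(round(100 * cov$fraction), 56)
  expect_error(deg_coverage(c("g1"), character()),
               class = "miremap_validation_error")
})
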