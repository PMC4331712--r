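# Synthetic-data generator: determinism, planted structure, sizing
# errors, read construction, expression model.

test_that("generators are byte-identical under a fixed seed", {
  cfg <- small_world(seed = 4)
  t1 <- generate_truth(cfg); t2 <- generate_truth(cfg)
  expect_identical(t1, t2)

  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  generate_mirna_annotation(cfg, t1, gff3 = f1)
  generate_mirna_annotation(cfg, t2, gff3 = f2)
  expect_identical(readLines(f1), readLines(f2))

  e1 <- generate_expression(cfg, t1); e2 <- generate_expression(cfg, t1)
  expect_identical(e1, e2)
  i1 <- generate_interactions(cfg, t1); i2 <- generate_interactions(cfg, t1)
  expect_identical(i1, i2)
})

test_that("cluster members are placed inside the cluster interval", {
  cfg <- synth_config(n_mirnas = 200, n_genes = 500, n_up_mirnas = 45,
                      n_down_mirnas = 5,
                      cluster_spec = list(chrom = "chr12",
                                          start = 109500000L,
                                          end = 109750000L, n_members = 41L),
                      hub_spec = list(), cotarget_spec = c(0, 0),
                      n_up_genes = 50, n_down_genes = 50, seed = 2)
  ann <- generate_mirna_annotation(cfg)
  cl <- ann$loci[ann$loci$in_cluster, ]
  expect_equal(nrow(cl), 41L)
  expect_true(all(cl$chrom == "chr12"))
  expect_true(all(cl$start >= 109500000 & cl$end <= 109750000))
  expect_true(all(ann$loci$chrom[!ann$loci$in_cluster] != "chr12"))
})

test_that("degenerate and invalid configurations behave as specified", {
  # empty panel: empty annotation, no error
  cfg0 <- synth_config(n_mirnas = 0, n_genes = 10, n_up_genes = 2,
                       n_down_genes = 2)
  ann0 <- generate_mirna_annotation(cfg0)
  expect_equal(nrow(ann0$loci), 0L)

  # cluster interval too small for its members
  cfg_bad <- synth_config(n_mirnas = 100, n_genes = 500,
                          n_up_mirnas = 45, n_down_mirnas = 5,
                          cluster_spec = list(chrom = "chr12",
                                              start = 1000L, end = 2000L,
                                              n_members = 40L),
                          hub_spec = list(), cotarget_spec = c(0, 0),
                          n_up_genes = 50, n_down_genes = 50)
  expect_error(generate_truth(cfg_bad), "too small")

  # invariant violations are rejected up front
  expect_error(synth_config(n_mirnas = 10, n_up_mirnas = 8, n_down_mirnas = 5),
               class = "miremap_validation_error")
  expect_error(synth_config(cross_platform_rho = 1.5),
               class = "miremap_validation_error")
  expect_error(synth_config(n_genes = 100, n_up_genes = 10, n_down_genes = 5,
                            hub_spec = list(c(1, 400))),
               "exceeds n_genes")
})

test_that("planted truth is internally consistent", {
  cfg <- small_world(seed = 12)
  tr <- generate_truth(cfg)
  md <- tr$mirna
  expect_equal(sum(md$direction == "up"), cfg$n_up_mirnas)
  expect_equal(sum(md$direction == "down"), cfg$n_down_mirnas)
  # every planted DE-target of an up miRNA is a down gene and vice versa
  for (m in names(tr$hub_targets)) {
    mdir <- md$direction[md$mirna == m]
    gdir <- tr$gene$direction[match(tr$hub_targets[[m]], tr$gene$gene)]
    expect_true(all(gdir == ifelse(mdir == "up", "down", "up")))
  }
  # cluster membership implies up direction
  expect_true(all(md$direction[md$in_cluster] == "up"))
  # reference set is disjoint from hub target sets
  expect_length(intersect(tr$reference_set, unlist(tr$hub_targets)), 0)
})

test_that("simulated reads have the documented construction", {
  cfg <- small_world()
  mature <- c(mirX = "ACGTACGTACGTACGTACGTAC")  # 22 nt
  reads <- generate_reads(c(mirX = 3), mature, cfg)
  expect_equal(nrow(reads), 3L)
  expect_true(all(substr(reads$seq, 1, 22) == mature[["mirX"]]))
  # bases 23..43 are the 21-nt adapter
  expect_true(all(substr(reads$seq, 23, 43) == cfg$adapter))
  expect_true(all(nchar(reads$seq) == 50L))
  expect_error(generate_reads(c(short = 2), c(short = "ACGTACGTACGTACG"), cfg),
               "16 nt")
})

test_that("noise-free expression recovers planted fold changes", {
  # all fold changes 1, zero noise: recomputed FCs exactly 1
  cfg_flat <- synth_config(n_mirnas = 30, n_genes = 50, n_up_mirnas = 0,
                           n_down_mirnas = 0, noise_sd_log2 = 0,
                           hub_spec = list(), cotarget_spec = c(0, 0),
                           n_up_genes = 5, n_down_genes = 5,
                           seq_depth = 10000, seed = 3)
  tr <- generate_truth(cfg_flat)
  expr <- generate_expression(cfg_flat, tr)
  fca <- normalize_openarray(expr$ct)
  expect_true(all(fca$fc == 1))
  fcs <- seq_fold_changes(expr$counts)
  expect_true(all(abs(log2(fcs$fc)) < 0.01))

  # a planted 4x up miRNA at low noise is called up on both platforms
  cfg4 <- synth_config(n_mirnas = 100, n_genes = 50, n_up_mirnas = 1,
                       n_down_mirnas = 0,
                       cluster_spec = list(chrom = "chr12",
                                           start = 109500000L,
                                           end = 109750000L, n_members = 0L),
                       planted_fc_range = c(4, 4), noise_sd_log2 = 0.1,
                       seq_depth = 1e6, hub_spec = list(),
                       cotarget_spec = c(0, 0), n_up_genes = 5,
                       n_down_genes = 5, seed = 8)
  tr4 <- generate_truth(cfg4)
  expr4 <- generate_expression(cfg4, tr4)
  planted <- tr4$mirna$mirna[tr4$mirna$direction == "up"]
  da <- call_de(normalize_openarray(expr4$ct), platform = "array")
  ds <- call_de(seq_fold_changes(expr4$counts), platform = "seq")
  expect_equal(da$direction[da$id == planted], "up")
  expect_equal(ds$direction[ds$id == planted], "up")
})

test_that("cross-platform correlation calibrates to rho", {
  cfg <- synth_config(n_mirnas = 500, seed = 21)
  tr <- generate_truth(cfg)
  expr <- generate_expression(cfg, tr)
  m <- merge(normalize_openarray(expr$ct), seq_fold_changes(expr$counts),
             by = "mirna", suffixes = c("_a", "_s"))
  r <- cor(log2(m$fc_a), log2(m$fc_s))
  expect_lt(abs(r - 0.7), 0.15)
})

test_that("planted interaction structures are realized exactly", {
  cfg <- small_world(seed = 6)
  tr <- generate_truth(cfg)
  inter <- generate_interactions(cfg, tr)
  mti <- interaction_records(inter$mti$mirna, inter$mti$gene, "mti",
                             inter$mti$source)
  # hub curated sets contain the planted targets
  for (m in names(tr$hub_targets)) {
    expect_true(all(tr$hub_targets[[m]] %in% mti$to[mti$from == m]))
  }
  # empty hub spec: background degrees only
  cfg_nohub <- small_world(seed = 6, hub_spec = list(), cotarget_spec = c(0, 0))
  tr2 <- generate_truth(cfg_nohub)
  inter2 <- generate_interactions(cfg_nohub, tr2)
  mti2 <- interaction_records(inter2$mti$mirna, inter2$mti$gene, "mti",
                              inter2$mti$source)
  deg <- table(mti2$from)
  expect_lte(max(deg), cfg_nohub$background_mti_per_mirna)
})
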