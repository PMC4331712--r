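# Seeded synthetic-data generator: emits every pipeline input (annotation,
# mature sequences, Ct tables, count tables, FASTQ reads, curated
# interaction tables, ChIP-Seq peaks) with planted ground truth for
# recovery tests.

#' Synthetic-data configuration
#'
#' Describes the simulated world: a miRNA panel with planted up/down
#' miRNAs (including a genomic cluster on one chromosome, emulating a
#' co-regulated imprinted cluster), a gene universe with planted DEGs,
#' curated interaction tables with planted hub degrees and a planted
#' co-targeting group around a reference target-gene set, and two
#' expression platforms whose log fold changes share a latent signal with
#' correlation `cross_platform_rho`.
#'
#' Setting `noise_sd_log2 = 0` switches the whole generator to noise-free
#' mode: no Ct noise, no platform-specific log-FC noise (the two
#' platforms coincide, so `cross_platform_rho` is effectively 1), and
#' sequencing counts are rounded expectations instead of multinomial
#' draws.  This is the mode under which the pipeline recovers planted
#' directions and hub degrees exactly.
#'
#' @param n_mirnas panel size (default 750, a rodent qPCR panel).
#' @param n_genes gene universe size.
#' @param n_up_mirnas,n_down_mirnas planted DEmiR counts (defaults 48/17).
#' @param cluster_spec list with `chrom`, `start`, `end`, `n_members`:
#'   the planted genomic cluster of up-regulated miRNAs (default: a
#'   250 kb window on chr12 with 41 members).
#' @param planted_fc_range linear fold-change range for planted DE
#'   miRNAs, sampled log-uniformly.  The default lower bound 2.5 leaves
#'   margin above the 1.5 calling threshold for the attenuation
#'   introduced by two-sample quantile normalization and by
#'   library-composition renormalization in the count data.
#' @param cross_platform_rho target Pearson correlation of the two
#'   platforms' log2 fold changes (must be in (0, 1]; induced by shared
#'   latent signal plus independent platform noise of variance
#'   `var(latent) * (1 - rho) / rho`).
#' @param noise_sd_log2 technical noise sd (log2 scale / Ct units) per
#'   replicate well; 0 = noise-free mode.
#' @param seq_depth total small-RNA-Seq read count per sample.
#' @param hub_spec list of `c(mirna_index, degree)` pairs: planted
#'   DE-target degrees, realized exactly in the inverse-consistent MTI
#'   subsets (defaults: one up hub of degree 45, one down hub of 115).
#' @param cotarget_spec `c(n_reference_genes, n_mirnas)`: size of the
#'   reference miRNA's target set and the number of planted co-targeting
#'   DEmiRs (default 39 genes shared by 9 down-regulated miRNAs).
#' @param n_up_genes,n_down_genes planted DEG counts.
#' @param gene_fc_range linear fold-change range for planted DEGs.
#' @param gene_noise_sd log2 noise on observed gene fold changes.
#' @param n_tfs number of TFs; TF1 is the "cluster TF" whose ChIP peaks
#'   cover every cluster member's promoter, TF2 the planted co-regulator.
#' @param coregulated_overlap number of miRNAs regulated by both TF1 and
#'   TF2 (planted overlap for combinatorial-regulation tests).
#' @param background_tf_edges random curated TF->miRNA rows.
#' @param background_mti_per_mirna random curated target genes per miRNA.
#' @param adapter 3' adapter appended to simulated reads.
#' @param read_length simulated read length (default 50).
#' @param error_rate per-base substitution error rate in reads.
#' @param mature_len_range mature miRNA length range (nt).
#' @param baseline_ct Ct for an abundance of 1 (Ct model:
#'   `Ct = baseline_ct - log2(abundance) + noise`, so ddCt recovers fold
#'   change).
#' @param nb_dispersion optional negative-binomial dispersion for counts
#'   (NULL = multinomial).
#' @param seed integer seed; all generators are deterministic given the
#'   config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_mirnas = 750L, n_genes = 5000L,
                         n_up_mirnas = NULL, n_down_mirnas = NULL,
                         cluster_spec = NULL,
                         planted_fc_range = c(2.5, 10),
                         cross_platform_rho = 0.7,
                         noise_sd_log2 = 0.25,
                         seq_depth = 200000L,
                         hub_spec = NULL,
                         cotarget_spec = NULL,
                         n_up_genes = 362L, n_down_genes = 217L,
                         gene_fc_range = c(2.5, 8),
                         gene_noise_sd = 0.1,
                         n_tfs = 40L,
                         coregulated_overlap = 6L,
                         background_tf_edges = 60L,
                         background_mti_per_mirna = 6L,
                         adapter = "TGGAATTCTCGGGTGCCAAGG",
                         read_length = 50L,
                         error_rate = 0,
                         mature_len_range = c(20L, 23L),
                         baseline_ct = 30,
                         nb_dispersion = NULL,
                         seed = 1L) {
  # adaptive defaults: the stated world (48 up / 17 down DEmiRs, a
  # 41-member cluster, hubs of degree 45 and 115, a 39-gene / 9-miRNA
  # co-targeting group) scales down gracefully for small panels
  if (is.null(n_up_mirnas)) n_up_mirnas <- min(48L, n_mirnas)
  if (is.null(n_down_mirnas)) {
    n_down_mirnas <- min(17L, n_mirnas - n_up_mirnas)
  }
  if (is.null(cluster_spec)) {
    cluster_spec <- list(chrom = "chr12", start = 109500000L,
                         end = 109750000L,
                         n_members = min(41L, n_up_mirnas))
  }
  if (is.null(hub_spec)) {
    hub_spec <- list()
    if (n_up_mirnas >= 1L && n_down_genes >= 45L) {
      hub_spec <- c(hub_spec, list(c(1L, 45L)))
    }
    if (n_down_mirnas >= 1L && n_up_genes >= 115L + 39L) {
      hub_spec <- c(hub_spec, list(c(n_up_mirnas + 1L, 115L)))
    }
  }
  if (is.null(cotarget_spec)) {
    cotarget_spec <- local({
      n_down_hubs <- sum(vapply(hub_spec, function(h)
        h[1] > n_up_mirnas, logical(1)))
      if (n_down_mirnas - n_down_hubs >= 9L) c(39L, 9L) else c(0L, 0L)
    })
  }
  cfg <- structure(as.list(environment()), class = "synth_config")
  if (any(c(n_mirnas, n_genes, n_up_mirnas, n_down_mirnas, n_up_genes,
            n_down_genes, seq_depth) < 0)) {
    abort_validation("all counts must be >= 0")
  }
  if (n_up_mirnas + n_down_mirnas > n_mirnas) {
    abort_validation("n_up_mirnas + n_down_mirnas must be <= n_mirnas")
  }
  if (n_up_genes + n_down_genes > n_genes) {
    abort_validation("n_up_genes + n_down_genes must be <= n_genes")
  }
  if (cluster_spec$n_members > n_up_mirnas) {
    abort_validation("cluster n_members must be <= n_up_mirnas")
  }
  if (abs(cross_platform_rho) > 1) {
    abort_validation("cross_platform_rho must be in [-1, 1]")
  }
  if (cross_platform_rho <= 0) {
    abort_validation("only cross_platform_rho in (0, 1] can be induced by ",
                     "the shared-signal model")
  }
  if (any(planted_fc_range <= 0) || planted_fc_range[1] > planted_fc_range[2]) {
    abort_validation("planted_fc_range must be increasing and positive")
  }
  if (noise_sd_log2 < 0 || error_rate < 0 || error_rate > 1) {
    abort_validation("invalid noise/error parameter")
  }
  for (h in hub_spec) {
    if (length(h) != 2L || h[1] < 1 || h[1] > n_mirnas) {
      abort_validation("hub_spec entries must be c(mirna_index, degree) with ",
                       "a valid index")
    }
    if (h[2] > n_genes) {
      abort_validation("planted hub degree ", h[2], " exceeds n_genes")
    }
  }
  cfg
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate the planted ground truth for a synthetic configuration
#'
#' Deterministically (under `cfg$seed`) builds the complete stated world:
#' miRNA directions and latent fold changes, per-platform log fold
#' changes, genomic loci (cluster members inside the cluster interval,
#' the rest on other chromosomes), unique mature sequences, baseline
#' abundances, the observed gene fold-change table with planted DEG
#' directions, planted hub target sets, the reference target-gene set
#' with its co-targeting miRNA group, and the TF structures.
#'
#' @param cfg a [synth_config()].
#' @return An object of class `synth_truth`: a list with data.frames
#'   `mirna` (name, direction, true_fc, lfc_array, lfc_seq, abundance,
#'   in_cluster, chrom, start, end, strand, mature) and `gene` (gene,
#'   direction, fc), plus `hub_targets` (named list), `reference_set`,
#'   `cotarget_mirnas`, `cotarget_assignment`, `cluster_tf`, `coreg_tf`,
#'   `coregulated_mirnas`, `mir122_target_tfs`, `tfs`.
#' @export
generate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(stage_seed(cfg$seed, 1L), {
    n <- cfg$n_mirnas
    mirna <- if (n > 0) sprintf("miR-s%d", seq_len(n)) else character()
    direction <- rep("none", n)
    up_idx <- seq_len(cfg$n_up_mirnas)
    down_idx <- cfg$n_up_mirnas + seq_len(cfg$n_down_mirnas)
    direction[up_idx] <- "up"
    direction[down_idx] <- "down"
    lfr <- log2(cfg$planted_fc_range)
    lfc <- numeric(n)
    lfc[up_idx] <- runif(cfg$n_up_mirnas, lfr[1], lfr[2])
    lfc[down_idx] <- -runif(cfg$n_down_mirnas, lfr[1], lfr[2])

    # Platform-specific noise from the correlation target.  With shared
    # latent signal t and independent per-platform noise, the observed
    # correlation is rho = var_t / sqrt(prod(var_t + s_p^2)), so each
    # platform needs total noise variance var_t (1 - rho) / rho.  Part of
    # that budget is already spent downstream by known technical layers -
    # Ct replicate noise contributes 2 sigma^2 to the array ddCt log-FC
    # (duplicate wells averaged, U6 subtracted, two samples), and
    # multinomial counting contributes about 2 n / (depth ln(2)^2) to the
    # sequencing log-FC - so the latent platform noise only makes up the
    # difference.
    var_t <- if (n > 1) stats::var(lfc) else 0
    if (cfg$noise_sd_log2 == 0 || var_t == 0) {
      s_a <- s_b <- 0
    } else {
      s2_target <- var_t * (1 - cfg$cross_platform_rho) /
        cfg$cross_platform_rho
      tech_array <- 2 * cfg$noise_sd_log2^2
      tech_seq <- if (cfg$seq_depth > 0) {
        (2 * n / cfg$seq_depth) / log(2)^2
      } else 0
      s_a <- sqrt(max(0, s2_target - tech_array))
      s_b <- sqrt(max(0, s2_target - tech_seq))
    }
    lfc_array <- lfc + rnorm(n, 0, s_a)
    lfc_seq <- lfc + rnorm(n, 0, s_b)

    in_cluster <- rep(FALSE, n)
    if (cfg$cluster_spec$n_members > 0) {
      in_cluster[sample(up_idx, cfg$cluster_spec$n_members)] <- TRUE
    }

    # loci: cluster members in equal slots of the cluster interval, the
    # rest on other chromosomes
    prec_max <- 100L
    chrom <- character(n); start <- integer(n); strand <- character(n)
    cs <- cfg$cluster_spec
    width <- cs$end - cs$start + 1L
    n_cl <- sum(in_cluster)
    if (n_cl > 0 && width < n_cl * (prec_max + 10L)) {
      abort_validation("cluster interval too small for ", n_cl, " members")
    }
    if (n_cl > 0) {
      slot <- floor(width / n_cl)
      offs <- floor(runif(n_cl, 0, slot - prec_max - 1L))
      start[in_cluster] <- cs$start + (seq_len(n_cl) - 1L) * slot + offs
      chrom[in_cluster] <- cs$chrom
      strand[in_cluster] <- "+"
    }
    others <- setdiff(paste0("chr", c(1:11, 13:19, "X")), cs$chrom)
    n_out <- n - n_cl
    if (n_out > 0) {
      chrom[!in_cluster] <- sample(others, n_out, replace = TRUE)
      start[!in_cluster] <- floor(runif(n_out, 1e6, 1.2e8))
      strand[!in_cluster] <- sample(c("+", "-"), n_out, replace = TRUE)
    }
    prec_len <- if (n > 0) floor(runif(n, 60, prec_max)) else integer()

    # unique mature sequences whose simulated reads trim back exactly
    ad_int <- utf8ToInt(cfg$adapter)
    mature <- character(n)
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      repeat {
        len <- sample(seq(cfg$mature_len_range[1], cfg$mature_len_range[2]), 1L)
        sq <- random_dna(len)
        read <- substr(paste0(sq, cfg$adapter, strrep("A", cfg$read_length)),
                       1L, cfg$read_length)
        ok <- !exists(sq, envir = seen) &&
          identical(adapter_match_pos(read, ad_int, 7L), len + 1L)
        if (ok) break
      }
      assign(sq, TRUE, envir = seen)
      mature[i] <- sq
    }

    # Baseline abundances are log-uniform over the panel's dynamic range
    # (128-fold).  Planted DE miRNAs get headroom so their KO abundance
    # also stays inside the range ("detected in both genotypes"): without
    # it, rank-based quantile normalization pins range-edge values and
    # cannot recover their fold change.
    a_lo <- log2(50); a_hi <- log2(6400)
    lab <- runif(n, a_lo, a_hi)
    if (length(up_idx)) lab[up_idx] <- runif(length(up_idx), a_lo,
                                             a_hi - lfc[up_idx])
    if (length(down_idx)) lab[down_idx] <- runif(length(down_idx),
                                                 a_lo - lfc[down_idx], a_hi)
    abundance <- 2^lab

    mirna_df <- data.frame(mirna = mirna, direction = direction,
                           true_fc = 2^lfc, lfc_array = lfc_array,
                           lfc_seq = lfc_seq, abundance = abundance,
                           in_cluster = in_cluster, chrom = chrom,
                           start = start, end = start + prec_len,
                           strand = strand, mature = mature)

    # gene universe with planted DEGs and observed fold changes
    gene <- sprintf("GENE%d", seq_len(cfg$n_genes))
    gdir <- rep("none", cfg$n_genes)
    gup <- seq_len(cfg$n_up_genes)
    gdn <- cfg$n_up_genes + seq_len(cfg$n_down_genes)
    gdir[gup] <- "up"; gdir[gdn] <- "down"
    glfr <- log2(cfg$gene_fc_range)
    glfc <- numeric(cfg$n_genes)
    glfc[gup] <- runif(cfg$n_up_genes, glfr[1], glfr[2])
    glfc[gdn] <- -runif(cfg$n_down_genes, glfr[1], glfr[2])
    gsd <- if (cfg$noise_sd_log2 == 0) 0 else cfg$gene_noise_sd
    gene_df <- data.frame(gene = gene, direction = gdir,
                          fc = 2^(glfc + rnorm(cfg$n_genes, 0, gsd)))

    # planted hub target sets: inverse-consistent DE genes, kept disjoint
    # from the reference set so planted degrees stay exact
    hub_idx <- vapply(cfg$hub_spec, `[`, numeric(1), 1L)
    hub_targets <- list()
    used <- character()
    for (h in cfg$hub_spec) {
      idx <- h[1]; degree <- h[2]
      opp <- if (direction[idx] == "up") "down"
             else if (direction[idx] == "down") "up"
             else abort_validation("hub_spec index ", idx,
                                   " is not a planted DE miRNA")
      pool <- gene[gdir == opp]
      if (length(pool) < degree) {
        abort_validation("hub degree ", degree, " exceeds the ", opp,
                         "-regulated gene pool (", length(pool), ")")
      }
      hub_targets[[mirna[idx]]] <- sample(pool, degree)
    }
    used <- unique(unlist(hub_targets))

    # reference target set (miR-122 analog: de-repressed, hence up in the
    # mutant) and the planted co-targeting group of down-regulated miRNAs
    n_ref <- cfg$cotarget_spec[1]; n_cot <- cfg$cotarget_spec[2]
    ref_pool <- setdiff(gene[gdir == "up"], used)
    if (length(ref_pool) < n_ref) {
      abort_validation("not enough up-regulated genes for the reference set")
    }
    reference_set <- sample(ref_pool, n_ref)
    cot_pool <- setdiff(mirna[down_idx], mirna[hub_idx])
    if (length(cot_pool) < n_cot) {
      abort_validation("cotarget_spec needs ", n_cot,
                       " non-hub down-regulated miRNAs (have ",
                       length(cot_pool), ")")
    }
    cotarget_mirnas <- sort(sample(cot_pool, n_cot))
    cot_assign <- if (n_ref > 0 && n_cot > 0) {
      split(reference_set, rep_len(cotarget_mirnas, n_ref))
    } else list()

    # TF structures
    tfs <- sprintf("TF%d", seq_len(cfg$n_tfs))
    cluster_tf <- if (cfg$n_tfs >= 1) tfs[1] else character()
    coreg_tf <- if (cfg$n_tfs >= 2) tfs[2] else character()
    cluster_mirnas <- mirna[in_cluster]
    coregulated <- if (length(coreg_tf) && length(cluster_mirnas)) {
      sort(sample(cluster_mirnas, min(cfg$coregulated_overlap,
                                      length(cluster_mirnas))))
    } else character()
    mir122_target_tfs <- if (cfg$n_tfs > 0) {
      sort(sample(tfs, min(10L, cfg$n_tfs)))
    } else character()

    structure(list(mirna = mirna_df, gene = gene_df,
                   hub_targets = hub_targets,
                   reference_set = reference_set,
                   cotarget_mirnas = cotarget_mirnas,
                   cotarget_assignment = cot_assign,
                   cluster_tf = cluster_tf, coreg_tf = coreg_tf,
                   coregulated_mirnas = coregulated,
                   mir122_target_tfs = mir122_target_tfs,
                   tfs = tfs, config = cfg),
              class = "synth_truth")
  })
}

#' Generate the miRNA annotation (loci and mature sequences)
#'
#' @param cfg a [synth_config()].
#' @param truth a [generate_truth()] result (regenerated from `cfg` when
#'   omitted).
#' @param gff3,bed,fasta optional output paths; when given, the loci are
#'   written as GFF3 / BED6 and the mature sequences as FASTA.
#' @return A list: `loci` data.frame (`mirna`, `chrom`, `start`, `end`,
#'   `strand`, `in_cluster`) and `mature` (named character vector).
#' @export
generate_mirna_annotation <- function(cfg, truth = generate_truth(cfg),
                                      gff3 = NULL, bed = NULL, fasta = NULL) {
  loci <- truth$mirna[, c("mirna", "chrom", "start", "end", "strand",
                          "in_cluster")]
  mature <- stats::setNames(truth$mirna$mature, truth$mirna$mirna)
  if (!is.null(gff3)) write_annotation_gff3(loci, gff3)
  if (!is.null(bed)) write_annotation_bed(loci, bed)
  if (!is.null(fasta)) write_mature_fasta(mature, fasta)
  list(loci = loci, mature = mature)
}

#' Write miRNA loci as GFF3 or BED6
#'
#' GFF3 records are 1-based closed with type `miRNA_primary_transcript`;
#' BED is written 0-based half-open.
#'
#' @param loci data.frame (`mirna`, `chrom`, `start`, `end`, `strand`).
#' @param path output path.
#' @export
write_annotation_gff3 <- function(loci, path) {
  lines <- c("##gff-version 3",
             if (nrow(loci)) sprintf(
               "%s\tmiremap\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
               loci$chrom, as.integer(loci$start), as.integer(loci$end),
               loci$strand, loci$mirna, loci$mirna))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
write_annotation_bed <- function(loci, path) {
  lines <- if (nrow(loci)) sprintf("%s\t%d\t%d\t%s\t0\t%s",
                                   loci$chrom, as.integer(loci$start) - 1L,
                                   as.integer(loci$end), loci$mirna,
                                   loci$strand) else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA annotation GFF3 into a loci table
#'
#' @param path GFF3 file path.
#' @return data.frame (`mirna`, `chrom`, `start`, `end`, `strand`).
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  nm <- if (!is.null(gr$Name)) gr$Name else gr$ID
  data.frame(mirna = as.character(nm),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Write mature miRNA sequences as FASTA
#'
#' @param mature named character vector of sequences.
#' @param path output path.
#' @export
write_mature_fasta <- function(mature, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(mature), path)
  invisible(path)
}

#' Read mature miRNA sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector (U converted to T).
#' @export
read_mature_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(chartr("Uu", "Tt", as.character(x))), names(x))
}

#' Generate the two-platform expression data
#'
#' Emits an OpenArray-style Ct table (two technical replicate wells per
#' miRNA per sample, a U6 endogenous-control row, Ct =
#' `baseline_ct - log2(abundance) + N(0, noise_sd_log2)`) and a
#' small-RNA-Seq count table (multinomial at `seq_depth`, or rounded
#' expectations in noise-free mode; optional negative-binomial
#' overdispersion via `nb_dispersion`).
#'
#' @param cfg a [synth_config()].
#' @param truth a [generate_truth()] result.
#' @return A list: `ct` data.frame (`mirna`, `well`, `sample`, `ct`) and
#'   `counts` data.frame (`mirna`, `sample`, `count`), samples `"WT"` and
#'   `"KO"`.
#' @export
generate_expression <- function(cfg, truth = generate_truth(cfg)) {
  stopifnot(inherits(truth, "synth_truth"))
  with_seed(stage_seed(cfg$seed, 2L), {
    md <- truth$mirna
    ab_wt <- md$abundance
    ab_ko_array <- ab_wt * 2^md$lfc_array
    ab_ko_seq <- ab_wt * 2^md$lfc_seq
    # Control abundance puts U6 at Ct = baseline - 6, in the quiet high-Ct
    # region: planted DE mass moves at lower Ct, so rank-based quantile
    # normalization leaves the control's value essentially invariant.
    u6_ab <- 2^6

    one_sample <- function(ab, sample, u6) {
      ab_all <- c(ab, u6)
      names_all <- c(md$mirna, "U6")
      do.call(rbind, lapply(1:2, function(w) {
        noise <- if (cfg$noise_sd_log2 == 0) 0 else
          rnorm(length(ab_all), 0, cfg$noise_sd_log2)
        data.frame(mirna = names_all,
                   well = paste0(sample, "_w", w),
                   sample = sample,
                   ct = cfg$baseline_ct - log2(ab_all) + noise)
      }))
    }
    ct <- rbind(one_sample(ab_wt, "WT", u6_ab),
                one_sample(ab_ko_array, "KO", u6_ab))
    rownames(ct) <- NULL

    draw_counts <- function(ab) {
      p <- ab / sum(ab)
      mu <- cfg$seq_depth * p
      if (cfg$noise_sd_log2 == 0) {
        round(mu)
      } else if (!is.null(cfg$nb_dispersion)) {
        rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
      } else {
        as.numeric(rmultinom(1L, cfg$seq_depth, p))
      }
    }
    counts <- rbind(
      data.frame(mirna = md$mirna, sample = "WT", count = draw_counts(ab_wt)),
      data.frame(mirna = md$mirna, sample = "KO", count = draw_counts(ab_ko_seq)))
    list(ct = ct, counts = counts)
  })
}

#' Generate small-RNA-Seq reads for a count vector
#'
#' Each read is the mature sequence followed by the 3' adapter, padded
#' with random bases (or truncated) to `read_length`, with optional
#' uniform per-base substitution errors; qualities are constant Phred 40.
#'
#' @param counts named numeric vector of per-miRNA read counts, or a
#'   data.frame (`mirna`, `count`).
#' @param mature named character vector of mature sequences (>= 16 nt).
#' @param cfg a [synth_config()] (adapter, read length, error rate).
#' @param seed_offset stage offset so different samples get different
#'   reads.
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
generate_reads <- function(counts, mature, cfg, seed_offset = 3L) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$count, counts$mirna)
  }
  counts <- round(counts[counts > 0])
  counts <- counts[counts > 0]
  if (length(counts) && (is.null(names(counts)) ||
                         !all(names(counts) %in% names(mature)))) {
    abort_validation("every counted miRNA needs a mature sequence")
  }
  if (any(nchar(mature[names(counts)]) < 16L)) {
    abort_validation("mature sequences must be at least 16 nt")
  }
  with_seed(stage_seed(cfg$seed, seed_offset), {
    n_total <- sum(counts)
    if (n_total == 0) {
      return(data.frame(id = character(), seq = character(),
                        qual = character()))
    }
    mirna_of <- rep(names(counts), counts)
    base <- substr(paste0(mature[mirna_of], cfg$adapter),
                   1L, cfg$read_length)
    pad_len <- cfg$read_length - nchar(base)
    need <- pad_len > 0
    if (any(need)) {
      pads <- vapply(pad_len[need], random_dna, character(1))
      base[need] <- paste0(base[need], pads)
    }
    if (cfg$error_rate > 0) {
      n_err <- stats::rbinom(n_total, cfg$read_length, cfg$error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample(cfg$read_length, n_err[i])
        s <- strsplit(base[i], "")[[1]]
        s[pos] <- vapply(s[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        base[i] <- paste(s, collapse = "")
      }
    }
    data.frame(id = sprintf("%s_r%d", mirna_of, seq_len(n_total)),
               seq = base,
               qual = strrep("I", cfg$read_length))
  })
}

#' Generate curated interaction tables and ChIP-Seq peaks
#'
#' Emits a TransmiR-like TF->miRNA table, per-TF ChIP-Seq peaks (the
#' cluster TF gets one peak inside every cluster member's promoter
#' window, the co-regulator TF shares a planted overlap of miRNAs with
#' it), and a curated miRNA-target table in which planted hub degrees
#' are realized exactly in the inverse-consistent subsets and the
#' co-targeting group shares the reference gene set.
#'
#' @param cfg a [synth_config()].
#' @param truth a [generate_truth()] result.
#' @param promoter a [promoter_config()] used to place the cluster TF's
#'   peaks.
#' @return A list: `tf_mirna` data.frame (`tf`, `mirna`, `source`),
#'   `peaks` data.frame (`chrom`, `start`, `end`, `tf`), `mti`
#'   data.frame (`mirna`, `gene`, `source`, `evidence`).
#' @export
generate_interactions <- function(cfg, truth = generate_truth(cfg),
                                  promoter = promoter_config()) {
  stopifnot(inherits(truth, "synth_truth"))
  with_seed(stage_seed(cfg$seed, 4L), {
    md <- truth$mirna
    gd <- truth$gene
    sources <- c("mirtarbase", "tarbase", "starbase")

    mti <- list()
    for (m in names(truth$hub_targets)) {
      mti[[length(mti) + 1L]] <- data.frame(
        mirna = m, gene = truth$hub_targets[[m]],
        source = sample(sources, length(truth$hub_targets[[m]]),
                        replace = TRUE))
    }
    for (m in names(truth$cotarget_assignment)) {
      mti[[length(mti) + 1L]] <- data.frame(
        mirna = m, gene = truth$cotarget_assignment[[m]],
        source = sample(sources, length(truth$cotarget_assignment[[m]]),
                        replace = TRUE))
    }
    # background curated targets; hub miRNAs avoid genes that would alter
    # their planted inverse-consistent degree, everyone avoids the
    # reference set so the co-targeting group stays exact
    hub_names <- names(truth$hub_targets)
    safe_pool <- setdiff(gd$gene, truth$reference_set)
    if (cfg$background_mti_per_mirna > 0 && nrow(md) > 0) {
      bg <- lapply(seq_len(nrow(md)), function(i) {
        pool <- safe_pool
        if (md$mirna[i] %in% hub_names) {
          opp <- if (md$direction[i] == "up") "down" else "up"
          pool <- setdiff(pool, gd$gene[gd$direction == opp])
        }
        k <- min(cfg$background_mti_per_mirna, length(pool))
        data.frame(mirna = md$mirna[i], gene = sample(pool, k),
                   source = sample(sources, k, replace = TRUE))
      })
      mti <- c(mti, bg)
    }
    mti <- if (length(mti)) do.call(rbind, mti) else
      data.frame(mirna = character(), gene = character(),
                 source = character())
    # duplicate a slice under a second source to exercise evidence merging
    if (nrow(mti) > 10L) {
      dup <- mti[sample(nrow(mti), ceiling(nrow(mti) * 0.1)), , drop = FALSE]
      dup$source <- vapply(dup$source, function(s)
        sample(setdiff(sources, s), 1L), character(1))
      mti <- rbind(mti, dup)
    }
    mti$evidence <- mti$source
    rownames(mti) <- NULL

    # cluster TF peaks: one peak per cluster member promoter
    cl <- md[md$in_cluster, , drop = FALSE]
    peaks <- NULL
    if (length(truth$cluster_tf) && nrow(cl)) {
      anchor <- ifelse(cl$strand == "+", cl$start, cl$end)
      peaks <- data.frame(chrom = cl$chrom,
                          start = pmax(1, anchor - 100L),
                          end = anchor + 100L,
                          tf = truth$cluster_tf)
    }
    # background peaks for other TFs, away from the planted structures
    bg_tfs <- setdiff(truth$tfs, c(truth$cluster_tf, truth$coreg_tf))
    if (length(bg_tfs)) {
      n_bg <- 2L * length(bg_tfs)
      peaks <- rbind(peaks, data.frame(
        chrom = sample(paste0("chr", c(1:19, "X")), n_bg, replace = TRUE),
        start = st <- floor(runif(n_bg, 1e6, 1.2e8)),
        end = st + 200L,
        tf = rep(bg_tfs, 2L)))
    }
    rownames(peaks) <- NULL

    # TransmiR-like table: the co-regulator TF shares a planted overlap
    # with the cluster TF; background edges avoid both planted TFs
    tf_rows <- list()
    if (length(truth$coreg_tf)) {
      extra <- setdiff(md$mirna[md$direction != "none"], cl$mirna)
      extra <- sample(extra, min(5L, length(extra)))
      tf_rows[[1L]] <- data.frame(tf = truth$coreg_tf,
                                  mirna = c(truth$coregulated_mirnas, extra),
                                  source = "transmir")
    }
    if (cfg$background_tf_edges > 0 && length(bg_tfs) && nrow(md)) {
      tf_rows[[length(tf_rows) + 1L]] <- data.frame(
        tf = sample(bg_tfs, cfg$background_tf_edges, replace = TRUE),
        mirna = sample(md$mirna, cfg$background_tf_edges, replace = TRUE),
        source = "transmir")
    }
    tf_mirna <- unique(do.call(rbind, tf_rows))
    rownames(tf_mirna) <- NULL

    list(tf_mirna = tf_mirna, peaks = peaks, mti = mti)
  })
}
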