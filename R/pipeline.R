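# End-to-end orchestration: synthetic simulation -> quantification ->
# DE calling -> interaction database -> network -> statistics ->
# enrichment, with a machine-readable summary.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and the global seed.  Every
#' random stage derives its own seed from `seed` plus a fixed offset, so
#' a run is deterministic end to end.
#'
#' @param seed global integer seed.
#' @param outdir optional artifact directory; created when given.
#'   Without it, only the in-memory results and summary are produced.
#' @param synthetic a [synth_config()]; its seed is overridden by `seed`.
#' @param de a [de_config()].
#' @param quant a [quant_config()].
#' @param promoter a [promoter_config()].
#' @param alpha raw-p significance threshold for the enrichment stage.
#' @param simulate_reads run the read-level route (FASTQ generation and
#'   quantification) for the sequencing platform?  When `FALSE` the
#'   simulated count table is used directly.
#' @param n_gene_sets,gene_set_size size of the synthetic gene-set
#'   collection used by the enrichment stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = NULL,
                            synthetic = synth_config(seed = seed),
                            de = de_config(), quant = quant_config(),
                            promoter = promoter_config(), alpha = 0.05,
                            simulate_reads = TRUE,
                            n_gene_sets = 20L, gene_set_size = 50L) {
  synthetic$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), outdir = outdir,
                 synthetic = synthetic, de = de, quant = quant,
                 promoter = promoter, alpha = alpha,
                 simulate_reads = simulate_reads,
                 n_gene_sets = as.integer(n_gene_sets),
                 gene_set_size = as.integer(gene_set_size)),
            class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[miremap] %s: %s", stage, paste0(...)))
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> quantify -> DE calling -> cross-platform
#' intersection -> interaction database -> network assembly -> network
#' statistics -> enrichment, returning all intermediate objects plus a
#' JSON-ready summary of the counts at each stage.  Deterministic under
#' `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `miremap_run` with elements `truth`,
#'   `annotation`, `expression`, `interactions`, `quant` (per-sample
#'   reports, when reads were simulated), `demirs`, `gene_calls`,
#'   `records`, `tf_network`, `mti_network`, `target_counts`, `stats`,
#'   `enrichment` and `summary`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$synthetic
  out <- config$outdir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  art <- function(f) if (is.null(out)) NULL else file.path(out, f)

  stage_log("simulate", "generating truth and inputs (seed ", config$seed, ")")
  truth <- generate_truth(cfg)
  ann <- generate_mirna_annotation(cfg, truth, gff3 = art("mirna_loci.gff3"),
                                   bed = art("mirna_loci.bed"),
                                   fasta = art("mature.fa"))
  expr <- generate_expression(cfg, truth)
  inter <- generate_interactions(cfg, truth, config$promoter)
  if (!is.null(out)) {
    write_tsv_file(expr$ct, file.path(out, "openarray_ct.tsv"))
    write_tsv_file(expr$counts, file.path(out, "seq_counts.tsv"))
    write_tsv_file(inter$tf_mirna, file.path(out, "tf_mirna.tsv"))
    write_tsv_file(inter$mti, file.path(out, "mti.tsv"))
    pk <- inter$peaks
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.", pk$chrom,
                       as.integer(pk$start) - 1L, as.integer(pk$end), pk$tf),
               file.path(out, "chip_peaks.bed"))
    write_tsv_file(truth$gene[, c("gene", "fc")],
                   file.path(out, "gene_fc.tsv"))
  }

  # sequencing platform: either the read-level route or the count table
  quant_reports <- NULL
  if (config$simulate_reads) {
    stage_log("quantify", "simulating and quantifying reads for WT and KO")
    offsets <- c(WT = 10L, KO = 11L)
    counts_list <- lapply(names(offsets), function(smp) {
      cnt <- expr$counts[expr$counts$sample == smp, ]
      reads <- generate_reads(cnt, ann$mature, cfg,
                              seed_offset = offsets[[smp]])
      quantify_reads(reads, ann$mature, cfg = config$quant)
    })
    names(counts_list) <- names(offsets)
    quant_reports <- counts_list
    seq_counts <- rbind(
      data.frame(mirna = names(counts_list$WT$counts), sample = "WT",
                 count = unname(counts_list$WT$counts)),
      data.frame(mirna = names(counts_list$KO$counts), sample = "KO",
                 count = unname(counts_list$KO$counts)))
  } else {
    seq_counts <- expr$counts
  }

  stage_log("decall", "per-platform fold changes and DE calls")
  fc_array <- normalize_openarray(expr$ct, config$de)
  fc_seq <- seq_fold_changes(seq_counts)
  calls_array <- call_de(fc_array, config$de, platform = "array")
  calls_seq <- call_de(fc_seq, config$de, platform = "seq")
  demirs <- intersect_platforms(calls_seq, calls_array)
  gene_calls <- call_de_genes(truth$gene[, c("gene", "fc")], config$de)

  stage_log("build-db", "curated interactions and ChIP-derived edges")
  chip_rec <- infer_tf_mirna_from_peaks(inter$peaks, ann$loci, config$promoter)
  transmir_rec <- interaction_records(inter$tf_mirna$tf, inter$tf_mirna$mirna,
                                      kind = "tf_mirna",
                                      evidence = inter$tf_mirna$source)
  mti_rec <- interaction_records(inter$mti$mirna, inter$mti$gene,
                                 kind = "mti", evidence = inter$mti$source)
  records <- merge_sources(chip_rec, transmir_rec, mti_rec)

  stage_log("network", "active-node projection and inverse filter")
  tf_net <- build_tf_mirna_network(records, demirs,
                                   mir122_targets = truth$mir122_target_tfs)
  mti_net <- build_mti_network(records, demirs, gene_calls)
  target_counts <- per_mirna_target_counts(records, mti_net, demirs)
  if (!is.null(out)) {
    export_network(mti_net, file.path(out, "mti_network.graphml"),
                   file.path(out, "mti_network_edges.tsv"))
    export_network(tf_net, file.path(out, "tf_network.graphml"),
                   file.path(out, "tf_network_edges.tsv"))
    write_tsv_file(target_counts, file.path(out, "target_counts.tsv"))
  }

  stage_log("stats", "hubs, co-regulation, co-targeting, clustering")
  hubs_up <- find_hubs(mti_net, "regulator", "up", kind = "mti")
  hubs_down <- find_hubs(mti_net, "regulator", "down", kind = "mti")
  coreg <- combinatorial_regulation(tf_net)
  cotarg <- if (length(truth$reference_set)) {
    co_targeting(records, truth$reference_set, demirs)
  } else {
    structure(data.frame(mirna = character(), direction = character(),
                         n_shared = integer(), shared = character()),
              union = character())
  }
  demir_loci <- merge(demirs, ann$loci, by = "mirna")
  regions <- data.frame(label = cfg$cluster_spec$chrom,
                        chrom = cfg$cluster_spec$chrom,
                        start = NA_real_, end = NA_real_)
  clust <- chromosomal_clustering(demir_loci, regions, enrich = TRUE)
  planted_degs <- truth$gene$gene[truth$gene$direction != "none"]
  coverage <- deg_coverage(mti_net, planted_degs)

  stage_log("enrich", "Fisher over-representation on a synthetic collection")
  universe <- truth$gene$gene
  targeted <- unique(mti_net$edges$to)
  collection <- with_seed(stage_seed(config$seed, 20L), {
    sets <- lapply(seq_len(config$n_gene_sets), function(i)
      sample(universe, min(config$gene_set_size, length(universe))))
    names(sets) <- sprintf("random_set_%02d", seq_along(sets))
    if (length(targeted)) {
      sets$network_targets <- sample(targeted,
                                     min(config$gene_set_size,
                                         length(targeted)))
    }
    sets
  })
  enr <- run_collection(targeted, collection, universe, config$alpha)

  summary <- list(
    seed = config$seed,
    n_mirnas = cfg$n_mirnas,
    n_genes = cfg$n_genes,
    quant = if (!is.null(quant_reports)) lapply(quant_reports, function(r)
      list(n_input = r$n_input, n_kept = r$n_kept,
           mirna_fraction = round(mirna_fraction(r), 4))) else NULL,
    n_demirs = nrow(demirs),
    n_demirs_up = sum(demirs$direction == "up"),
    n_demirs_down = sum(demirs$direction == "down"),
    n_conflicts = length(attr(demirs, "conflicts")),
    n_degs = sum(gene_calls$direction != "none"),
    tf_network = list(n_edges = nrow(tf_net$edges),
                      n_tfs = sum(tf_net$nodes$type == "TF"),
                      n_mirnas = sum(tf_net$nodes$type == "miRNA")),
    mti_network = list(n_edges = nrow(mti_net$edges),
                       n_mirnas = sum(mti_net$nodes$type == "miRNA"),
                       n_genes = sum(mti_net$nodes$type == "gene")),
    hub_up = list(max_degree = hubs_up$max_degree, mirnas = hubs_up$hubs),
    hub_down = list(max_degree = hubs_down$max_degree,
                    mirnas = hubs_down$hubs),
    cotargeting = list(n_mirnas = nrow(cotarg),
                       union_size = length(attr(cotarg, "union"))),
    cluster_region = list(label = clust$label[1], n_up = clust$n_up[1],
                          n_down = clust$n_down[1]),
    deg_coverage = list(n_targeted = coverage$n_targeted,
                        n_reference = coverage$n_reference,
                        fraction = round(coverage$fraction, 4)),
    top_enrichment = list(set = enr$set[1], p = enr$p[1],
                          significant = enr$significant[1])
  )
  if (!is.null(out)) {
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(truth = truth, annotation = ann, expression = expr,
                 interactions = inter, quant = quant_reports,
                 demirs = demirs, gene_calls = gene_calls,
                 records = records, tf_network = tf_net,
                 mti_network = mti_net, target_counts = target_counts,
                 stats = list(hubs_up = hubs_up, hubs_down = hubs_down,
                              coregulation = coreg, cotargeting = cotarg,
                              clustering = clust, coverage = coverage),
                 enrichment = enr, summary = summary),
            class = "miremap_run")
}

#' Render a pipeline summary as a human-readable report
#'
#' @param summary the `summary` element of a [run_pipeline()] result, or
#'   a path to a summary JSON file.
#' @return Character vector of markdown lines (also printed when
#'   `quiet = FALSE`).
#' @param quiet suppress printing?
#' @export
render_report <- function(summary, quiet = FALSE) {
  if (is.character(summary) && length(summary) == 1L) {
    summary <- jsonlite::read_json(summary, simplifyVector = TRUE)
  }
  need <- c("n_demirs", "n_demirs_up", "n_demirs_down", "mti_network",
            "tf_network", "hub_up", "hub_down", "cluster_region")
  missing <- setdiff(need, names(summary))
  if (length(missing)) {
    abort_validation("summary is missing field(s): ",
                     paste(missing, collapse = ", "))
  }
  fmt_hub <- function(h) {
    if (!length(h$mirnas) || h$max_degree == 0) "none (empty subnetwork)"
    else paste0(paste(h$mirnas, collapse = ", "), " (", h$max_degree,
                " target genes)")
  }
  lines <- c(
    "# miRNA regulatory network report",
    "",
    sprintf("- high-confidence DEmiRs: %d (%d up, %d down)",
            summary$n_demirs, summary$n_demirs_up, summary$n_demirs_down),
    sprintf("- TF-miRNA network: %d edges, %d TFs, %d miRNAs",
            summary$tf_network$n_edges, summary$tf_network$n_tfs,
            summary$tf_network$n_mirnas),
    if (summary$mti_network$n_edges == 0) {
      "- miRNA-target network: empty (no inverse-consistent interactions)"
    } else {
      sprintf("- miRNA-target network: %d edges, %d miRNAs, %d genes",
              summary$mti_network$n_edges, summary$mti_network$n_mirnas,
              summary$mti_network$n_genes)
    },
    sprintf("- up-side regulator hub: %s", fmt_hub(summary$hub_up)),
    sprintf("- down-side regulator hub: %s", fmt_hub(summary$hub_down)),
    sprintf("- cluster region %s: %d up / %d down DEmiRs",
            summary$cluster_region$label, summary$cluster_region$n_up,
            summary$cluster_region$n_down))
  if (!is.null(summary$cotargeting)) {
    lines <- c(lines, sprintf(
      "- co-targeting of the reference set: %d miRNAs sharing %d genes",
      summary$cotargeting$n_mirnas, summary$cotargeting$union_size))
  }
  if (!is.null(summary$deg_coverage)) {
    lines <- c(lines, sprintf(
      "- DEG coverage: %d/%d (%.1f%%)", summary$deg_coverage$n_targeted,
      summary$deg_coverage$n_reference,
      100 * summary$deg_coverage$fraction))
  }
  if (!is.null(summary$top_enrichment)) {
    lines <- c(lines, sprintf(
      "- top enrichment: %s (p = %.3g)", summary$top_enrichment$set,
      summary$top_enrichment$p))
  }
  if (!quiet) cat(lines, sep = "\n")
  invisible(lines)
}

#' Parse counts back out of a rendered report
#'
#' Self-consistency helper: extracts the DE and network counts from the
#' text produced by [render_report()].
#'
#' @param lines character vector of report lines.
#' @return A list with `n_demirs`, `n_demirs_up`, `n_demirs_down`,
#'   `n_mti_edges`.
#' @export
parse_report <- function(lines) {
  de <- regmatches(lines, regexec(
    "DEmiRs: (\\d+) \\((\\d+) up, (\\d+) down\\)", lines))
  de <- de[lengths(de) == 4][[1]]
  mti_line <- grep("miRNA-target network", lines, value = TRUE)
  n_mti <- if (grepl("empty", mti_line)) 0L else
    as.integer(sub(".*network: (\\d+) edges.*", "\\1", mti_line))
  list(n_demirs = as.integer(de[2]), n_demirs_up = as.integer(de[3]),
       n_demirs_down = as.integer(de[4]), n_mti_edges = n_mti)
}
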