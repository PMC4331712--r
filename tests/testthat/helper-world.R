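# Shared fixtures for the test suite: a small, well-proportioned synthetic
# world (DE fraction and planted structures scaled together so
# library-composition and quantile-normalization effects stay benign),
# plus independent brute-force oracles.

small_world <- function(seed = 101L, noise_free = TRUE,
                        hub_spec = list(c(1L, 8L), c(11L, 12L)),
                        cotarget_spec = c(6L, 3L), ...) {
  synth_config(n_mirnas = 150L, n_genes = 600L,
               n_up_mirnas = 10L, n_down_mirnas = 6L,
               cluster_spec = list(chrom = "chr12", start = 109500000L,
                                   end = 109750000L, n_members = 5L),
               hub_spec = hub_spec, cotarget_spec = cotarget_spec,
               n_up_genes = 80L, n_down_genes = 50L,
               seq_depth = 20000L,
               noise_sd_log2 = if (noise_free) 0 else 0.25,
               seed = seed, ...)
}

# Independent oracle: exhaustive all-pairs sliding Hamming scan with
# fractional assignment, written without reusing the package internals.
oracle_match_counts <- function(seqs, mature, loci_per_seq = NULL,
                                max_mismatches = 2L, max_loci = 20L) {
  if (is.null(loci_per_seq)) {
    loci_per_seq <- stats::setNames(rep(1L, length(mature)), names(mature))
  }
  counts <- stats::setNames(numeric(length(mature)), names(mature))
  fates <- character(length(seqs))
  for (i in seq_along(seqs)) {
    rd <- strsplit(seqs[[i]], "")[[1]]
    dists <- sapply(names(mature), function(nm) {
      rf <- strsplit(mature[[nm]], "")[[1]]
      if (length(rd) > length(rf)) return(Inf)
      min(sapply(0:(length(rf) - length(rd)), function(off) {
        sum(rd != rf[(off + 1):(off + length(rd))])
      }))
    })
    best <- min(dists)
    if (!is.finite(best) || best > max_mismatches) {
      fates[i] <- "unassigned"
      next
    }
    hits <- names(mature)[dists == best]
    if (sum(loci_per_seq[hits]) > max_loci) {
      fates[i] <- "multimapped"
      next
    }
    counts[hits] <- counts[hits] + 1 / length(hits)
    fates[i] <- "assigned"
  }
  list(counts = counts, fates = fates)
}

# Independent oracle: per-base promoter-overlap scan on small coordinates.
oracle_peak_edges <- function(peaks, loci, upstream = 5000L,
                              downstream = 1000L) {
  edges <- character()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(loci))) {
      if (peaks$chrom[i] != loci$chrom[j]) next
      anchor <- if (loci$strand[j] == "+") loci$start[j] else loci$end[j]
      win <- if (loci$strand[j] == "+") {
        max(1, anchor - upstream):(anchor + downstream)
      } else {
        max(1, anchor - downstream):(anchor + upstream)
      }
      if (any(peaks$start[i]:peaks$end[i] %in% win)) {
        edges <- c(edges, paste(peaks$tf[i], loci$mirna[j]))
      }
    }
  }
  sort(unique(edges))
}

# Independent oracle: hypergeometric upper tail by explicit enumeration
# of all draws (tiny universes only).
oracle_hyper_upper <- function(k, set_size, universe_size, query_size) {
  draws <- utils::combn(universe_size, query_size)
  in_set <- seq_len(set_size)  # wlog the first set_size elements
  mean(apply(draws, 2, function(d) sum(d %in% in_set) >= k))
}
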