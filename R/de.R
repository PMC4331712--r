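# Fold-change differential-expression calling for miRNAs (two platforms)
# and genes, plus the cross-platform intersection.

#' Differential-expression configuration
#'
#' Fold-change-only DE calling: up if fold change >= `up_threshold`
#' (default 1.5), down if <= `down_threshold` (default 0.66), both
#' inclusive.  Ct-based filtering for the qPCR platform removes miRNAs
#' undetermined or outside `[ct_min, ct_max]` in every sample.
#'
#' @param up_threshold linear fold change at or above which a molecule is
#'   called up-regulated.
#' @param down_threshold linear fold change at or below which a molecule is
#'   called down-regulated; must satisfy `down_threshold < 1 < up_threshold`.
#' @param ct_min,ct_max Ct detection range for the qPCR platform.
#' @param control_id identifier of the endogenous control row (default
#'   `"U6"`).
#' @return An object of class `de_config`.
#' @export
de_config <- function(up_threshold = 1.5, down_threshold = 0.66,
                      ct_min = 15, ct_max = 35, control_id = "U6") {
  if (!(down_threshold < 1 && 1 < up_threshold)) {
    abort_validation("need down_threshold < 1 < up_threshold")
  }
  if (!(ct_min < ct_max)) abort_validation("need ct_min < ct_max")
  structure(list(up_threshold = up_threshold, down_threshold = down_threshold,
                 ct_min = ct_min, ct_max = ct_max, control_id = control_id),
            class = "de_config")
}

#' Normalize an OpenArray-style Ct table to per-miRNA fold changes
#'
#' Processing follows standard qPCR panel practice: miRNAs undetermined or
#' with Ct outside the detection range in every sample are removed,
#' technical duplicate wells are averaged, the two sample columns are
#' quantile-normalized (for two samples this is rank-wise mean
#' substitution), and fold changes are computed as `2^(-ddCt)` with dCt
#' taken against the endogenous control row (default U6).
#'
#' @param ct data.frame with columns `mirna`, `well`, `sample`, `ct`.  The
#'   `ct` column may contain the token `"Undetermined"` (treated as NA).
#' @param cfg a [de_config()].
#' @param wt,ko sample labels of the reference (wild-type) and test
#'   (knockout) sample; fold change is KO over WT.
#' @param quantile apply quantile normalization across samples?
#' @return data.frame with columns `mirna`, `fc` (linear fold change, KO
#'   vs WT); the control row is excluded.
#' @examples
#' ct <- data.frame(mirna = c("m1", "m1", "U6", "U6"),
#'                  well = c(1, 2, 3, 4),
#'                  sample = c("WT", "KO", "WT", "KO"),
#'                  ct = c(25, 24, 20, 20))
#' normalize_openarray(ct, quantile = FALSE)  # fc = 2
#' @export
normalize_openarray <- function(ct, cfg = de_config(), wt = "WT", ko = "KO",
                                quantile = TRUE) {
  stopifnot_cols(ct, c("mirna", "well", "sample", "ct"), "Ct table")
  samples <- unique(ct$sample)
  if (!all(c(wt, ko) %in% samples)) {
    abort_validation("Ct table must contain both samples '", wt, "' and '", ko, "'")
  }
  vals <- suppressWarnings(as.numeric(ifelse(
    tolower(trimws(as.character(ct$ct))) == "undetermined", NA, ct$ct)))
  ct$ct_num <- vals
  if (!any(ct$mirna == cfg$control_id)) {
    abort_validation("Ct table lacks the endogenous control row '",
                     cfg$control_id, "'")
  }
  # a value is "detected" when determined and within the Ct range
  detected <- !is.na(vals) & vals >= cfg$ct_min & vals <= cfg$ct_max
  keep_mirna <- tapply(detected, ct$mirna, any)
  ct <- ct[keep_mirna[ct$mirna], , drop = FALSE]
  # average technical duplicates per (mirna, sample)
  agg <- stats::aggregate(ct_num ~ mirna + sample, data = ct,
                          FUN = mean, na.rm = TRUE, na.action = NULL)
  m <- tapply(agg$ct_num, list(agg$mirna, agg$sample), mean)
  m <- m[, c(wt, ko), drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (!(cfg$control_id %in% rownames(m))) {
    abort_validation("control '", cfg$control_id,
                     "' was removed by the Ct filters; cannot normalize")
  }
  if (quantile && nrow(m) > 1L) m <- quantile_normalize(m)
  dct <- m - rep(m[cfg$control_id, ], each = nrow(m))
  ddct <- dct[, 2L] - dct[, 1L]
  fc <- 2^(-ddct)
  out <- data.frame(mirna = rownames(m), fc = unname(fc))
  out[out$mirna != cfg$control_id, , drop = FALSE]
}

# Rank-wise mean substitution (quantile normalization).  Average-tie ranks
# are interpolated between the two neighbouring sorted means.
quantile_normalize <- function(m) {
  mu <- rowMeans(apply(m, 2L, sort))
  out <- apply(m, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (mu[lo] + mu[hi]) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Fold changes from a small RNA-Seq count table
#'
#' Normalizes by library proportion: the fold change of a miRNA is the
#' ratio of its library proportions in the test and reference samples,
#' with a pseudocount of 0.5 added to each raw count (library sizes are
#' sums of raw counts).
#'
#' @param counts data.frame with columns `mirna`, `sample`, `count`.
#' @param wt,ko sample labels; fold change is KO over WT.
#' @param pseudocount added to each numerator count (default 0.5).
#' @return data.frame with columns `mirna`, `fc`.
#' @export
seq_fold_changes <- function(counts, wt = "WT", ko = "KO", pseudocount = 0.5) {
  stopifnot_cols(counts, c("mirna", "sample", "count"), "count table")
  cw <- counts[counts$sample == wt, , drop = FALSE]
  ck <- counts[counts$sample == ko, , drop = FALSE]
  if (!nrow(cw) || !nrow(ck)) {
    abort_validation("count table must contain both samples '", wt, "' and '", ko, "'")
  }
  lib_w <- sum(cw$count); lib_k <- sum(ck$count)
  if (lib_w <= 0 || lib_k <= 0) abort_validation("zero library size")
  mirnas <- union(cw$mirna, ck$mirna)
  n_w <- cw$count[match(mirnas, cw$mirna)]; n_w[is.na(n_w)] <- 0
  n_k <- ck$count[match(mirnas, ck$mirna)]; n_k[is.na(n_k)] <- 0
  fc <- ((n_k + pseudocount) / lib_k) / ((n_w + pseudocount) / lib_w)
  data.frame(mirna = mirnas, fc = fc)
}

#' Call differential expression from fold changes
#'
#' Applies the inclusive fold-change thresholds: `fc >= up_threshold` is
#' `"up"`, `fc <= down_threshold` is `"down"`, everything else `"none"`.
#'
#' @param fc_table data.frame whose first column is the molecule id and
#'   which has a numeric `fc` column (linear scale, test over reference).
#' @param cfg a [de_config()].
#' @param platform tag recorded in the output (e.g. `"seq"`, `"array"`).
#' @return data.frame with columns `id`, `fc`, `direction`, `platform`.
#' @examples
#' call_de(data.frame(mirna = c("a", "b", "c"), fc = c(1.5, 0.66, 1.0)))
#' @export
call_de <- function(fc_table, cfg = de_config(), platform = "unspecified") {
  stopifnot_cols(fc_table, "fc", "fold-change table")
  id <- fc_table[[1L]]
  fc <- fc_table$fc
  if (any(!is.finite(fc)) || any(fc <= 0)) {
    abort_validation("fold changes must be finite and positive")
  }
  direction <- ifelse(fc >= cfg$up_threshold, "up",
                      ifelse(fc <= cfg$down_threshold, "down", "none"))
  data.frame(id = id, fc = fc, direction = direction, platform = platform)
}

#' @rdname call_de
#' @param gene_fc_table data.frame with gene ids in the first column and a
#'   numeric `fc` column.
#' @export
call_de_genes <- function(gene_fc_table, cfg = de_config()) {
  call_de(gene_fc_table, cfg, platform = "gene")
}

#' Intersect DE calls from two miRNA platforms
#'
#' A miRNA is a high-confidence DEmiR when it is called differentially
#' expressed (direction not `"none"`) on both platforms with the same
#' direction.  miRNAs DE on one platform only are dropped; miRNAs with
#' conflicting directions are dropped and recorded in the `"conflicts"`
#' attribute.
#'
#' @param calls_a,calls_b DE call tables from [call_de()].
#' @return data.frame with columns `mirna`, `direction`, `fc_a`, `fc_b`
#'   (platform order as given), with attribute `"conflicts"` listing
#'   direction-discordant miRNAs.
#' @export
intersect_platforms <- function(calls_a, calls_b) {
  stopifnot_cols(calls_a, c("id", "fc", "direction"), "platform A calls")
  stopifnot_cols(calls_b, c("id", "fc", "direction"), "platform B calls")
  m <- merge(calls_a, calls_b, by = "id", suffixes = c("_a", "_b"))
  both_de <- m$direction_a != "none" & m$direction_b != "none"
  agree <- both_de & m$direction_a == m$direction_b
  conflict <- both_de & !agree
  out <- data.frame(mirna = m$id[agree],
                    direction = m$direction_a[agree],
                    fc_a = m$fc_a[agree],
                    fc_b = m$fc_b[agree])
  out <- out[order(out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conflicts") <- m$id[conflict]
  if (any(conflict)) {
    message("dropped ", sum(conflict),
            " miRNA(s) with conflicting cross-platform directions: ",
            paste(m$id[conflict], collapse = ", "))
  }
  out
}
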