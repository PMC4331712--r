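# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded generators do not perturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-specific seed from a global seed.  Kept below 2^31 - 1.
stage_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483629L
}

# Validation error helper: condition class "miremap_validation_error" so the
# CLI can map it to exit code 2.
abort_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("miremap_validation_error", "error")))
}

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  if (!is.data.frame(df)) {
    abort_validation(what, " must be a data.frame")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_validation(what, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Read/write TSV with consistent settings.
read_tsv_file <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  data.table = FALSE, ...))
}

write_tsv_file <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# Comma-joined sorted evidence sets (set semantics over a character scalar).
evidence_join <- function(x) {
  paste(sort(unique(x[nzchar(x)])), collapse = ",")
}

evidence_split <- function(x) {
  strsplit(x, ",", fixed = TRUE)
}

evidence_union <- function(a, b) {
  mapply(function(x, y) evidence_join(c(x, y)),
         evidence_split(a), evidence_split(b))
}
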