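#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

GENOTYPES <- c("AA", "AB", "BB")
NO_CALL <- "NC"
ID_COLS <- c("Sample_ID", "Case_Control")

#' SNP columns of a sample-by-SNP dataset
#'
#' Returns the names of the genotype (or encoded-genotype) columns of a
#' dataset in sample-per-row layout, i.e. every column except `Sample_ID`
#' and `Case_Control`.
#'
#' @param data A tibble with one row per sample.
#' @return Character vector of SNP column names.
#' @export
snp_cols <- function(data) {
  setdiff(names(data), ID_COLS)
}

#' Case/Control labels as 0/1
#'
#' Fixed positive-class convention: Case = 1, Control = 0, everywhere in the
#' package (so sensitivity is always the recall of the Case class).
#'
#' @param data A labeled dataset (has a `Case_Control` column).
#' @return Integer vector of 0/1.
#' @export
case_indicator <- function(data) {
  check_labeled(data)
  as.integer(data$Case_Control == "Case")
}

check_labeled <- function(data, call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with one row per sample.", call = call)
  }
  if (!"Case_Control" %in% names(data)) {
    abort("`data` must be labeled: no `Case_Control` column found.",
      call = call
    )
  }
  bad <- setdiff(unique(data$Case_Control), c("Case", "Control"))
  if (length(bad) > 0) {
    abort(sprintf(
      "`Case_Control` contains values other than Case/Control: %s",
      paste(bad, collapse = ", ")
    ), call = call)
  }
  invisible(data)
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE,
                           call = rlang::caller_env()) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single number in %s%g, %g%s (got %s).",
      name, if (lo_open) "(" else "[", lo, hi,
      if (hi_open) ")" else "]", paste(format(x), collapse = ", ")
    ), call = call)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1, call = rlang::caller_env()) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    x == round(x) && x >= min
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single integer >= %d (got %s).",
      name, min, paste(format(x), collapse = ", ")
    ), call = call)
  }
  invisible(as.integer(x))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions do not perturb the
# user's RNG stream.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# numeric matrix of the SNP columns (samples x SNPs)
snp_matrix <- function(data) {
  cols <- snp_cols(data)
  m <- as.matrix(data[, cols, drop = FALSE])
  if (is.character(m)) {
    abort("expected numeric (encoded) SNP columns; got character genotypes.")
  }
  storage.mode(m) <- "double"
  rownames(m) <- data$Sample_ID
  m
}
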