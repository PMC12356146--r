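#' Arithmetic-mean / geometric-mean ratio
#'
#' The AMGM ratio of a positive vector is its arithmetic mean divided by its
#' geometric mean. By the AM-GM inequality the ratio is always >= 1, with
#' equality exactly for constant vectors; it grows with the spread of the
#' values, which is what makes it usable as a variability/relevance score
#' for encoded SNP columns. The geometric mean is computed in log space for
#' numerical stability.
#'
#' @param x Numeric vector, all values strictly positive.
#' @return A single number >= 1.
#' @export
#' @examples
#' amgm_ratio(c(1, 2, 4)) # (7/3) / 2
amgm_ratio <- function(x) {
  if (length(x) < 1 || !is.numeric(x)) {
    abort("`x` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("`x` must be strictly positive and finite (apply an epsilon shift to encoded values that can be 0).")
  }
  exp(log(mean(x)) - mean(log(x)))
}

#' Rank SNPs by AMGM relevance
#'
#' Scores every encoded SNP column by the AMGM ratio of its values after a
#' small epsilon shift (mean encodings can be exactly 0, which would
#' degenerate the geometric mean) and returns the SNPs in descending score
#' order. Constant columns score exactly 1 and therefore sort to the bottom.
#' Ties are broken by SNP id so the ranking is invariant to the column order
#' of the input.
#'
#' @param data Labeled encoded tibble (numeric SNP columns).
#' @param eps Positive shift added to every value before scoring.
#' @return A `feature_ranking` tibble with columns `SNP_ID`, `score`, in
#'   descending score order.
#' @export
rank_by_amgm <- function(data, eps = 1e-6) {
  check_fraction(eps, "eps", 0, 1, lo_open = TRUE)
  m <- snp_matrix(data)
  scores <- exp(log(colMeans(m + eps)) - colMeans(log(m + eps)))
  new_feature_ranking(colnames(m), scores,
    method = "amgm", params = list(eps = eps)
  )
}

new_feature_ranking <- function(snp_ids, scores, method, params = list()) {
  ord <- order(-scores, snp_ids)
  structure(
    tibble(SNP_ID = snp_ids[ord], score = unname(scores[ord])),
    class = c("feature_ranking", class(tibble())),
    method = method, params = params
  )
}

#' Cosine similarity of two vectors
#'
#' Standard inner-product cosine, in [-1, 1]. Zero vectors have no direction
#' and are a domain error.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single number in [-1, 1].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("`u` and `v` must have equal length.")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine similarity is undefined for zero vectors.")
  sum(u * v) / (nu * nv)
}

#' Greedy cosine-redundancy filter
#'
#' Walks a relevance ranking from most to least relevant and keeps a SNP iff
#' its maximum cosine similarity to every already-kept SNP is below `tau`,
#' stopping once `n_final` SNPs are kept. If the pass over the whole ranking
#' ends short (everything left is redundant), the remaining slots are filled
#' from the skipped SNPs in rank order, with a warning, so the requested
#' panel size is always honored when the pool allows it.
#'
#' @param data Labeled encoded tibble whose columns the ranking refers to.
#' @param ranking A `feature_ranking` covering (at least) the SNPs to
#'   consider; only ranked SNPs present in `data` are considered.
#' @param n_final Number of SNPs to keep.
#' @param tau Cosine-similarity threshold above which a SNP is considered
#'   redundant with one already kept (default 0.95).
#' @return A `snp_selection` tibble with columns `rank`, `SNP_ID`.
#' @export
cosine_redundancy_filter <- function(data, ranking, n_final = 100, tau = 0.95) {
  n_final <- check_count(n_final, "n_final")
  check_fraction(tau, "tau", 0, 1, lo_open = TRUE)
  ids <- ranking$SNP_ID[ranking$SNP_ID %in% snp_cols(data)]
  if (length(ids) == 0) abort("ranking covers none of the dataset's SNPs.")
  if (n_final > length(ids)) {
    warn(sprintf(
      "n_final (%d) exceeds the candidate pool (%d); returning the full pool",
      n_final, length(ids)
    ))
    n_final <- length(ids)
  }
  m <- snp_matrix(data)[, ids, drop = FALSE]
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0)) {
    abort("encoded SNP columns must be non-zero vectors for cosine filtering.")
  }
  unit <- sweep(m, 2, norms, "/")

  kept <- integer(0)
  skipped <- integer(0)
  for (j in seq_along(ids)) {
    if (length(kept) >= n_final) break
    if (length(kept) == 0) {
      kept <- j
      next
    }
    sims <- crossprod(unit[, kept, drop = FALSE], unit[, j])
    if (max(sims) < tau) {
      kept <- c(kept, j)
    } else {
      skipped <- c(skipped, j)
    }
  }
  if (length(kept) < n_final) {
    fill <- utils::head(skipped, n_final - length(kept))
    warn(sprintf(
      "cosine filter kept only %d/%d SNPs at tau = %g; filling %d slot(s) from skipped SNPs in rank order",
      length(kept), n_final, tau, length(fill)
    ))
    kept <- c(kept, fill)
  }
  new_snp_selection(ids[kept],
    method = "cosine_redundancy",
    provenance = list(tau = tau, n_pool = length(ids), n_final = n_final)
  )
}

new_snp_selection <- function(snp_ids, method, provenance = list()) {
  structure(
    tibble(rank = seq_along(snp_ids), SNP_ID = snp_ids),
    class = c("snp_selection", class(tibble())),
    method = method, provenance = provenance
  )
}

#' Write a selection as a two-column CSV plus provenance sidecar
#'
#' @param selection A `snp_selection`.
#' @param path Output CSV path; the provenance sidecar is written next to it
#'   as `<path>.yml`.
#' @return The CSV path, invisibly.
#' @export
write_selection <- function(selection, path) {
  readr::write_csv(as_tibble(selection), path)
  yaml::write_yaml(
    list(
      method = attr(selection, "method"),
      provenance = attr(selection, "provenance")
    ),
    paste0(path, ".yml")
  )
  invisible(path)
}
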