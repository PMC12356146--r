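#' ReliefF feature weights
#'
#' Instance-based feature weighting: for each probe sample, the k nearest
#' neighbours of the same class (hits) and of each other class (misses,
#' weighted by class prior) are found, and each feature's weight is updated
#' by the mean value difference to the misses minus the mean difference to
#' the hits. Value differences are range-normalized, so weights are
#' invariant to positive rescaling of any feature; a constant feature always
#' weighs 0. By default every sample is used as a probe, making the result
#' deterministic.
#'
#' @param data Labeled encoded tibble (numeric SNP columns).
#' @param k_neighbors Number of nearest hits/misses per probe (default 10);
#'   must be smaller than the size of each class.
#' @param n_iterations Number of probe samples (default: all samples, used
#'   in their dataset order; fewer probes subsample deterministically from
#'   the front after a seeded shuffle when `seed` is given).
#' @param seed Optional seed for probe subsampling.
#' @return A `feature_ranking` tibble (`SNP_ID`, `score`), descending.
#' @export
relieff_weights <- function(data, k_neighbors = 10, n_iterations = NULL,
                            seed = NULL) {
  x <- snp_matrix(data)
  y <- case_indicator(data)
  k_neighbors <- check_count(k_neighbors, "k_neighbors")
  n <- nrow(x)
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("ReliefF requires both classes present.")
  class_n <- table(factor(y, levels = classes))
  if (k_neighbors >= min(class_n)) {
    abort(sprintf(
      "k_neighbors (%d) must be smaller than the smallest class (%d).",
      k_neighbors, min(class_n)
    ))
  }
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- Inf # constant feature -> all diffs 0
  xn <- sweep(x, 2, rng, "/")

  probes <- seq_len(n)
  if (!is.null(n_iterations)) {
    n_iterations <- check_count(n_iterations, "n_iterations")
    if (n_iterations < n) {
      probes <- if (is.null(seed)) {
        seq_len(n_iterations)
      } else {
        with_rng(seed, sample.int(n, n_iterations))
      }
    }
  }
  prior <- as.numeric(class_n) / n
  names(prior) <- classes
  d2 <- as.matrix(stats::dist(xn, method = "manhattan"))
  diag(d2) <- Inf

  w <- numeric(ncol(x))
  for (i in probes) {
    own <- y[i]
    idx <- order(d2[i, ])
    hits <- idx[y[idx] == own][seq_len(k_neighbors)]
    dh <- abs(sweep(xn[hits, , drop = FALSE], 2, xn[i, ]))
    upd <- -colMeans(dh)
    for (cl in setdiff(classes, own)) {
      miss <- idx[y[idx] == cl][seq_len(k_neighbors)]
      dm <- abs(sweep(xn[miss, , drop = FALSE], 2, xn[i, ]))
      wcl <- prior[as.character(cl)] / (1 - prior[as.character(own)])
      upd <- upd + wcl * colMeans(dm)
    }
    w <- w + upd
  }
  w <- w / length(probes)
  new_feature_ranking(colnames(x), w,
    method = "relieff",
    params = list(k_neighbors = k_neighbors, n_iterations = length(probes))
  )
}
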