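#' Autoencoder + L1 feature ranking
#'
#' Trains a single-hidden-layer autoencoder to reconstruct the
#' (internally mean-centered) encoded feature matrix with an L1 penalty on
#' the first-layer weights, then scores each feature by the sum of absolute
#' first-layer weights attached to it. Columns are centered but not
#' variance-scaled: on mean-encoded genotypes the spread of the
#' case-proportion values is exactly what makes a SNP worth keeping, so
#' scaling it away would blind the selector. Features that carry no shared
#' reconstruction signal are driven toward zero weight by the penalty and
#' fall to the bottom of the ranking; constant features score (near) zero by
#' construction. The fit is deterministic given the seed.
#'
#' @param data Labeled encoded tibble.
#' @param bottleneck Hidden-code size; default `ceiling(d / 4)`.
#' @param l1_lambda L1 weight-penalty strength (default 1e-3).
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param seed Integer RNG seed.
#' @return A `feature_ranking` tibble, descending by score.
#' @export
autoencoder_l1_ranking <- function(data, bottleneck = NULL, l1_lambda = 1e-3,
                                   epochs = 100, batch_size = 32,
                                   learning_rate = 1e-2, seed = 1) {
  X <- snp_matrix(data)
  d <- ncol(X)
  bn <- bottleneck %||% ceiling(d / 4)
  if (bn >= d) abort("`bottleneck` must be smaller than the number of features.")
  # centered but deliberately NOT variance-scaled: on mean-encoded SNPs the
  # between-genotype spread of the case proportion IS the relevance signal,
  # and z-scoring would erase it for an unsupervised selector
  Xs <- sweep(X, 2, colMeans(X))
  fit <- with_rng(seed, train_autoencoder(
    Xs, bn,
    epochs = epochs, batch_size = batch_size,
    learning_rate = learning_rate, l1_weights = l1_lambda
  ))
  const <- apply(X, 2, stats::sd) == 0
  scores <- rowSums(abs(fit$params$W1))
  scores[const] <- 0 # a constant feature carries no reconstruction signal
  new_feature_ranking(colnames(X), scores,
    method = "ae_l1",
    params = list(
      bottleneck = bn, l1_lambda = l1_lambda, epochs = epochs,
      seed = seed
    )
  )
}

FS_METHODS <- c(
  "amgm_cosine", "ae_l1", "relieff", "cmim_svmrfe",
  "chi_squared", "mutual_information"
)

#' Select SNPs with any of the package's feature-selection methods
#'
#' Single dispatcher over the feature-selection suite. Methods that need
#' numeric inputs (`amgm_cosine`, `ae_l1`, `relieff`, the SVM-RFE stage of
#' `cmim_svmrfe`) run on mean-encoded values; information-theoretic methods
#' (`chi_squared`, `mutual_information`, the CMIM stage) run on the raw
#' genotype categories. If `encoded` is not supplied it is fitted on `data`
#' itself — inside cross-validation pass the fold-safe encoding explicitly.
#'
#' Defaults follow the two-stage panel-building flow: `amgm_cosine` keeps
#' the `n_intermediate = 1000` most relevant SNPs by AMGM ratio and then
#' cosine-filters them down to `n_select = 100` unique SNPs; the other
#' methods return their top `n_select` directly.
#'
#' @param data Labeled, NC-free genotype tibble (character genotypes).
#' @param method One of `r paste0('"', FS_METHODS, '"', collapse = ", ")`.
#' @param n_select Final panel size (default 100).
#' @param encoded Optional labeled encoded tibble over the same samples and
#'   SNPs; computed from `data` when absent.
#' @param n_intermediate Intermediate pool size for the two-stage methods
#'   (`amgm_cosine`, `cmim_svmrfe`); default 1000 (capped at the pool).
#' @param tau Cosine-redundancy threshold for `amgm_cosine`.
#' @param seed Seed forwarded to stochastic selectors (`ae_l1`).
#' @param ... Further arguments passed to the underlying selector.
#' @return A `snp_selection` tibble (`rank`, `SNP_ID`) with method and stage
#'   parameters as provenance.
#' @export
select_features <- function(data, method, n_select = 100, encoded = NULL,
                            n_intermediate = 1000, tau = 0.95, seed = 1, ...) {
  if (!is.character(method) || length(method) != 1 ||
    !method %in% FS_METHODS) {
    abort(sprintf(
      "unknown feature-selection method '%s'; options: %s",
      paste(method, collapse = ","), paste(FS_METHODS, collapse = ", ")
    ))
  }
  check_labeled(data)
  n_select <- check_count(n_select, "n_select")
  pool <- snp_cols(data)
  needs_encoding <- method %in% c("amgm_cosine", "ae_l1", "relieff", "cmim_svmrfe")
  if (needs_encoding && is.null(encoded)) {
    encoded <- mean_encode(data)
  }
  n_out <- min(n_select, length(pool))
  if (n_select > length(pool)) {
    warn(sprintf(
      "n_select (%d) exceeds the SNP pool (%d); returning the full pool",
      n_select, length(pool)
    ))
  }
  sel <- switch(method,
    amgm_cosine = {
      ranking <- rank_by_amgm(encoded, ...)
      n_mid <- min(n_intermediate, nrow(ranking))
      top <- ranking[seq_len(n_mid), ]
      keep <- c("Sample_ID", "Case_Control", top$SNP_ID)
      out <- cosine_redundancy_filter(encoded[, keep], top,
        n_final = n_out, tau = tau
      )
      attr(out, "provenance") <- c(
        list(n_intermediate = n_mid),
        attr(out, "provenance")
      )
      out
    },
    ae_l1 = {
      ranking <- autoencoder_l1_ranking(encoded, seed = seed, ...)
      new_snp_selection(utils::head(ranking$SNP_ID, n_out),
        method = "ae_l1", provenance = attr(ranking, "params")
      )
    },
    relieff = {
      ranking <- relieff_weights(encoded, ...)
      new_snp_selection(utils::head(ranking$SNP_ID, n_out),
        method = "relieff", provenance = attr(ranking, "params")
      )
    },
    cmim_svmrfe = hybrid_cmim_svmrfe(
      data, encoded,
      n_intermediate = min(n_intermediate, length(pool)),
      n_select = n_out, ...
    ),
    chi_squared = ,
    mutual_information = {
      ranking <- univariate_ranking(data, method = method)
      new_snp_selection(utils::head(ranking$SNP_ID, n_out),
        method = method, provenance = list()
      )
    }
  )
  attr(sel, "method") <- method
  sel
}
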