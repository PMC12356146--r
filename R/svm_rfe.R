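#' SVM-RFE feature selection
#'
#' Recursive feature elimination with a linear soft-margin SVM (C = 1,
#' libsvm via \pkg{e1071}): repeatedly fit on the surviving features and
#' remove the `ceiling(drop_fraction * surviving)` features with the
#' smallest absolute weight in the primal hyperplane, never dropping below
#' `n_select`. The elimination order is recorded in the provenance.
#'
#' @param data Labeled encoded tibble (numeric SNP columns).
#' @param n_select Number of features to retain.
#' @param drop_fraction Fraction of surviving features eliminated per
#'   iteration (default 0.1).
#' @return A `snp_selection`; survivors are ordered by final |weight|
#'   (largest first).
#' @export
svm_rfe_select <- function(data, n_select, drop_fraction = 0.1) {
  n_select <- check_count(n_select, "n_select")
  check_fraction(drop_fraction, "drop_fraction", 0, 1,
    lo_open = TRUE, hi_open = TRUE
  )
  x <- snp_matrix(data)
  y <- factor(case_indicator(data), levels = c(0, 1))
  if (nlevels(droplevels(y)) < 2) abort("SVM-RFE requires both classes.")
  if (n_select > ncol(x)) {
    warn(sprintf(
      "n_select (%d) exceeds the SNP pool (%d); returning the full pool",
      n_select, ncol(x)
    ))
    n_select <- ncol(x)
  }
  surviving <- colnames(x)
  eliminated <- character(0)
  w_final <- NULL
  repeat {
    fit <- e1071::svm(x[, surviving, drop = FALSE], y,
      kernel = "linear", cost = 1, scale = FALSE
    )
    w <- drop(crossprod(fit$coefs, fit$SV))
    names(w) <- surviving
    w_final <- w
    if (length(surviving) <= n_select) break
    n_drop <- min(
      ceiling(drop_fraction * length(surviving)),
      length(surviving) - n_select
    )
    # smallest |w| go first; ties by SNP id for determinism
    ord <- order(abs(w), names(w))
    drop_ids <- names(w)[ord][seq_len(n_drop)]
    eliminated <- c(eliminated, drop_ids)
    surviving <- setdiff(surviving, drop_ids)
  }
  ord <- order(-abs(w_final), names(w_final))
  new_snp_selection(names(w_final)[ord],
    method = "svm_rfe",
    provenance = list(
      n_select = n_select, drop_fraction = drop_fraction,
      elimination_order = eliminated
    )
  )
}

#' Hybrid CMIM + SVM-RFE selection
#'
#' Two-stage hybrid: [cmim_select()] on the raw genotype categories reduces
#' the pool to `n_intermediate` SNPs, then [svm_rfe_select()] on the encoded
#' values of those SNPs reduces to `n_select`. Both stage parameters are
#' recorded in the provenance. With `n_intermediate` equal to the pool the
#' hybrid degenerates to plain SVM-RFE; with `n_select = n_intermediate` it
#' degenerates to plain CMIM.
#'
#' @param data Labeled, NC-free genotype tibble (categorical, for CMIM).
#' @param encoded Labeled encoded tibble over the same SNPs (for SVM-RFE).
#' @param n_intermediate Pool size after the CMIM stage.
#' @param n_select Final panel size.
#' @inheritParams svm_rfe_select
#' @return A `snp_selection`.
#' @export
hybrid_cmim_svmrfe <- function(data, encoded, n_intermediate, n_select,
                               drop_fraction = 0.1) {
  n_intermediate <- check_count(n_intermediate, "n_intermediate")
  n_select <- check_count(n_select, "n_select")
  if (n_select > n_intermediate) {
    abort("`n_select` must be <= `n_intermediate`.")
  }
  stage1 <- cmim_select(data, n_select = n_intermediate)
  keep <- c("Sample_ID", "Case_Control", stage1$SNP_ID)
  keep <- keep[keep %in% names(encoded)]
  if (n_select == nrow(stage1)) {
    out <- stage1
    prov2 <- NULL
  } else {
    out <- svm_rfe_select(encoded[, keep],
      n_select = n_select,
      drop_fraction = drop_fraction
    )
    prov2 <- attr(out, "provenance")
  }
  new_snp_selection(utils::head(out$SNP_ID, n_select),
    method = "cmim_svmrfe",
    provenance = list(
      n_intermediate = n_intermediate, n_select = n_select,
      cmim = attr(stage1, "provenance"),
      svm_rfe = prov2
    )
  )
}
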