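#' Remove SNPs with no genotype variation
#'
#' Drops every SNP whose non-No-Call genotypes are all identical (including
#' SNPs with no called genotypes at all): a SNP on which every sample agrees
#' carries no information for case/control discrimination. Invariance is
#' judged on called (non-NC) cells, since this cleaning step precedes
#' imputation.
#'
#' @param data Labeled sample-per-row genotype tibble.
#' @return The tibble with invariant SNP columns removed; the number removed
#'   is reported via a message.
#' @export
drop_invariant_snps <- function(data) {
  check_labeled(data)
  cols <- snp_cols(data)
  if (length(cols) == 0) abort("dataset has no SNP columns.")
  keep <- vapply(cols, function(s) {
    g <- data[[s]]
    length(unique(g[g != NO_CALL])) >= 2
  }, logical(1))
  if (!any(keep)) {
    abort("all SNPs are invariant; nothing left after filtering.")
  }
  if (any(!keep)) {
    inform(sprintf("drop_invariant_snps: removed %d SNP(s)", sum(!keep)))
  }
  data[, c("Sample_ID", "Case_Control", cols[keep])]
}

#' Remove SNPs with a high No-Call fraction
#'
#' Drops SNPs whose fraction of `NC` cells is strictly greater than
#' `threshold` (default 0.10, i.e. "more than 10% No Call"): a SNP at
#' exactly the threshold is retained.
#'
#' @param data Labeled sample-per-row genotype tibble.
#' @param threshold Maximum tolerated NC fraction, in [0, 1).
#' @return The tibble with high-NC SNP columns removed.
#' @export
drop_high_nocall_snps <- function(data, threshold = 0.10) {
  check_labeled(data)
  check_fraction(threshold, "threshold", 0, 1, hi_open = TRUE)
  cols <- snp_cols(data)
  nc_frac <- vapply(cols, function(s) mean(data[[s]] == NO_CALL), numeric(1))
  keep <- nc_frac <= threshold
  if (!any(keep)) {
    abort("all SNPs exceed the No-Call threshold; nothing left.")
  }
  if (any(!keep)) {
    inform(sprintf(
      "drop_high_nocall_snps: removed %d SNP(s) with NC fraction > %g",
      sum(!keep), threshold
    ))
  }
  data[, c("Sample_ID", "Case_Control", cols[keep])]
}

#' Replace No-Call cells by the SNP's modal genotype
#'
#' Each `NC` cell is replaced with the most common called genotype (AA, AB
#' or BB) of its SNP across all samples. Ties are broken deterministically
#' in the order AA < AB < BB. Every SNP must have at least one called cell
#' (guaranteed after [drop_high_nocall_snps()] with any threshold < 1).
#'
#' @param data Labeled sample-per-row genotype tibble.
#' @return The tibble with no remaining `NC` cells.
#' @export
impute_nocall_mode <- function(data) {
  check_labeled(data)
  cols <- snp_cols(data)
  for (s in cols) {
    g <- data[[s]]
    nc <- g == NO_CALL
    if (!any(nc)) next
    counts <- table(factor(g[!nc], levels = GENOTYPES))
    if (sum(counts) == 0) {
      abort(sprintf("SNP '%s' has no called genotypes; cannot impute.", s))
    }
    # which.max returns the first maximum => AA < AB < BB tie-break
    g[nc] <- GENOTYPES[which.max(counts)]
    data[[s]] <- g
  }
  data
}

#' Fit per-SNP mean (case-proportion) encodings
#'
#' For each SNP and each genotype G observed in the fitting samples, the
#' encoding is the proportion of Case samples among samples carrying G:
#'
#'   E(G) = (# Case samples with genotype G) / (# samples with genotype G)
#'
#' The fitted map also stores a fallback value — the fitting samples' overall
#' case fraction — used by [apply_mean_encoding()] for genotypes never seen
#' at fit time. Fitting on a subset of samples (`sample_ids`) supports
#' leakage-safe use inside cross-validation, where the map must be fitted on
#' training folds only.
#'
#' @param data Labeled, NC-free sample-per-row genotype tibble.
#' @param sample_ids Optional character vector restricting the fit to those
#'   samples; must contain both classes.
#' @return An `encoding_map`: list with `levels` (tibble `SNP_ID`,
#'   `genotype`, `value`), `fallback` (scalar case fraction of the fitting
#'   samples) and `n_fit`.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   Sample_ID = paste0("S", 1:6),
#'   Case_Control = c("Case", "Case", "Case", "Case", "Control", "Control"),
#'   SNP_1 = c("AA", "AA", "AA", "AA", "AA", "AA"),
#'   SNP_2 = c("AA", "AB", "AB", "BB", "AA", "BB")
#' )
#' fit_mean_encoding(d)$levels
fit_mean_encoding <- function(data, sample_ids = NULL) {
  check_labeled(data)
  fit <- if (is.null(sample_ids)) {
    data
  } else {
    if (length(sample_ids) == 0) abort("`sample_ids` must be non-empty.")
    data[data$Sample_ID %in% sample_ids, , drop = FALSE]
  }
  if (nrow(fit) == 0) abort("no fitting samples found.")
  y <- case_indicator(fit)
  if (length(unique(y)) < 2) {
    abort("fitting samples must contain both Case and Control labels.")
  }
  cols <- snp_cols(fit)
  lv <- purrr::map(cols, function(s) {
    g <- fit[[s]]
    if (any(g == NO_CALL)) {
      abort(sprintf("SNP '%s' still contains NC cells; impute first.", s))
    }
    tot <- tapply(rep(1L, length(g)), g, sum)
    cas <- tapply(y, g, sum)
    tibble(
      SNP_ID = s, genotype = names(tot),
      value = as.numeric(cas) / as.numeric(tot)
    )
  })
  structure(
    list(
      levels = dplyr::bind_rows(lv),
      fallback = mean(y),
      n_fit = nrow(fit)
    ),
    class = "encoding_map"
  )
}

#' @export
print.encoding_map <- function(x, ...) {
  cat(sprintf(
    "<encoding_map> %d SNPs, fitted on %d samples (fallback %.4f)\n",
    dplyr::n_distinct(x$levels$SNP_ID), x$n_fit, x$fallback
  ))
  invisible(x)
}

#' Apply a fitted mean-encoding map
#'
#' Replaces every genotype cell by its SNP's fitted E(G). Genotypes unseen
#' at fit time receive the map's fallback (the fitting samples' case
#' fraction). Labels are carried through unchanged. Every SNP in `data`
#' must be covered by the map.
#'
#' @param map An `encoding_map` from [fit_mean_encoding()].
#' @param data Labeled, NC-free genotype tibble to encode.
#' @return Labeled tibble with numeric SNP columns, all values in [0, 1].
#' @export
apply_mean_encoding <- function(map, data) {
  if (!inherits(map, "encoding_map")) abort("`map` must be an encoding_map.")
  check_labeled(data)
  cols <- snp_cols(data)
  missing <- setdiff(cols, unique(map$levels$SNP_ID))
  if (length(missing) > 0) {
    abort(sprintf(
      "encoding map does not cover SNP(s): %s",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  lv <- split(map$levels, map$levels$SNP_ID)
  for (s in cols) {
    tab <- lv[[s]]
    vals <- stats::setNames(tab$value, tab$genotype)
    enc <- unname(vals[data[[s]]])
    enc[is.na(enc)] <- map$fallback
    data[[s]] <- enc
  }
  data
}

#' Clean a labeled genotype panel
#'
#' Runs the fixed cleaning order: invariant-SNP removal, then removal of
#' SNPs with more than `nc_threshold` No-Call cells, then modal imputation
#' of the remaining No-Calls. The output is NC-free and ready for encoding.
#'
#' @param data Labeled sample-per-row genotype tibble.
#' @param nc_threshold NC-fraction threshold for [drop_high_nocall_snps()].
#' @return Cleaned labeled tibble.
#' @export
preprocess_genotypes <- function(data, nc_threshold = 0.10) {
  data |>
    drop_invariant_snps() |>
    drop_high_nocall_snps(threshold = nc_threshold) |>
    impute_nocall_mode()
}

#' Fit-and-apply mean encoding in one step
#'
#' Convenience wrapper fitting [fit_mean_encoding()] on all samples of
#' `data` and applying it to the same samples — the whole-dataset encoding
#' mode. Inside cross-validation use [fit_mean_encoding()] on the training
#' fold instead (see [cross_validate()]'s `encoding` argument).
#'
#' @inheritParams fit_mean_encoding
#' @return Labeled encoded tibble.
#' @export
mean_encode <- function(data) {
  apply_mean_encoding(fit_mean_encoding(data), data)
}

#' Serialize an encoding map to a plain-text file
#'
#' Writes the per-SNP, per-genotype encodings plus the fallback as YAML for
#' audit.
#'
#' @param map An `encoding_map`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_encoding_map <- function(map, path) {
  if (!inherits(map, "encoding_map")) abort("`map` must be an encoding_map.")
  yaml::write_yaml(
    list(
      fallback = map$fallback,
      n_fit = map$n_fit,
      levels = purrr::pmap(map$levels, function(SNP_ID, genotype, value) {
        list(snp = SNP_ID, genotype = genotype, value = value)
      })
    ),
    path, precision = 15
  )
  invisible(path)
}
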