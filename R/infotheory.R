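# Plug-in (empirical) information-theoretic quantities in bits, on raw
# genotype categories. Running these selectors on categories rather than on
# mean-encoded values keeps label information out of the selector's input
# representation.

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# I(X; Y) from two aligned category vectors
mi_bits <- function(x, y) {
  joint <- table(x, y)
  n <- sum(joint)
  px <- rowSums(joint) / n
  py <- colSums(joint) / n
  pj <- joint / n
  terms <- pj * log2(pj / outer(px, py))
  sum(terms[pj > 0])
}

# I(X; Y | Z) = sum_z p(z) I(X; Y | Z = z)
cmi_bits <- function(x, y, z) {
  out <- 0
  for (zl in unique(z)) {
    sel <- z == zl
    out <- out + mean(sel) * mi_bits(x[sel], y[sel])
  }
  out
}

#' Univariate SNP ranking by chi-squared or mutual information
#'
#' Scores every SNP on its genotype-by-class contingency table: either the
#' Pearson chi-squared statistic (no continuity correction) or the plug-in
#' mutual information in bits. Operates on raw genotype categories, not on
#' encoded values.
#'
#' @param data Labeled, NC-free genotype tibble (character SNP columns).
#' @param method `"chi_squared"` or `"mutual_information"`.
#' @return A `feature_ranking` tibble, descending by score.
#' @export
univariate_ranking <- function(data,
                               method = c("chi_squared", "mutual_information")) {
  method <- rlang::arg_match(method)
  check_labeled(data)
  y <- data$Case_Control
  cols <- snp_cols(data)
  scores <- vapply(cols, function(s) {
    g <- data[[s]]
    if (method == "chi_squared") {
      tab <- table(g, y)
      if (nrow(tab) < 2 || ncol(tab) < 2) {
        return(0)
      }
      unname(suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$statistic
      ))
    } else {
      mi_bits(g, y)
    }
  }, numeric(1))
  new_feature_ranking(cols, scores, method = method)
}

#' Greedy CMIM feature selection
#'
#' Conditional Mutual Information Maximization on raw genotype categories:
#' the first SNP maximizes I(F; Y); each subsequent pick maximizes the
#' minimum over already-selected SNPs S of I(F; Y | S), so a SNP whose class
#' information is already carried by a selected SNP (e.g. an exact
#' duplicate, for which I(F; Y | F) = 0) scores 0 and is never picked while
#' informative alternatives remain. Entropies are plug-in estimates in bits.
#' Ties are broken by SNP id.
#'
#' @param data Labeled, NC-free genotype tibble (character SNP columns).
#' @param n_select Number of SNPs to select. If it exceeds the pool, the
#'   full pool is returned with a warning.
#' @return A `snp_selection` tibble (`rank`, `SNP_ID`), with the selection
#'   order as provenance.
#' @export
cmim_select <- function(data, n_select) {
  check_labeled(data)
  n_select <- check_count(n_select, "n_select")
  y <- data$Case_Control
  cols <- sort(snp_cols(data))
  if (n_select > length(cols)) {
    warn(sprintf(
      "n_select (%d) exceeds the SNP pool (%d); returning the full pool",
      n_select, length(cols)
    ))
    n_select <- length(cols)
  }
  # running CMIM score: min over selected S of I(F; Y | S), initialized at
  # I(F; Y); after each pick only the running minimum needs updating
  score <- vapply(cols, function(s) mi_bits(data[[s]], y), numeric(1))
  selected <- character(0)
  remaining <- cols
  while (length(selected) < n_select) {
    best <- remaining[which.max(score[remaining])]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining) == 0) break
    for (f in remaining) {
      score[f] <- min(score[f], cmi_bits(data[[f]], y, data[[best]]))
    }
  }
  new_snp_selection(selected,
    method = "cmim",
    provenance = list(n_select = n_select)
  )
}
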