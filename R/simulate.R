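#' Simulation configuration for synthetic genotype panels
#'
#' Bundles and validates the parameters of the synthetic case/control
#' genotype generator. Defaults describe a desk-scale panel in the style of
#' public case/control SNP series: a few hundred near-balanced samples, SNPs
#' drawn under Hardy-Weinberg proportions with minor-allele frequencies
#' between 0.05 and 0.5, and a handful of causal SNPs acting additively on
#' the log-odds of disease.
#'
#' @param n_samples Number of samples (columns of the genotype file).
#' @param n_snps Number of SNPs (rows of the genotype file).
#' @param n_causal Number of causal SNPs planted into the label model
#'   (`0` gives a pure null panel).
#' @param causal_effect Multiplicative odds effect per copy of the risk
#'   allele at each causal SNP (dimensionless, `>= 1`; `1` means no effect).
#'   The risk allele is always the minor ("B") allele.
#' @param maf_range Length-2 numeric, lower/upper bound of the per-SNP
#'   minor-allele frequency, each in (0, 0.5].
#' @param nc_rate Fraction of cells replaced by No-Call (`NC`), in [0, 1).
#' @param case_fraction Target fraction of Case samples, in (0, 1); enforced
#'   by calibrating the logistic intercept on the simulated linear
#'   predictors.
#' @param seed Integer RNG seed; identical configurations (seed included)
#'   yield identical panels.
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 50, n_snps = 20, n_causal = 2, seed = 1)
sim_config <- function(n_samples = 200, n_snps = 1000, n_causal = 10,
                       causal_effect = 2, maf_range = c(0.05, 0.5),
                       nc_rate = 0, case_fraction = 0.5, seed = 1) {
  n_samples <- check_count(n_samples, "n_samples")
  n_snps <- check_count(n_snps, "n_snps")
  n_causal <- check_count(n_causal, "n_causal", min = 0)
  if (n_causal > n_snps) {
    abort("`n_causal` must be <= `n_snps`.")
  }
  if (!is.numeric(causal_effect) || length(causal_effect) != 1 ||
    !is.finite(causal_effect) || causal_effect < 1) {
    abort("`causal_effect` must be a single finite number >= 1.")
  }
  if (!is.numeric(maf_range) || length(maf_range) != 2 ||
    any(!is.finite(maf_range)) || maf_range[1] <= 0 ||
    maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be two increasing values in (0, 0.5].")
  }
  check_fraction(nc_rate, "nc_rate", 0, 1, hi_open = TRUE)
  check_fraction(case_fraction, "case_fraction", 0, 1,
    lo_open = TRUE, hi_open = TRUE
  )
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(
      n_samples = n_samples, n_snps = n_snps, n_causal = n_causal,
      causal_effect = causal_effect, maf_range = as.numeric(maf_range),
      nc_rate = nc_rate, case_fraction = case_fraction, seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d samples x %d SNPs, %d causal (odds x%.3g/allele)\n",
    x$n_samples, x$n_snps, x$n_causal, x$causal_effect
  ))
  cat(sprintf(
    "  MAF in [%.3g, %.3g], NC rate %.3g, case fraction %.3g, seed %d\n",
    x$maf_range[1], x$maf_range[2], x$nc_rate, x$case_fraction, x$seed
  ))
  invisible(x)
}

#' Generate a synthetic case/control genotype panel
#'
#' Simulates a labeled SNP panel with known ground truth. Per-SNP genotypes
#' are drawn under Hardy-Weinberg proportions (p^2, 2pq, q^2) from a
#' minor-allele frequency sampled uniformly in `maf_range`; the "B" allele is
#' always the minor (risk) allele. Case/Control labels are drawn from a
#' logistic model whose linear predictor is the sum over causal SNPs of the
#' sample's B-allele count times `log(causal_effect)`, plus an intercept
#' calibrated by root-finding so the expected case fraction matches
#' `case_fraction`. Non-causal SNPs are independent of the labels by
#' construction. If `nc_rate > 0`, No-Call values are injected afterwards
#' via [inject_nocalls()].
#'
#' @param config A [sim_config()].
#' @return A list with components:
#'   * `data` — labeled tibble, one row per sample: `Sample_ID`,
#'     `Case_Control`, then one character genotype column per SNP;
#'   * `truth` — a `ground_truth` list: `causal_snp_ids`,
#'     `genotype_probs` (tibble of per-SNP AA/AB/BB probabilities),
#'     `maf`, `log_odds_per_allele`, `intercept`.
#' @export
#' @examples
#' sim <- generate_genotypes(sim_config(n_samples = 40, n_snps = 10, seed = 3))
#' dim(sim$data)
generate_genotypes <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, as.list(config))
  }
  with_rng(config$seed, {
    n <- config$n_samples
    p <- config$n_snps
    snp_ids <- sprintf("SNP_%05d", seq_len(p))
    sample_ids <- sprintf("S%04d", seq_len(n))
    maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
    probs <- cbind(
      AA = (1 - maf)^2,
      AB = 2 * maf * (1 - maf),
      BB = maf^2
    )
    # B-allele dosage per (sample, SNP): 0/1/2 drawn per SNP's HW triple
    u <- matrix(stats::runif(n * p), nrow = n)
    dos <- matrix(0L, nrow = n, ncol = p)
    thr1 <- matrix(probs[, "AA"], nrow = n, ncol = p, byrow = TRUE)
    thr2 <- matrix(probs[, "AA"] + probs[, "AB"], nrow = n, ncol = p, byrow = TRUE)
    dos[u >= thr1] <- 1L
    dos[u >= thr2] <- 2L

    causal <- if (config$n_causal > 0) {
      sort(sample.int(p, config$n_causal))
    } else {
      integer(0)
    }
    beta <- log(config$causal_effect)
    eta <- if (length(causal) > 0) {
      rowSums(dos[, causal, drop = FALSE]) * beta
    } else {
      rep(0, n)
    }
    # intercept calibration: mean predicted probability == case_fraction
    f <- function(b0) mean(stats::plogis(eta + b0)) - config$case_fraction
    b0 <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
    y <- stats::rbinom(n, 1, stats::plogis(eta + b0))

    geno <- matrix(GENOTYPES[dos + 1L], nrow = n, ncol = p,
      dimnames = list(NULL, snp_ids)
    )
    data <- dplyr::bind_cols(
      tibble(
        Sample_ID = sample_ids,
        Case_Control = ifelse(y == 1, "Case", "Control")
      ),
      as_tibble(geno)
    )
    truth <- structure(
      list(
        causal_snp_ids = snp_ids[causal],
        genotype_probs = dplyr::bind_cols(
          tibble(SNP_ID = snp_ids), as_tibble(probs)
        ),
        maf = stats::setNames(maf, snp_ids),
        log_odds_per_allele = beta,
        intercept = b0
      ),
      class = "ground_truth"
    )
    if (config$nc_rate > 0) {
      data <- inject_nocalls(data, config$nc_rate, seed = config$seed + 1L)
    }
    list(data = data, truth = truth)
  })
}

#' Inject No-Call values into a genotype panel
#'
#' Independently replaces each genotype cell with `NC` with probability
#' `nc_rate`. Identifier and label columns are untouched. Seeded and
#' reproducible.
#'
#' @param data Labeled or unlabeled sample-per-row genotype tibble.
#' @param nc_rate Per-cell No-Call probability, in [0, 1).
#' @param seed Integer RNG seed.
#' @return The tibble with some cells set to `"NC"`.
#' @export
inject_nocalls <- function(data, nc_rate, seed = 1) {
  check_fraction(nc_rate, "nc_rate", 0, 1, hi_open = TRUE)
  if (nc_rate == 0) {
    return(data)
  }
  cols <- snp_cols(data)
  with_rng(seed, {
    m <- as.matrix(data[, cols, drop = FALSE])
    mask <- matrix(stats::runif(length(m)) < nc_rate, nrow = nrow(m))
    m[mask] <- NO_CALL
    data[, cols] <- as_tibble(m)
    data
  })
}

#' Write a labeled panel as a GEO-style genotype/phenotype CSV pair
#'
#' Writes the two-file dialect read back by [read_genotype_csv()] and
#' [read_phenotype_csv()]: a genotype CSV with one row per SNP (header
#' `SNP_ID` followed by sample IDs, cells in AA/AB/BB/NC) and a phenotype CSV
#' with columns `Sample_ID`, `Case_Control`. A plain-text `ground_truth.yml`
#' sidecar recording causal SNP ids and simulation parameters is written
#' when `truth` is supplied.
#'
#' @param data Labeled sample-per-row genotype tibble.
#' @param out_dir Output directory (created if missing).
#' @param truth Optional `ground_truth` object from [generate_genotypes()].
#' @return Named character vector with paths `genotype`, `phenotype` (and
#'   `truth` if written).
#' @export
write_geo_style_csvs <- function(data, out_dir, truth = NULL) {
  check_labeled(data)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  cols <- snp_cols(data)
  geno <- as.matrix(data[, cols, drop = FALSE])
  gtab <- dplyr::bind_cols(
    tibble(SNP_ID = cols),
    as_tibble(t(geno), .name_repair = "minimal") |>
      stats::setNames(data$Sample_ID)
  )
  gpath <- file.path(out_dir, "genotypes.csv")
  ppath <- file.path(out_dir, "phenotypes.csv")
  readr::write_csv(gtab, gpath)
  readr::write_csv(
    tibble(Sample_ID = data$Sample_ID, Case_Control = data$Case_Control),
    ppath
  )
  paths <- c(genotype = gpath, phenotype = ppath)
  if (!is.null(truth)) {
    tpath <- file.path(out_dir, "ground_truth.yml")
    yaml::write_yaml(
      list(
        causal_snp_ids = as.list(truth$causal_snp_ids),
        log_odds_per_allele = truth$log_odds_per_allele,
        intercept = truth$intercept
      ),
      tpath, precision = 15
    )
    paths <- c(paths, truth = tpath)
  }
  paths
}
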