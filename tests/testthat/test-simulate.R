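test_that("sim_config validates its fields and names the offender", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(n_causal = 50, n_snps = 10), "n_causal")
  expect_error(sim_config(causal_effect = 0.5), "causal_effect")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(nc_rate = 1), "nc_rate")
  expect_error(sim_config(case_fraction = 0), "case_fraction")
})

test_that("generated panels have the right shape, vocabulary and determinism", {
  cfg <- sim_config(n_samples = 40, n_snps = 15, n_causal = 3, seed = 7)
  sim1 <- generate_genotypes(cfg)
  sim2 <- generate_genotypes(cfg)
  expect_identical(sim1$data, sim2$data)
  expect_identical(sim1$truth$causal_snp_ids, sim2$truth$causal_snp_ids)
  d <- sim1$data
  expect_equal(dim(d), c(40, 15 + 2))
  cells <- as.matrix(d[, snp_cols(d)])
  expect_true(all(cells %in% c("AA", "AB", "BB")))
  expect_true(all(sim1$truth$causal_snp_ids %in% snp_cols(d)))
  probs <- sim1$truth$genotype_probs
  expect_equal(probs$AA + probs$AB + probs$BB, rep(1, 15), tolerance = 1e-9)
})

test_that("null panels have labels independent of every SNP", {
  sim <- generate_genotypes(sim_config(
    n_samples = 600, n_snps = 40, n_causal = 0, causal_effect = 1, seed = 11
  ))
  d <- sim$data
  pvals <- vapply(snp_cols(d), function(s) {
    tab <- table(d[[s]], d$Case_Control)
    if (nrow(tab) < 2) return(NA_real_)
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  # under the null, p-values are uniform; KS test should not reject strongly
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
  expect_gt(mean(pvals), 0.3)
})

test_that("planted effects reproduce the oracle's marginal odds ratio", {
  n <- 50000
  cfg <- sim_config(
    n_samples = n, n_snps = 8, n_causal = 5, causal_effect = 4,
    maf_range = c(0.3, 0.3001), case_fraction = 0.5, seed = 21
  )
  sim <- generate_genotypes(cfg)
  d <- sim$data
  y <- case_indicator(d)
  or_pkg <- vapply(sim$truth$causal_snp_ids, function(s) {
    g <- d[[s]]
    odds <- function(sel) {
      p <- mean(y[sel])
      p / (1 - p)
    }
    odds(g == "BB") / odds(g == "AA")
  }, numeric(1))
  set.seed(99)
  or_ref <- replicate(3, oracle_marginal_odds_ratio(
    n = n, maf = 0.3, beta = log(4), n_causal = 5, case_fraction = 0.5
  ))
  # marginal (collapsed over other causal SNPs) odds ratios agree with the
  # independent tabulation; both sit below the conditional effect^2 = 16
  expect_equal(mean(or_pkg), mean(or_ref), tolerance = 0.15)
  expect_true(all(or_pkg > 4))
})

test_that("case_fraction calibration holds on average", {
  sim <- generate_genotypes(sim_config(
    n_samples = 4000, n_snps = 30, n_causal = 5, causal_effect = 3,
    case_fraction = 0.3, seed = 5
  ))
  frac <- mean(sim$data$Case_Control == "Case")
  se <- sqrt(0.3 * 0.7 / 4000)
  expect_lt(abs(frac - 0.3), 4 * se)
})

test_that("inject_nocalls is a seeded no-op at rate 0 and binomial otherwise", {
  sim <- generate_genotypes(sim_config(n_samples = 100, n_snps = 100, seed = 3))
  d <- sim$data
  expect_identical(inject_nocalls(d, 0), d)
  d1 <- inject_nocalls(d, 0.5, seed = 4)
  d2 <- inject_nocalls(d, 0.5, seed = 4)
  expect_identical(d1, d2)
  frac <- mean(as.matrix(d1[, snp_cols(d1)]) == "NC")
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(frac - 0.5), 3 * se)
  expect_identical(d1$Case_Control, d$Case_Control)
  expect_error(inject_nocalls(d, 1.2), "nc_rate")
})

test_that("GEO-style CSV pair round-trips exactly through the readers", {
  sim <- generate_genotypes(sim_config(
    n_samples = 12, n_snps = 6, n_causal = 2, nc_rate = 0.1, seed = 13
  ))
  dir <- withr::local_tempdir()
  paths <- write_geo_style_csvs(sim$data, dir, truth = sim$truth)
  expect_true(all(file.exists(paths)))
  geno <- read_genotype_csv(paths[["genotype"]])
  expect_equal(nrow(geno), 6)
  expect_equal(ncol(geno), 13) # SNP_ID + 12 samples
  pheno <- read_phenotype_csv(paths[["phenotype"]])
  expect_equal(nrow(pheno), 12)
  merged <- merge_case_control(geno, pheno)
  expect_identical(merged, sim$data)
  truth <- yaml::read_yaml(paths[["truth"]])
  expect_identical(unlist(truth$causal_snp_ids), sim$truth$causal_snp_ids)
})
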