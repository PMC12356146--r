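test_that("invariant-SNP removal judges called genotypes only", {
  d <- toy_genotypes()
  out <- suppressMessages(drop_invariant_snps(d))
  expect_false("SNP_A" %in% names(out)) # all AA
  expect_true(all(c("SNP_B", "SNP_C", "SNP_D") %in% names(out)))
  # invariant among non-NC cells is removed too
  d2 <- d
  d2$SNP_C <- c("AA", "NC", "AA", "AA", "AA", "NC")
  out2 <- suppressMessages(drop_invariant_snps(d2))
  expect_false("SNP_C" %in% names(out2))
  d3 <- d[, c("Sample_ID", "Case_Control", "SNP_A")]
  expect_error(suppressMessages(drop_invariant_snps(d3)), "invariant")
})

test_that("No-Call filter removes strictly above the threshold", {
  # 10 samples: SNPs with 0, 1 (exactly 10%) and 2 (20%) NC cells
  d <- encoded_tbl(matrix(0, 10, 0), rep(c(1, 0), 5))
  d$SNP_0 <- rep(c("AA", "AB"), 5)
  d$SNP_1 <- c("NC", rep(c("AB", "BB"), length.out = 9))
  d$SNP_2 <- c("NC", "NC", rep(c("AA", "AB"), length.out = 8))
  out <- suppressMessages(drop_high_nocall_snps(d, threshold = 0.10))
  expect_setequal(snp_cols(out), c("SNP_0", "SNP_1"))
  expect_error(drop_high_nocall_snps(d, threshold = 1), "threshold")
})

test_that("mode imputation uses the modal genotype with AA < AB < BB ties", {
  d <- encoded_tbl(matrix(0, 4, 0), c(1, 1, 0, 0))
  d$SNP_mode <- c("AA", "AA", "AB", "NC")
  d$SNP_tie <- c("AA", "AB", "NC", "NC")
  d$SNP_clean <- c("AB", "AB", "BB", "AA")
  out <- impute_nocall_mode(d)
  expect_equal(out$SNP_mode[4], "AA")
  expect_equal(out$SNP_tie[3:4], c("AA", "AA")) # tie broken toward AA
  expect_identical(out$SNP_clean, d$SNP_clean)
  expect_false(any(as.matrix(out[, snp_cols(out)]) == "NC"))
})

test_that("mean encoding matches the case-proportion formula exactly", {
  d <- toy_genotypes()[, c("Sample_ID", "Case_Control", "SNP_B", "SNP_D")]
  map <- fit_mean_encoding(d)
  lv <- map$levels
  # SNP_B: AA carriers S1(Case), S5(Control) -> 1/2; AB S2,S3 (Case) -> 1;
  # BB S4(Case), S6(Control) -> 1/2
  expect_equal(lv$value[lv$SNP_ID == "SNP_B" & lv$genotype == "AA"], 1 / 2)
  expect_equal(lv$value[lv$SNP_ID == "SNP_B" & lv$genotype == "AB"], 1)
  expect_equal(lv$value[lv$SNP_ID == "SNP_B" & lv$genotype == "BB"], 1 / 2)
  expect_equal(map$fallback, 4 / 6)

  # brute-force counting oracle on a random panel
  sim <- generate_genotypes(sim_config(
    n_samples = 20, n_snps = 5, n_causal = 2, seed = 31
  ))
  m2 <- fit_mean_encoding(sim$data)
  y <- case_indicator(sim$data)
  for (i in seq_len(nrow(m2$levels))) {
    row <- m2$levels[i, ]
    carriers <- sim$data[[row$SNP_ID]] == row$genotype
    expect_equal(row$value, sum(y[carriers]) / sum(carriers))
  }
})

test_that("encoding conserves case counts per SNP", {
  sim <- generate_genotypes(sim_config(
    n_samples = 50, n_snps = 8, n_causal = 2, seed = 17
  ))
  d <- sim$data
  map <- fit_mean_encoding(d)
  y <- case_indicator(d)
  for (s in snp_cols(d)) {
    lv <- map$levels[map$levels$SNP_ID == s, ]
    counts <- table(factor(d[[s]], levels = lv$genotype))
    expect_equal(
      sum(lv$value * as.numeric(counts)), sum(y),
      tolerance = 1e-12
    )
  }
})

test_that("applying a map encodes consistently and falls back on unseen genotypes", {
  d <- toy_genotypes()[, c("Sample_ID", "Case_Control", "SNP_B", "SNP_D")]
  map <- fit_mean_encoding(d)
  enc <- apply_mean_encoding(map, d)
  m <- as.matrix(enc[, snp_cols(enc)])
  expect_true(all(m >= 0 & m <= 1))
  # cells sharing (SNP, genotype) share encoded values
  expect_equal(enc$SNP_B[1], enc$SNP_B[5])
  # unseen genotype -> fallback
  d2 <- d[1:2, ]
  d2$SNP_B <- c("BB", "BB")
  map2 <- fit_mean_encoding(dplyr::mutate(d, SNP_B = ifelse(
    SNP_B == "BB", "AA", SNP_B
  )))
  enc2 <- apply_mean_encoding(map2, d2)
  expect_equal(enc2$SNP_B, rep(map2$fallback, 2))
  # SNP absent from map
  d3 <- dplyr::rename(d, SNP_X = SNP_B)
  expect_error(apply_mean_encoding(map, d3), "SNP")
})

test_that("fold-fitted encodings are insensitive to held-out labels", {
  sim <- generate_genotypes(sim_config(
    n_samples = 40, n_snps = 6, n_causal = 2, seed = 23
  ))
  d <- sim$data
  train_ids <- d$Sample_ID[1:28]
  held <- d[29:40, ]
  map <- fit_mean_encoding(d, sample_ids = train_ids)
  enc1 <- apply_mean_encoding(map, held)
  # permute held-out labels; encoded values must not change
  set.seed(1)
  held2 <- held
  held2$Case_Control <- sample(held2$Case_Control)
  map2 <- fit_mean_encoding(
    dplyr::bind_rows(d[1:28, ], held2),
    sample_ids = train_ids
  )
  enc2 <- apply_mean_encoding(map2, held2)
  expect_equal(
    as.matrix(enc1[, snp_cols(enc1)]),
    as.matrix(enc2[, snp_cols(enc2)])
  )
})

test_that("fit_mean_encoding rejects unlabeled and single-class input", {
  d <- toy_genotypes()
  expect_error(
    fit_mean_encoding(dplyr::select(d, -Case_Control)),
    "Case_Control"
  )
  expect_error(fit_mean_encoding(d, sample_ids = paste0("S", 1:4)), "both")
  d_nc <- d[, c("Sample_ID", "Case_Control", "SNP_C")]
  expect_error(fit_mean_encoding(d_nc), "NC")
})

test_that("encoding map serializes to auditable YAML", {
  d <- toy_genotypes()[, c("Sample_ID", "Case_Control", "SNP_B")]
  map <- fit_mean_encoding(d)
  path <- withr::local_tempfile(fileext = ".yml")
  write_encoding_map(map, path)
  back <- yaml::read_yaml(path)
  expect_equal(back$fallback, map$fallback)
  expect_equal(length(back$levels), nrow(map$levels))
})
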