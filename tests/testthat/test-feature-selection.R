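test_that("amgm_ratio matches hand values and the AM-GM inequality", {
  expect_equal(amgm_ratio(c(2, 2, 2)), 1, tolerance = 1e-12)
  expect_equal(amgm_ratio(c(1, 2, 4)), (7 / 3) / 2, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:50) {
    x <- runif(sample(2:20, 1), min = 1e-4, max = 5)
    r <- amgm_ratio(x)
    expect_gte(r, 1 - 1e-12)
    if (diff(range(x)) > 1e-6) expect_gt(r, 1)
  }
  expect_error(amgm_ratio(c(1, 0)), "positive")
  expect_error(amgm_ratio(c(1, -2)), "positive")
})

test_that("AMGM ranking puts variable SNPs first and constants last", {
  X <- cbind(
    SNP_const = rep(0.5, 20),
    SNP_var = c(rep(0.05, 10), rep(0.95, 10)),
    SNP_mild = c(rep(0.4, 10), rep(0.6, 10))
  )
  d <- encoded_tbl(X, rep(c(1, 0), 10))
  r <- rank_by_amgm(d)
  expect_equal(r$SNP_ID, c("SNP_var", "SNP_mild", "SNP_const"))
  expect_equal(r$score[3], 1, tolerance = 1e-9)
  # permutation equivariance: column order must not matter
  r2 <- rank_by_amgm(d[, c("Sample_ID", "Case_Control", "SNP_mild", "SNP_const", "SNP_var")])
  expect_identical(r$SNP_ID, r2$SNP_ID)
})

test_that("cosine similarity matches hand computations", {
  expect_equal(cosine_similarity(c(3, 4), c(3, 4)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(1:3, 1:2), "length")
})

test_that("greedy cosine filter matches the brute-force rule and skips duplicates", {
  set.seed(12)
  X <- matrix(runif(30 * 9, 0.05, 0.95), 30, 9)
  X <- cbind(X, X[, 3]) # planted duplicate of column 3
  colnames(X) <- sprintf("SNP_%02d", 1:10)
  d <- encoded_tbl(X, rep(c(1, 0), 15))
  ranking <- rank_by_amgm(d)
  for (nf in c(3, 5, 9)) {
    sel <- cosine_redundancy_filter(d, ranking, n_final = nf, tau = 0.95)
    ref <- oracle_greedy_cosine(X, ranking$SNP_ID, nf, 0.95)
    expect_identical(sel$SNP_ID, ref)
  }
  # the duplicate pair can never both be kept in the greedy pass at tau close to 1
  sel9 <- cosine_redundancy_filter(d, ranking, n_final = 9, tau = 0.9999)
  first9 <- sel9$SNP_ID[1:8]
  expect_false(all(c("SNP_03", "SNP_10") %in% first9))
})

test_that("orthogonal features pass the cosine filter in pure rank order", {
  X <- diag(6) + 0 # orthogonal columns
  colnames(X) <- sprintf("SNP_%d", 1:6)
  d <- encoded_tbl(X, rep(c(1, 0), 3))
  ranking <- snpsieve:::new_feature_ranking(
    colnames(X), c(6, 5, 4, 3, 2, 1),
    method = "manual"
  )
  sel <- cosine_redundancy_filter(d, ranking, n_final = 4, tau = 0.95)
  expect_identical(sel$SNP_ID, ranking$SNP_ID[1:4])
})

test_that("ReliefF matches the brute-force reference and its invariances", {
  set.seed(77)
  X <- matrix(runif(12 * 5), 12, 5)
  X[, 2] <- rep(0.5, 12) # constant
  y <- rep(c(1, 0), 6)
  X[, 4] <- ifelse(y == 1, 0.9, 0.1) + runif(12, 0, 0.01) # separator
  colnames(X) <- paste0("SNP_", 1:5)
  d <- encoded_tbl(X, y)
  r <- relieff_weights(d, k_neighbors = 3)
  w <- stats::setNames(r$score, r$SNP_ID)[colnames(X)]
  ref <- oracle_relieff(X, y, k = 3)
  expect_equal(unname(w), unname(ref), tolerance = 1e-9)
  expect_equal(w[["SNP_2"]], 0) # constant feature
  expect_equal(r$SNP_ID[1], "SNP_4") # separator wins
  # scaling invariance (range normalization)
  X2 <- X
  X2[, 1] <- X2[, 1] * 10
  r2 <- relieff_weights(encoded_tbl(X2, y), k_neighbors = 3)
  expect_equal(r$score, r2$score, tolerance = 1e-9)
  expect_error(relieff_weights(d, k_neighbors = 6), "smaller")
})

test_that("CMIM matches exhaustive evaluation and shuns duplicated features", {
  set.seed(41)
  n <- 40
  df <- tibble::tibble(
    F1 = sample(c("AA", "AB", "BB"), n, TRUE),
    F2 = sample(c("AA", "AB"), n, TRUE),
    F3 = sample(c("AA", "AB", "BB"), n, TRUE),
    F4 = sample(c("AA", "BB"), n, TRUE),
    F5 = sample(c("AA", "AB", "BB"), n, TRUE)
  )
  df$F6 <- df$F1 # exact duplicate
  y <- ifelse(df$F1 == "AA" | df$F4 == "BB", "Case", "Control")
  if (length(unique(y)) < 2) y[1] <- "Control"
  d <- dplyr::bind_cols(
    tibble::tibble(Sample_ID = paste0("S", 1:n), Case_Control = y), df
  )
  sel <- cmim_select(d, n_select = 4)
  ref <- oracle_cmim(df, y, 4)
  expect_identical(sel$SNP_ID, ref)
  # duplicate of the first pick contributes nothing and is never selected
  # while informative alternatives remain
  first <- sel$SNP_ID[1]
  dup <- c(F1 = "F6", F6 = "F1")[first]
  if (!is.na(dup)) expect_false(dup %in% sel$SNP_ID)
  expect_warning(cmim_select(d, n_select = 10), "pool")
})

test_that("univariate rankings match textbook formulas", {
  # 3x2 table ((10,0),(0,10),(5,5))
  g <- c(rep("AA", 10), rep("AB", 10), rep("BB", 10))
  y <- c(rep("Case", 10), rep("Control", 10), rep(c("Case", "Control"), 5))
  d <- tibble::tibble(
    Sample_ID = paste0("S", 1:30), Case_Control = y, SNP_1 = g
  )
  r <- univariate_ranking(d, "chi_squared")
  # hand computation: expected 5 per cell in rows 1-2, 5/5 in row 3
  expected <- 15 * 10 / 30
  stat <- 2 * (10 - 5)^2 / 5 + 2 * (0 - 5)^2 / 5 + 0
  expect_equal(r$score, stat)
  # MI of a perfectly class-determined SNP equals H(Y)
  d2 <- d[1:20, ]
  r2 <- univariate_ranking(d2, "mutual_information")
  expect_equal(r2$score, 1) # H(Y) = 1 bit at 10/10 split
  expect_equal(r2$score, oracle_mi(d2$SNP_1, d2$Case_Control))
})

test_that("chi-squared on label-independent SNPs stays near its df expectation", {
  sim <- generate_genotypes(sim_config(
    n_samples = 800, n_snps = 30, n_causal = 0, causal_effect = 1, seed = 3
  ))
  r <- univariate_ranking(sim$data, "chi_squared")
  # E[chi2] = df (about 2 per SNP); the mean over 30 null SNPs should be close
  expect_lt(mean(r$score), 4)
})

test_that("SVM-RFE keeps a perfectly separating feature to the end", {
  set.seed(6)
  n <- 50
  X <- matrix(runif(n * 20), n, 20)
  y <- rep(c(1, 0), 25)
  X[, 7] <- ifelse(y == 1, 0.95, 0.05)
  colnames(X) <- sprintf("SNP_%02d", 1:20)
  d <- encoded_tbl(X, y)
  sel <- svm_rfe_select(d, n_select = 3)
  expect_equal(nrow(sel), 3)
  expect_true("SNP_07" %in% sel$SNP_ID)
  # no-op bound: n_select = n_features
  sel_all <- svm_rfe_select(d, n_select = 20)
  expect_setequal(sel_all$SNP_ID, colnames(X))
  expect_length(attr(sel_all, "provenance")$elimination_order, 0)
  # determinism
  sel2 <- svm_rfe_select(d, n_select = 3)
  expect_identical(sel$SNP_ID, sel2$SNP_ID)
})

test_that("the CMIM + SVM-RFE hybrid degenerates to its stages at the bounds", {
  sim <- generate_genotypes(sim_config(
    n_samples = 60, n_snps = 12, n_causal = 3, causal_effect = 6, seed = 9
  ))
  d <- sim$data
  enc <- mean_encode(d)
  h1 <- hybrid_cmim_svmrfe(d, enc, n_intermediate = 12, n_select = 12)
  c1 <- cmim_select(d, 12)
  expect_setequal(h1$SNP_ID, c1$SNP_ID)
  h2 <- hybrid_cmim_svmrfe(d, enc, n_intermediate = 12, n_select = 5)
  s2 <- svm_rfe_select(enc, n_select = 5)
  expect_setequal(h2$SNP_ID, s2$SNP_ID)
  expect_error(hybrid_cmim_svmrfe(d, enc, 5, 10), "n_select")
})

test_that("autoencoder-L1 ranking is seeded and sinks constant features", {
  set.seed(10)
  X <- matrix(runif(40 * 8, 0.1, 0.9), 40, 8)
  X[, 5] <- 0.5
  colnames(X) <- paste0("SNP_", 1:8)
  d <- encoded_tbl(X, rep(c(1, 0), 20))
  r1 <- autoencoder_l1_ranking(d, bottleneck = 2, epochs = 20, seed = 3)
  r2 <- autoencoder_l1_ranking(d, bottleneck = 2, epochs = 20, seed = 3)
  expect_identical(r1, r2)
  expect_equal(r1$SNP_ID[8], "SNP_5")
  expect_equal(r1$score[8], 0)
})

test_that("autoencoder-L1 ranking surfaces factor-linked features over noise", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 60
    f1 <- runif(n)
    f2 <- runif(n)
    X <- cbind(
      f1 + rnorm(n, 0, 0.02), f1 + rnorm(n, 0, 0.02),
      f2 + rnorm(n, 0, 0.02), f2 + rnorm(n, 0, 0.02),
      f1 + rnorm(n, 0, 0.02),
      matrix(rnorm(n * 15, sd = 0.25), n, 15)
    )
    colnames(X) <- sprintf("SNP_%02d", 1:20)
    d <- encoded_tbl(X, rep(c(1, 0), n / 2))
    r <- autoencoder_l1_ranking(d,
      bottleneck = 2, l1_lambda = 5e-3,
      epochs = 150, learning_rate = 1e-2, seed = s
    )
    if (all(r$SNP_ID[1:3] %in% sprintf("SNP_%02d", 1:5))) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("the dispatcher honors panel sizes, determinism and unknown methods", {
  sim <- generate_genotypes(sim_config(
    n_samples = 60, n_snps = 15, n_causal = 3, causal_effect = 4, seed = 19
  ))
  d <- sim$data
  expect_error(select_features(d, "pca"), "unknown feature-selection method")
  for (m in c("amgm_cosine", "relieff", "chi_squared", "mutual_information")) {
    s1 <- suppressWarnings(select_features(d, m, n_select = 5, n_intermediate = 10, seed = 2))
    s2 <- suppressWarnings(select_features(d, m, n_select = 5, n_intermediate = 10, seed = 2))
    expect_equal(nrow(s1), 5)
    expect_identical(s1$SNP_ID, s2$SNP_ID)
  }
  expect_warning(
    sel <- select_features(d, "chi_squared", n_select = 99),
    "pool"
  )
  expect_equal(nrow(sel), 15)
})
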