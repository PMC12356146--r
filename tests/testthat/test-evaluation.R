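test_that("stratified folds partition samples with balanced classes", {
  y <- rep(c("Case", "Control"), each = 5)
  folds <- stratified_kfold(y, k = 5, seed = 1)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f, 2)
    expect_setequal(y[f], c("Case", "Control"))
  }
  expect_setequal(unlist(folds), seq_along(y))
  expect_equal(sum(lengths(folds)), length(y)) # disjoint + exhaustive

  # 103 samples, imbalanced
  set.seed(2)
  y2 <- sample(rep(c("Case", "Control"), c(40, 63)))
  folds2 <- stratified_kfold(y2, k = 5, seed = 3)
  expect_true(all(lengths(folds2) %in% c(20, 21)))
  expect_equal(sum(lengths(folds2)), 103)
  expect_setequal(unlist(folds2), seq_along(y2))
  case_counts <- vapply(folds2, function(f) sum(y2[f] == "Case"), numeric(1))
  expect_lte(diff(range(case_counts)), 1)

  expect_error(stratified_kfold(c("Case", rep("Control", 9)), k = 5), "smaller k")
})

test_that("confusion counts match a brute-force tally", {
  set.seed(5)
  y_true <- sample(c("Case", "Control"), 10, TRUE)
  y_pred <- sample(c("Case", "Control"), 10, TRUE)
  cc <- confusion_counts(y_true, y_pred)
  ref <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in 1:10) {
    key <- if (y_true[i] == "Case" && y_pred[i] == "Case") "TP"
    else if (y_true[i] == "Control" && y_pred[i] == "Case") "FP"
    else if (y_true[i] == "Control" && y_pred[i] == "Control") "TN"
    else "FN"
    ref[key] <- ref[key] + 1
  }
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]), ref)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 10)
  cc2 <- confusion_counts(y_true, y_true)
  expect_equal(cc2$FP + cc2$FN, 0)
  expect_error(confusion_counts(y_true, y_pred[1:5]), "length")
})

test_that("the four metrics match their formulas and flag degenerate cells", {
  m <- classification_metrics(list(TP = 4, FP = 1, TN = 3, FN = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$f1, 8 / 11)
  expect_true(is.na(m$degenerate))

  perfect <- classification_metrics(list(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(
    unlist(perfect[c("accuracy", "sensitivity", "specificity", "f1")]),
    c(accuracy = 1, sensitivity = 1, specificity = 1, f1 = 1)
  )

  degen <- classification_metrics(list(TP = 0, FP = 0, TN = 6, FN = 0))
  expect_equal(degen$sensitivity, 0)
  expect_match(degen$degenerate, "sensitivity")

  # identity: accuracy = (sens*P + spec*N) / (P + N)
  set.seed(11)
  for (i in 1:20) {
    cc <- list(
      TP = rpois(1, 5), FP = rpois(1, 3),
      TN = rpois(1, 5), FN = rpois(1, 3)
    )
    if (cc$TP + cc$FP + cc$TN + cc$FN == 0) next
    m <- classification_metrics(cc)
    P <- cc$TP + cc$FN
    N <- cc$TN + cc$FP
    sens <- if (P == 0) 0 else cc$TP / P
    spec <- if (N == 0) 0 else cc$TN / N
    expect_equal(m$accuracy, (sens * P + spec * N) / (P + N), tolerance = 1e-12)
  }
})

test_that("cross_validate tests each sample exactly once and is deterministic", {
  sim <- generate_genotypes(sim_config(
    n_samples = 50, n_snps = 12, n_causal = 3, causal_effect = 6, seed = 13
  ))
  spec <- model_spec("fnn",
    epochs = 15, neurons_1 = 8, neurons_2 = 4,
    batch_size = 16, learning_rate = 0.02, seed = 4
  )
  r1 <- cross_validate(sim$data,
    fs_method = "chi_squared", n_select = 5,
    spec = spec, k = 5, seed = 2
  )
  r2 <- cross_validate(sim$data,
    fs_method = "chi_squared", n_select = 5,
    spec = spec, k = 5, seed = 2
  )
  expect_identical(r1$folds, r2$folds)
  expect_equal(nrow(r1$folds), 5)
  expect_equal(sum(r1$folds$TP + r1$folds$FP + r1$folds$TN + r1$folds$FN), 50)
  # fold-averaged metrics are plain means
  expect_equal(r1$summary$accuracy, mean(r1$folds$accuracy), tolerance = 1e-12)
  expect_equal(r1$summary$f1, mean(r1$folds$f1), tolerance = 1e-12)
  g <- glance(r1)
  expect_equal(g$model, "fnn")
  expect_equal(g$accuracy, r1$summary$accuracy)
  expect_equal(nrow(tidy(r1)), 5)
})

test_that("strong planted signal yields above-majority CV accuracy", {
  sim <- generate_genotypes(sim_config(
    n_samples = 200, n_snps = 30, n_causal = 5, causal_effect = 6,
    case_fraction = 0.5, seed = 42
  ))
  spec <- model_spec("fnn",
    epochs = 40, neurons_1 = 16, neurons_2 = 8,
    batch_size = 32, learning_rate = 0.02, dropout_rate = 0.1, seed = 5
  )
  r <- suppressWarnings(cross_validate(sim$data,
    fs_method = "amgm_cosine", n_select = 10,
    n_intermediate = 30, spec = spec, k = 5, seed = 3
  ))
  maj <- max(mean(sim$data$Case_Control == "Case"),
             mean(sim$data$Case_Control == "Control"))
  expect_gt(r$summary$accuracy, maj + 0.08)
})

test_that("summarize_heatmap yields one row per cell and metric, and plots", {
  sim <- generate_genotypes(sim_config(
    n_samples = 40, n_snps = 8, n_causal = 2, causal_effect = 4, seed = 8
  ))
  spec <- model_spec("fnn",
    epochs = 5, neurons_1 = 4, neurons_2 = 2,
    batch_size = 16, seed = 1
  )
  reports <- list(
    a = cross_validate(sim$data, "chi_squared", 4, spec, k = 4, seed = 1),
    b = cross_validate(sim$data, "mutual_information", 4, spec, k = 4, seed = 1)
  )
  tab <- summarize_heatmap(reports)
  expect_s3_class(tab, "cv_summary")
  expect_equal(nrow(tab), 2 * 4) # 2 reports x 4 metrics
  expect_setequal(
    unique(tab$metric),
    c("accuracy", "sensitivity", "specificity", "f1")
  )
  # best-cell lookup matches brute-force max over inputs
  acc <- tab[tab$metric == "accuracy", ]
  expect_equal(
    max(acc$value),
    max(vapply(reports, function(r) r$summary$accuracy, numeric(1)))
  )
  # lossless round-trip through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(tab), path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$value, tab$value)
  p <- autoplot(tab)
  expect_s3_class(p, "ggplot")
  expect_error(summarize_heatmap(list()), "at least one")
})
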