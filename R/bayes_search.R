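#' Sequential model-based hyperparameter search
#'
#' Bayesian-style hyperparameter optimization for one architecture:
#' an initial batch of randomly sampled configurations is scored by mean
#' inner 3-fold stratified cross-validated accuracy on the supplied data,
#' then a random-forest surrogate fitted to the trial log proposes each next
#' configuration by maximizing an upper-confidence acquisition (surrogate
#' mean + one between-tree standard deviation) over a random candidate pool.
#' The full trial log is retained.
#'
#' @param data Labeled encoded tibble (the training fold when used inside
#'   an outer CV).
#' @param architecture Architecture name (see [model_spec()]).
#' @param space Named list of parameter ranges, each a length-2 numeric
#'   `c(lo, hi)`. Supported names: `learning_rate` (searched on a log
#'   scale), `dropout_rate`, `epochs`, `batch_size`, `neurons_1`,
#'   `neurons_2`, `units`, `filter_size`, `bottleneck`. Integer-valued
#'   parameters are rounded.
#' @param budget Total number of configurations evaluated (>= 1).
#' @param seed Integer seed; (data, space, budget, seed) determine the
#'   result.
#' @param inner_k Inner CV folds (default 3).
#' @return A `model_spec` for the best configuration found, with the trial
#'   log as attribute `"trials"` (tibble: parameters + `accuracy`).
#' @export
bayesian_search <- function(data, architecture,
                            space = list(
                              learning_rate = c(1e-4, 1e-1),
                              dropout_rate = c(0, 0.5)
                            ),
                            budget = 10, seed = 1, inner_k = 3) {
  budget <- check_count(budget, "budget")
  int_params <- c(
    "epochs", "batch_size", "neurons_1", "neurons_2", "units",
    "filter_size", "bottleneck"
  )
  for (nm in names(space)) {
    rg <- space[[nm]]
    if (!is.numeric(rg) || length(rg) != 2 || rg[1] > rg[2]) {
      abort(sprintf("space entry '%s' must be a numeric c(lo, hi).", nm))
    }
  }
  y <- case_indicator(data)

  sample_point <- function() {
    vals <- lapply(names(space), function(nm) {
      rg <- space[[nm]]
      v <- if (nm == "learning_rate") {
        exp(stats::runif(1, log(rg[1]), log(rg[2])))
      } else {
        stats::runif(1, rg[1], rg[2])
      }
      if (nm %in% int_params) v <- round(v)
      v
    })
    stats::setNames(vals, names(space))
  }
  eval_point <- function(point, trial_seed) {
    spec <- do.call(model_spec, c(
      list(architecture = architecture, seed = trial_seed), point
    ))
    folds <- stratified_kfold(data$Case_Control, k = inner_k, seed = trial_seed)
    accs <- vapply(folds, function(test_idx) {
      train <- data[-test_idx, , drop = FALSE]
      test <- data[test_idx, , drop = FALSE]
      fit <- train_classifier(train, spec)
      pred <- predict(fit, test)
      mean(pred$.pred == test$Case_Control)
    }, numeric(1))
    mean(accs)
  }

  with_rng(seed, {
    n_init <- max(min(budget, 4), ceiling(budget / 3))
    trials <- list()
    scores <- numeric(0)
    for (i in seq_len(budget)) {
      if (i <= n_init || length(scores) < 3) {
        point <- sample_point()
      } else {
        log_ <- dplyr::bind_rows(lapply(trials, as_tibble))
        xtr <- as.data.frame(log_)
        if ("learning_rate" %in% names(xtr)) {
          xtr$learning_rate <- log(xtr$learning_rate)
        }
        # small trial logs trip randomForest's few-unique-responses warning
        rf <- suppressWarnings(
          randomForest::randomForest(xtr, scores, ntree = 100)
        )
        cands <- dplyr::bind_rows(lapply(seq_len(64), function(j) {
          as_tibble(sample_point())
        }))
        xc <- as.data.frame(cands)
        if ("learning_rate" %in% names(xc)) {
          xc$learning_rate <- log(xc$learning_rate)
        }
        pred_all <- stats::predict(rf, xc, predict.all = TRUE)
        mu <- pred_all$aggregate
        sd_ <- apply(pred_all$individual, 1, stats::sd)
        point <- as.list(cands[which.max(mu + sd_), ])
      }
      trials[[i]] <- point
      scores[i] <- eval_point(point, trial_seed = seed + i)
    }
    best <- which.max(scores)
    spec <- do.call(model_spec, c(
      list(architecture = architecture, seed = seed + best), trials[[best]]
    ))
    log_tbl <- dplyr::bind_cols(
      dplyr::bind_rows(lapply(trials, as_tibble)),
      tibble(accuracy = scores)
    )
    attr(spec, "trials") <- log_tbl
    spec
  })
}
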