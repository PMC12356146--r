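#' Stratified k-fold test-index sets
#'
#' Partitions the samples into `k` folds whose sizes differ by at most one
#' and whose per-class counts differ by at most one across folds, after a
#' seeded shuffle within each class.
#'
#' @param y Vector of class labels (one per sample).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the within-class shuffle.
#' @return List of `k` integer vectors of test indices (a partition of
#'   `seq_along(y)`).
#' @export
stratified_kfold <- function(y, k = 5, seed = 1) {
  k <- check_count(k, "k", min = 2)
  tab <- table(y)
  if (any(tab < k)) {
    abort(sprintf(
      "class '%s' has only %d sample(s), fewer than k = %d; use a smaller k.",
      names(tab)[which.min(tab)], min(tab), k
    ))
  }
  with_rng(seed, {
    folds <- vector("list", k)
    for (cl in names(tab)) {
      idx <- sample(which(y == cl))
      assign_ <- rep(seq_len(k), length.out = length(idx))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[assign_ == f])
      }
    }
    lapply(folds, sort)
  })
}

#' Confusion counts with Case as the positive class
#'
#' @param y_true,y_pred Character vectors of "Case"/"Control", equal length.
#' @return A `confusion_counts` list: `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length.")
  }
  structure(
    list(
      TP = sum(y_true == "Case" & y_pred == "Case"),
      FP = sum(y_true == "Control" & y_pred == "Case"),
      TN = sum(y_true == "Control" & y_pred == "Control"),
      FN = sum(y_true == "Case" & y_pred == "Control")
    ),
    class = "confusion_counts"
  )
}

#' The four classification metrics
#'
#' Accuracy, sensitivity (Case recall), specificity (Control recall) and F1
#' from confusion counts. A metric whose denominator is zero (e.g.
#' sensitivity on a fold with no true Cases) is reported as 0 and flagged in
#' the `degenerate` field rather than raised as an error — folds dominated
#' by a single class are a real failure mode worth reporting, not crashing
#' on.
#'
#' @param c A `confusion_counts` (or list with TP/FP/TN/FN).
#' @return A tibble row: `accuracy`, `sensitivity`, `specificity`, `f1`,
#'   `degenerate` (comma-separated names of zero-denominator metrics, or
#'   `NA`).
#' @export
classification_metrics <- function(c) {
  tot <- c$TP + c$FP + c$TN + c$FN
  if (tot == 0) abort("confusion counts sum to zero.")
  safe <- function(num, den) if (den == 0) 0 else num / den
  degen <- c(
    if (c$TP + c$FN == 0) "sensitivity",
    if (c$TN + c$FP == 0) "specificity",
    if (2 * c$TP + c$FP + c$FN == 0) "f1"
  )
  tibble(
    accuracy = (c$TP + c$TN) / tot,
    sensitivity = safe(c$TP, c$TP + c$FN),
    specificity = safe(c$TN, c$TN + c$FP),
    f1 = safe(2 * c$TP, 2 * c$TP + c$FP + c$FN),
    degenerate = if (length(degen) > 0) paste(degen, collapse = ",") else NA_character_
  )
}

#' Cross-validate the full pipeline on a labeled genotype panel
#'
#' Stratified k-fold cross-validation of encode -> select -> train ->
#' predict. In the default leakage-safe mode (`encoding = "fold_safe"`)
#' the mean-encoding map and the feature selection are fitted on each
#' training fold only, and test samples are encoded with the training
#' fold's map — no test label can influence any fitted quantity. The
#' `"global"` mode instead fits encoding and selection once on the full
#' dataset before splitting, the way a whole-dataset analysis would; it is
#' provided deliberately so the optimistic bias of that practice can be
#' measured (compare the two modes on a null panel).
#'
#' @param data Labeled, NC-free genotype tibble (character genotypes).
#' @param fs_method Feature-selection method (see [select_features()]), or
#'   `"none"` to use all SNPs.
#' @param n_select Panel size passed to the selector.
#' @param spec A [model_spec()] for the classifier.
#' @param encoding `"fold_safe"` (default) or `"global"`.
#' @param k Number of folds (default 5).
#' @param seed Seed for fold assignment (the model's own seed lives in
#'   `spec`).
#' @param ... Passed on to [select_features()].
#' @return A `cv_report`: list with `folds` (per-fold counts + metrics
#'   tibble), `summary` (fold-averaged metrics), and `provenance`.
#' @export
cross_validate <- function(data, fs_method = "amgm_cosine", n_select = 100,
                           spec = model_spec("fnn"),
                           encoding = c("fold_safe", "global"),
                           k = 5, seed = 1, ...) {
  encoding <- rlang::arg_match(encoding)
  check_labeled(data)
  folds <- stratified_kfold(data$Case_Control, k = k, seed = seed)

  if (encoding == "global") {
    map_all <- fit_mean_encoding(data)
    enc_all <- apply_mean_encoding(map_all, data)
    sel_all <- if (fs_method == "none") {
      NULL
    } else {
      select_features(data, fs_method,
        n_select = n_select, encoded = enc_all,
        seed = seed, ...
      )
    }
  }

  fold_rows <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    res <- tryCatch(
      {
        test_idx <- folds[[f]]
        train <- data[-test_idx, , drop = FALSE]
        test <- data[test_idx, , drop = FALSE]
        if (encoding == "fold_safe") {
          map <- fit_mean_encoding(train)
          enc_train <- apply_mean_encoding(map, train)
          enc_test <- apply_mean_encoding(map, test)
          sel <- if (fs_method == "none") {
            NULL
          } else {
            select_features(train, fs_method,
              n_select = n_select,
              encoded = enc_train, seed = seed, ...
            )
          }
        } else {
          enc_train <- apply_mean_encoding(map_all, train)
          enc_test <- apply_mean_encoding(map_all, test)
          sel <- sel_all
        }
        keep <- if (is.null(sel)) {
          snp_cols(data)
        } else {
          sel$SNP_ID
        }
        cols <- c("Sample_ID", "Case_Control", keep)
        fit <- train_classifier(enc_train[, cols], spec)
        pred <- predict(fit, enc_test[, cols])
        cc <- confusion_counts(test$Case_Control, pred$.pred)
        dplyr::bind_cols(
          tibble(fold = f, TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN),
          classification_metrics(cc)
        )
      },
      error = function(e) {
        abort(sprintf("cross-validation failed in fold %d: %s", f, conditionMessage(e)))
      }
    )
    fold_rows[[f]] <- res
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  metrics <- c("accuracy", "sensitivity", "specificity", "f1")
  summary <- dplyr::summarise(
    folds_tbl,
    dplyr::across(dplyr::all_of(metrics), mean)
  )
  structure(
    list(
      folds = folds_tbl,
      summary = summary,
      provenance = list(
        fs_method = fs_method, n_select = n_select, spec = unclass(spec),
        encoding = encoding, k = k, seed = seed,
        n_samples = nrow(data), n_snps = length(snp_cols(data))
      )
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<cv_report> %s + %s (%s encoding, %d folds)\n",
    p$fs_method, p$spec$architecture, p$encoding, p$k
  ))
  s <- x$summary
  cat(sprintf(
    "  accuracy %.3f | sensitivity %.3f | specificity %.3f | F1 %.3f\n",
    s$accuracy, s$sensitivity, s$specificity, s$f1
  ))
  invisible(x)
}

#' Tidy and summarize pipeline results
#'
#' `tidy()` on a `cv_report` returns the per-fold confusion counts and
#' metrics; `glance()` returns one row of fold-averaged metrics plus
#' pipeline provenance. `tidy()`/`glance()` on a `trained_model` return the
#' training-loss history and a one-row fit summary.
#'
#' @param x A `cv_report` or `trained_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  x$folds
}

#' @rdname tidy.cv_report
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  p <- x$provenance
  dplyr::bind_cols(
    tibble(
      fs_method = p$fs_method, n_select = p$n_select,
      model = p$spec$architecture, encoding = p$encoding, k = p$k
    ),
    x$summary
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
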