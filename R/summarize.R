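#' Summarize a collection of CV reports as a long results table
#'
#' Condenses many (dataset, FS method, panel size, model) cells into one
#' long-format table with one row per cell and metric — the tabular form
#' behind a results heatmap. Plot it with [autoplot()] / [plot_heatmap()].
#'
#' @param reports A list of `cv_report` objects (optionally named; names
#'   become the `dataset` column when the reports carry none).
#' @param dataset Optional character vector of dataset names, recycled
#'   against `reports`.
#' @return A `cv_summary` tibble: `dataset`, `fs_method`, `n_select`,
#'   `model`, `encoding`, `metric`, `value`.
#' @export
summarize_heatmap <- function(reports, dataset = NULL) {
  if (inherits(reports, "cv_report")) reports <- list(reports)
  if (length(reports) == 0) abort("`reports` must contain at least one cv_report.")
  if (!all(vapply(reports, inherits, logical(1), "cv_report"))) {
    abort("every element of `reports` must be a cv_report.")
  }
  ds <- dataset %||% names(reports) %||% rep("dataset", length(reports))
  if (length(ds) == 0) ds <- rep("dataset", length(reports))
  ds <- rep_len(ds, length(reports))
  rows <- purrr::map2(reports, ds, function(r, d) {
    g <- glance(r)
    dplyr::bind_cols(tibble(dataset = d), g)
  })
  long <- dplyr::bind_rows(rows) |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(c("accuracy", "sensitivity", "specificity", "f1")),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::select(
      dplyr::all_of(c(
        "dataset", "fs_method", "n_select", "model", "encoding",
        "metric", "value"
      ))
    )
  structure(long, class = c("cv_summary", class(tibble())))
}

#' Heatmap of fold-averaged metrics
#'
#' One tile per (dataset x FS method, model) cell, faceted by metric.
#'
#' @param object A `cv_summary` from [summarize_heatmap()].
#' @param metric Metrics to plot (default: all present).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_summary
#' @export
autoplot.cv_summary <- function(object, metric = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(metric)) df <- df[df$metric %in% metric, ]
  df$cell <- paste(df$dataset, df$fs_method, df$n_select, sep = " / ")
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$model, y = .data$cell, fill = .data$value)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data$value)),
      size = 3
    ) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_gradient(
      low = "#fff5eb", high = "#d94801", limits = c(0, 1)
    ) +
    ggplot2::labs(x = "model", y = NULL, fill = "mean") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.cv_summary
#' @export
plot_heatmap <- function(object, metric = NULL, ...) {
  autoplot.cv_summary(object, metric = metric, ...)
}

#' Training-curve plot for a trained model
#'
#' @param object A `trained_model`.
#' @param ... Unused.
#' @return A ggplot object of training loss per epoch.
#' @method autoplot trained_model
#' @export
autoplot.trained_model <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$epoch, y = .data$loss)
  ) +
    ggplot2::geom_line(color = "#2171b5") +
    ggplot2::labs(
      x = "epoch", y = "training loss",
      title = object$spec$architecture
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
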