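CONFIG_KEYS <- c("dataset", "preprocessing", "selection", "models", "cv", "output_dir")

#' Read and validate an experiment configuration
#'
#' An experiment config is a YAML file that fully captures one run of the
#' pipeline; re-running the same config reproduces the same results.
#' Top-level keys (unknown keys are rejected):
#'
#' * `dataset`: either `genotype_csv` + `phenotype_csv` paths, or a
#'   `simulate` block with [sim_config()] fields.
#' * `preprocessing`: `nc_threshold` (default 0.1), `encoding`
#'   ("fold_safe"/"global").
#' * `selection`: `methods` (character vector), `n_select` (integer vector,
#'   e.g. 100/1000/1500), optional `n_intermediate`, `tau`.
#' * `models`: list of [model_spec()] field blocks (each must name an
#'   `architecture`).
#' * `cv`: `k` (default 5), `seed` (default 1).
#' * `output_dir`: where results are written.
#'
#' @param path Path to the YAML config.
#' @return A validated `experiment_config` list.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  validate_experiment_config(raw)
}

#' @rdname read_experiment_config
#' @param config A named list with the structure above (as from
#'   [yaml::read_yaml()]).
#' @export
validate_experiment_config <- function(config) {
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown config key(s): %s (allowed: %s)",
      paste(unknown, collapse = ", "), paste(CONFIG_KEYS, collapse = ", ")
    ))
  }
  ds <- config$dataset
  if (is.null(ds) ||
    (is.null(ds$simulate) && (is.null(ds$genotype_csv) || is.null(ds$phenotype_csv)))) {
    abort("config must provide dataset$simulate or dataset$genotype_csv + dataset$phenotype_csv.")
  }
  if (!is.null(ds$simulate)) {
    config$dataset$simulate <- do.call(sim_config, ds$simulate)
  }
  pp <- config$preprocessing %||% list()
  pp$nc_threshold <- pp$nc_threshold %||% 0.1
  pp$encoding <- pp$encoding %||% "fold_safe"
  if (!pp$encoding %in% c("fold_safe", "global")) {
    abort("preprocessing$encoding must be 'fold_safe' or 'global'.")
  }
  config$preprocessing <- pp
  sel <- config$selection %||% list()
  sel$methods <- sel$methods %||% "amgm_cosine"
  bad <- setdiff(sel$methods, c(FS_METHODS, "none"))
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown feature-selection method(s) in config: %s (options: %s)",
      paste(bad, collapse = ", "), paste(FS_METHODS, collapse = ", ")
    ))
  }
  sel$n_select <- as.integer(sel$n_select %||% 100)
  config$selection <- sel
  if (is.null(config$models)) {
    config$models <- list(list(architecture = "fnn"))
  }
  config$models <- lapply(config$models, function(m) {
    if (is.null(m$architecture)) abort("every models[] entry needs an architecture.")
    do.call(model_spec, m)
  })
  cv <- config$cv %||% list()
  cv$k <- as.integer(cv$k %||% 5)
  cv$seed <- as.integer(cv$seed %||% 1)
  config$cv <- cv
  config$output_dir <- config$output_dir %||% "snpsieve_results"
  structure(config, class = "experiment_config")
}

#' Run a full experiment from a configuration
#'
#' Executes simulate (if requested) -> ingest/merge -> clean -> the
#' (FS method x panel size x model) evaluation grid -> summary table, and
#' writes everything under the config's output directory: the processed
#' dataset (`processed.csv`), each selection (`selection_*.csv` + sidecar),
#' the long results table (`results.csv`), a heatmap (`heatmap_<metric>.png`
#' per metric), and a run log (`run.yml`) recording the config hash, seeds
#' and package version.
#'
#' @param config An `experiment_config`, or a path to a YAML config file.
#' @param write_plots Whether to write heatmap PNGs (default TRUE).
#' @return The output directory path, invisibly; the summary table is
#'   attached as attribute `"summary"`.
#' @export
run_experiment <- function(config, write_plots = TRUE) {
  if (is.character(config)) config <- read_experiment_config(config)
  if (!inherits(config, "experiment_config")) {
    config <- validate_experiment_config(config)
  }
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  ds <- config$dataset
  if (!is.null(ds$simulate)) {
    sim <- generate_genotypes(ds$simulate)
    data <- sim$data
    write_geo_style_csvs(data, file.path(out_dir, "simulated"), sim$truth)
  } else {
    geno <- read_genotype_csv(ds$genotype_csv)
    pheno <- read_phenotype_csv(ds$phenotype_csv)
    data <- merge_case_control(geno, pheno)
  }

  data <- preprocess_genotypes(data, nc_threshold = config$preprocessing$nc_threshold)
  write_processed_csv(data, file.path(out_dir, "processed.csv"))

  reports <- list()
  for (method in config$selection$methods) {
    for (n_sel in config$selection$n_select) {
      if (method != "none") {
        sel <- select_features(data, method,
          n_select = n_sel,
          seed = config$cv$seed
        )
        write_selection(sel, file.path(
          out_dir, sprintf("selection_%s_%d.csv", method, n_sel)
        ))
      }
      for (spec in config$models) {
        rep_ <- cross_validate(data,
          fs_method = method, n_select = n_sel, spec = spec,
          encoding = config$preprocessing$encoding,
          k = config$cv$k, seed = config$cv$seed
        )
        reports[[length(reports) + 1]] <- rep_
      }
    }
  }
  summary <- summarize_heatmap(reports, dataset = basename(out_dir))
  readr::write_csv(as_tibble(summary), file.path(out_dir, "results.csv"))
  if (write_plots) {
    for (m in unique(summary$metric)) {
      p <- autoplot.cv_summary(summary, metric = m)
      ggplot2::ggsave(
        file.path(out_dir, sprintf("heatmap_%s.png", m)), p,
        width = 7, height = 5, dpi = 120
      )
    }
  }
  yaml::write_yaml(
    list(
      config_hash = rlang::hash(unclass(config)),
      package_version = as.character(utils::packageVersion("snpsieve")),
      seed = config$cv$seed,
      n_reports = length(reports),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    file.path(out_dir, "run.yml")
  )
  structure(invisible(out_dir), summary = summary)
}
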