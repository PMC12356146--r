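#' Read a GEO-style genotype CSV
#'
#' Reads a genotype table with one row per SNP: first column the SNP
#' identifier, remaining columns one per sample, cells in AA/AB/BB/NC.
#' Cell strings are normalized case-insensitively; `"NC"`, `"No Call"`,
#' `"NoCall"`, `"-"` and empty cells all map to `NC`. Anything else is a
#' format error naming the offending SNP and sample — readers reject
#' silently-corrupting inputs rather than coercing them.
#'
#' @param path Path to the genotype CSV.
#' @return An unlabeled tibble in file orientation: `SNP_ID` plus one
#'   character column per sample.
#' @export
read_genotype_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("genotype file '%s' does not exist", path))
  }
  tab <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(tab) < 2) {
    abort("genotype CSV must have a SNP id column plus >= 1 sample column.")
  }
  names(tab)[1] <- "SNP_ID"
  tab$SNP_ID <- trimws(tab$SNP_ID)
  dup <- tab$SNP_ID[duplicated(tab$SNP_ID)]
  if (length(dup) > 0) {
    abort(sprintf(
      "duplicate SNP id(s) in '%s': %s", path,
      paste(utils::head(unique(dup), 5), collapse = ", ")
    ))
  }
  samples <- setdiff(names(tab), "SNP_ID")
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicate sample id(s) in header of '%s'", path))
  }
  for (s in samples) {
    norm <- normalize_genotype(tab[[s]])
    bad <- which(is.na(norm))
    if (length(bad) > 0) {
      abort(sprintf(
        "unrecognized genotype '%s' at SNP '%s', sample '%s' in '%s'",
        tab[[s]][bad[1]], tab$SNP_ID[bad[1]], s, path
      ))
    }
    tab[[s]] <- norm
  }
  tab
}

normalize_genotype <- function(x) {
  z <- toupper(gsub("[ _]", "", trimws(x)))
  z[is.na(z) | z == "" | z == "NOCALL" | z == "-" | z == "NA"] <- NO_CALL
  z[!z %in% c(GENOTYPES, NO_CALL)] <- NA_character_
  z
}

#' Read a phenotype CSV
#'
#' Reads sample metadata and extracts the Case/Control designation. The
#' sample-id column is the first column (or one named like `Sample_ID`); the
#' status column is located by name (anything matching case/control, status,
#' phenotype or disease state). Status values are normalized
#' case-insensitively to `Case`/`Control`; samples with any other status are
#' dropped with a warning unless `status_map` says how to map them.
#'
#' @param path Path to the phenotype CSV.
#' @param status_map Optional named character vector mapping raw status
#'   strings (lower-cased) to `"Case"` or `"Control"`, for series whose
#'   phenotype labels are disease subtypes rather than literal Case/Control.
#' @return A tibble with columns `Sample_ID`, `Case_Control`.
#' @export
read_phenotype_csv <- function(path, status_map = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("phenotype file '%s' does not exist", path))
  }
  tab <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  norm_names <- tolower(gsub("[^a-z]", "", tolower(names(tab))))
  id_col <- which(norm_names %in% c("sampleid", "sample", "id", "geoaccession"))
  id_col <- if (length(id_col) > 0) id_col[1] else 1L
  status_col <- which(norm_names %in% c(
    "casecontrol", "caseorcontrol", "status", "phenotype", "diseasestate",
    "diseasestatus"
  ))
  if (length(status_col) == 0) {
    abort(sprintf(
      "no recognizable Case/Control status column in '%s' (columns: %s)",
      path, paste(names(tab), collapse = ", ")
    ))
  }
  status_raw <- trimws(tab[[status_col[1]]])
  status <- dplyr::case_when(
    tolower(status_raw) == "case" ~ "Case",
    tolower(status_raw) == "control" ~ "Control",
    .default = NA_character_
  )
  if (!is.null(status_map)) {
    mapped <- unname(status_map[tolower(status_raw)])
    status <- dplyr::coalesce(status, mapped)
  }
  out <- tibble(
    Sample_ID = trimws(tab[[id_col]]),
    Case_Control = status
  )
  n_bad <- sum(is.na(out$Case_Control))
  if (n_bad > 0) {
    warn(sprintf(
      "dropping %d sample(s) with unrecognized status in '%s'", n_bad, path
    ))
    out <- out[!is.na(out$Case_Control), ]
  }
  if (anyDuplicated(out$Sample_ID)) {
    abort(sprintf("duplicate sample id(s) in '%s'", path))
  }
  out
}

#' Merge genotype and phenotype tables into one labeled dataset
#'
#' Attaches the Case/Control designation to the genotype data and transposes
#' to the modeling orientation. GEO genotype files are SNPs-as-rows; all
#' downstream modeling in this package is samples-as-rows, and this is the
#' single place where the transpose happens. Samples are restricted to the
#' intersection of the two files' ids (exact string match after whitespace
#' trimming — no fuzzy matching), keeping the genotype file's sample order;
#' dropped-sample counts are reported. Merging an already-labeled
#' sample-per-row dataset with a consistent phenotype table is a no-op.
#'
#' @param geno Genotype tibble from [read_genotype_csv()] (SNPs as rows), or
#'   an already-labeled sample-per-row dataset.
#' @param pheno Phenotype tibble from [read_phenotype_csv()].
#' @return Labeled tibble: `Sample_ID`, `Case_Control`, one genotype column
#'   per SNP.
#' @export
merge_case_control <- function(geno, pheno) {
  if (!all(c("Sample_ID", "Case_Control") %in% names(pheno))) {
    abort("`pheno` must have Sample_ID and Case_Control columns.")
  }
  pheno$Sample_ID <- trimws(pheno$Sample_ID)
  if ("Sample_ID" %in% names(geno)) {
    # already samples-as-rows
    sample_ids <- trimws(geno$Sample_ID)
    cells <- geno[, setdiff(snp_cols(geno), "SNP_ID"), drop = FALSE]
  } else {
    sample_ids <- trimws(setdiff(names(geno), "SNP_ID"))
    if (anyDuplicated(geno$SNP_ID)) {
      abort("duplicate SNP ids in genotype table.")
    }
    m <- t(as.matrix(geno[, setdiff(names(geno), "SNP_ID"), drop = FALSE]))
    colnames(m) <- geno$SNP_ID
    cells <- as_tibble(m)
  }
  keep <- sample_ids %in% pheno$Sample_ID
  n_geno_drop <- sum(!keep)
  n_pheno_drop <- sum(!pheno$Sample_ID %in% sample_ids)
  if (!any(keep)) {
    abort("no samples in common between genotype and phenotype tables.")
  }
  if (n_geno_drop + n_pheno_drop > 0) {
    inform(sprintf(
      "merge_case_control: dropped %d genotyped sample(s) without phenotype and %d phenotyped sample(s) without genotypes",
      n_geno_drop, n_pheno_drop
    ))
  }
  status <- stats::setNames(pheno$Case_Control, pheno$Sample_ID)
  out <- dplyr::bind_cols(
    tibble(
      Sample_ID = sample_ids[keep],
      Case_Control = unname(status[sample_ids[keep]])
    ),
    cells[keep, , drop = FALSE]
  )
  check_labeled(out)
  out
}

#' Write a processed (labeled) dataset as a single CSV
#'
#' One row per sample, one column per SNP, with `Sample_ID` first and
#' `Case_Control` last. Numeric (encoded) cells are serialized at full
#' precision so the round-trip through [read_processed_csv()] is lossless.
#'
#' @param data Labeled genotype or encoded tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_processed_csv <- function(data, path) {
  check_labeled(data)
  out <- data[, c("Sample_ID", snp_cols(data), "Case_Control")]
  readr::write_csv(out, path)
  invisible(path)
}

#' Read back a processed dataset written by [write_processed_csv()]
#'
#' @param path File path.
#' @return Labeled tibble with `Sample_ID`, `Case_Control` and one column
#'   per SNP (numeric if the file held encodings, character otherwise).
#' @export
read_processed_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist", path))
  }
  tab <- readr::read_csv(path,
    progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      Sample_ID = readr::col_character(),
      Case_Control = readr::col_character(),
      .default = readr::col_guess()
    )
  )
  if (!all(c("Sample_ID", "Case_Control") %in% names(tab))) {
    abort(sprintf("'%s' lacks Sample_ID/Case_Control columns", path))
  }
  tab <- tab[, c("Sample_ID", "Case_Control",
    setdiff(names(tab), ID_COLS))]
  check_labeled(tab)
  tab
}
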