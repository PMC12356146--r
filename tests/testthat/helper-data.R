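# In-code fixtures shared across the suite.

# small labeled genotype dataset built by hand
toy_genotypes <- function() {
  tibble::tibble(
    Sample_ID = paste0("S", 1:6),
    Case_Control = c("Case", "Case", "Case", "Case", "Control", "Control"),
    SNP_A = c("AA", "AA", "AA", "AA", "AA", "AA"), # invariant
    SNP_B = c("AA", "AB", "AB", "BB", "AA", "BB"),
    SNP_C = c("AA", "NC", "AA", "AB", "AB", "NC"), # 2/6 NC
    SNP_D = c("AB", "BB", "AB", "AB", "BB", "AA")
  )
}

# labeled numeric dataset from a matrix
encoded_tbl <- function(X, y, ids = NULL) {
  colnames(X) <- colnames(X) %||% sprintf("SNP_%03d", seq_len(ncol(X)))
  dplyr::bind_cols(
    tibble::tibble(
      Sample_ID = ids %||% sprintf("S%03d", seq_len(nrow(X))),
      Case_Control = ifelse(y == 1, "Case", "Control")
    ),
    tibble::as_tibble(X)
  )
}

`%||%` <- rlang::`%||%`
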