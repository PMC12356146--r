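# Independent brute-force reference implementations used as oracles. These
# deliberately share no code with the package: plain loops, textbook
# formulas.

# greedy cosine-redundancy rule, literal transcription
oracle_greedy_cosine <- function(X, order_ids, n_final, tau) {
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  kept <- character(0)
  skipped <- character(0)
  for (id in order_ids) {
    if (length(kept) >= n_final) break
    if (length(kept) == 0) {
      kept <- id
      next
    }
    sims <- sapply(kept, function(kid) cosine(X[, id], X[, kid]))
    if (max(sims) < tau) kept <- c(kept, id) else skipped <- c(skipped, id)
  }
  if (length(kept) < n_final) {
    kept <- c(kept, head(skipped, n_final - length(kept)))
  }
  kept
}

# textbook ReliefF with m = all samples, range-normalized diffs
oracle_relieff <- function(X, y, k) {
  n <- nrow(X)
  rngs <- apply(X, 2, function(v) diff(range(v)))
  rngs[rngs == 0] <- Inf
  w <- numeric(ncol(X))
  prior <- table(y) / n
  for (i in seq_len(n)) {
    d <- sapply(seq_len(n), function(j) {
      if (j == i) Inf else sum(abs(X[i, ] - X[j, ]) / rngs)
    })
    ord <- order(d)
    hits <- ord[y[ord] == y[i]][1:k]
    for (f in seq_len(ncol(X))) {
      w[f] <- w[f] - mean(abs(X[i, f] - X[hits, f]) / rngs[f]) / n
    }
    for (cl in setdiff(unique(y), y[i])) {
      miss <- ord[y[ord] == cl][1:k]
      pw <- prior[[as.character(cl)]] / (1 - prior[[as.character(y[i])]])
      for (f in seq_len(ncol(X))) {
        w[f] <- w[f] + pw * mean(abs(X[i, f] - X[miss, f]) / rngs[f]) / n
      }
    }
  }
  stats::setNames(w, colnames(X))
}

oracle_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  mi <- 0
  for (a in rownames(tab)) {
    for (b in colnames(tab)) {
      pxy <- tab[a, b] / n
      if (pxy > 0) {
        mi <- mi + pxy * log2(pxy / (sum(tab[a, ]) / n * sum(tab[, b]) / n))
      }
    }
  }
  mi
}

oracle_cmi <- function(x, y, z) {
  out <- 0
  for (zl in unique(z)) {
    sel <- z == zl
    out <- out + mean(sel) * oracle_mi(x[sel], y[sel])
  }
  out
}

# CMIM selection by exhaustive evaluation of the criterion at every step
oracle_cmim <- function(df, y, n_select) {
  pool <- sort(names(df))
  selected <- character(0)
  while (length(selected) < n_select && length(pool) > 0) {
    scores <- sapply(pool, function(f) {
      if (length(selected) == 0) {
        oracle_mi(df[[f]], y)
      } else {
        min(sapply(selected, function(s) oracle_cmi(df[[f]], y, df[[s]])))
      }
    })
    best <- pool[order(-scores, pool)][1]
    selected <- c(selected, best)
    pool <- setdiff(pool, best)
  }
  selected
}

# direct Monte-Carlo tabulation of the generator's label model: empirical
# case odds for carriers of 2 vs 0 risk alleles at one causal SNP
oracle_marginal_odds_ratio <- function(n, maf, beta, n_causal, case_fraction) {
  dos <- matrix(rbinom(n * n_causal, 2, maf), n, n_causal)
  eta <- rowSums(dos) * beta
  b0 <- uniroot(function(b) mean(plogis(eta + b)) - case_fraction, c(-50, 50))$root
  y <- rbinom(n, 1, plogis(eta + b0))
  g <- dos[, 1]
  odds <- function(sel) {
    p <- mean(y[sel])
    p / (1 - p)
  }
  odds(g == 2) / odds(g == 0)
}
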