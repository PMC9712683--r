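# Independent brute-force oracles. These deliberately use plain loops and
# alternative formulations so that agreement with the package's vectorized
# implementations is a real check, not a restatement.

# lagged autocovariance of each column, explicit double loop
oracle_segment_act <- function(part, lag) {
  n <- nrow(part)
  out <- numeric(ncol(part))
  for (j in seq_len(ncol(part))) {
    mu <- mean(part[, j])
    acc <- 0
    for (m in seq_len(n - lag)) {
      acc <- acc + (part[m, j] - mu) * (part[m + lag, j] - mu)
    }
    out[j] <- acc / (n - lag)
  }
  out
}

# mean squared difference at a fixed rank, explicit double loop
oracle_pse_correlation <- function(part, rank) {
  n <- nrow(part)
  out <- numeric(ncol(part))
  for (j in seq_len(ncol(part))) {
    acc <- 0
    for (m in seq_len(n - rank)) {
      acc <- acc + (part[m, j] - part[m + rank, j])^2
    }
    out[j] <- acc / (n - rank)
  }
  out
}

# threshold metrics recomputed from reconstructed prediction/truth vectors;
# MCC via the Pearson correlation of the two binary vectors
oracle_metrics <- function(cc) {
  truth <- rep(c(1, 1, 0, 0), cc[c("TP", "FN", "TN", "FP")])
  pred <- rep(c(1, 0, 0, 1), cc[c("TP", "FN", "TN", "FP")])
  mcc <- suppressWarnings(stats::cor(pred, truth))
  if (is.na(mcc)) mcc <- 0
  list(
    acc = mean(pred == truth),
    sn = if (sum(truth) == 0) NA_real_ else mean(pred[truth == 1] == 1),
    sp = if (sum(truth == 0) == 0) NA_real_ else mean(pred[truth == 0] == 0),
    precision = if (sum(pred) == 0) NA_real_ else mean(truth[pred == 1] == 1),
    mcc = mcc
  )
}

# AUROC as the normalized Mann-Whitney U statistic (midranks handle ties)
oracle_auroc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# GAAC recomputed with a naive per-group character counter
oracle_gaac <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  vapply(gaac_groups, function(g) {
    sum(vapply(chars, function(ch) ch %in% g, logical(1))) / length(chars)
  }, numeric(1))
}

# DPC counts with a naive sliding window
oracle_dpc_count <- function(sequence, dipeptide) {
  chars <- strsplit(sequence, "")[[1]]
  hits <- 0
  for (i in seq_len(length(chars) - 1)) {
    if (paste0(chars[i], chars[i + 1]) == dipeptide) hits <- hits + 1
  }
  hits
}

random_sequence <- function(L) {
  paste(sample(aa_alphabet, L, replace = TRUE), collapse = "")
}

# a normalized pssm with haphazard entries in (0, 1)
random_norm_pssm <- function(L, id = "rnd") {
  raw <- matrix(rnorm(L * 20, sd = 2), nrow = L)
  normalize_pssm(pssm(raw, sample(aa_alphabet, L, replace = TRUE), id))
}

# signal/noise feature matrix for selection and modeling tests:
# first `n_signal` columns have class means shifted by `shift` SDs
signal_matrix <- function(n = 60, p = 10, n_signal = 3, shift = 3) {
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), nrow = n,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  x[y == 1L, seq_len(n_signal)] <- x[y == 1L, seq_len(n_signal)] + shift
  list(x = x, y = y)
}
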