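# Independent oracles used across the suite. These deliberately re-derive
# quantities with naive algorithms, never through the package's own code
# paths.

# Quadratic dynamic-programming edit distance
dp_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1, length(y) + 1)
  d[, 1] <- 0:length(x)
  d[1, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[length(x) + 1, length(y) + 1]
}

# O(n^2) pairwise-concordance ROC-AUC
concordance_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

random_peptides <- function(n, L = 10) {
  vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""), character(1))
}

# small library with analytic structure for fast model tests
tiny_library <- function(n = 60, M = 2, seed = 42) {
  withr::with_seed(seed, {
    seqs <- random_peptides(n)
    Z <- matrix(rnorm(n * M), n, M,
                dimnames = list(NULL, sprintf("P%02d", seq_len(M))))
    peptide_library(seqs, Z = Z)
  })
}

# independent per-position amino-acid frequency table
position_freqs <- function(seqs) {
  chars <- do.call(rbind, strsplit(seqs, ""))
  apply(chars, 2, function(col)
    as.numeric(table(factor(col, levels = AA_ALPHABET))) / length(col))
}
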