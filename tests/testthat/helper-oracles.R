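# Independent oracles used to validate the package implementations.
# Deliberately written as naive loops so they share no code path with the
# functions under test.

# brute-force motif scan: returns 0-based cut positions
oracle_cuts <- function(sequence, motif, cut_offset) {
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  L <- nchar(sequence)
  k <- nchar(motif)
  cuts <- integer(0)
  for (i in seq_len(max(L - k + 1, 0))) {
    if (substr(sequence, i, i + k - 1) == motif) {
      cuts <- c(cuts, i - 1 + cut_offset)
    }
  }
  sort(unique(cuts[cuts > 0 & cuts < L]))
}

oracle_fragment_lengths <- function(sequence, motif, cut_offset) {
  L <- nchar(sequence)
  diff(c(0, oracle_cuts(sequence, motif, cut_offset), L))
}

# exhaustive-permutation Mann-Whitney: U counted pair by pair, p from all
# group reassignments of the pooled values
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

oracle_mwu_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  obs <- abs(oracle_u(x, y) - mu)
  picks <- combn(length(pool), n1)
  extreme <- 0
  for (j in seq_len(ncol(picks))) {
    xx <- pool[picks[, j]]
    yy <- pool[-picks[, j]]
    extreme <- extreme + (abs(oracle_u(xx, yy) - mu) >= obs - 1e-9)
  }
  extreme / ncol(picks)
}

# coefficient of determination straight from the sums of squares
oracle_r_squared <- function(x, y) {
  n <- length(x)
  num <- (n * sum(x * y) - sum(x) * sum(y))^2
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  num / den
}

# random DNA sequence
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
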