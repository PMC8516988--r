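# Independent textbook-formula oracles, kept free of the package's own code
# paths so they can arbitrate.

oracle_student_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_welch_t <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

oracle_chi2 <- function(a, b, c, d) {
  o <- rbind(c(a, b), c(c, d))
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  chi2 <- sum((o - e)^2 / e)
  list(chi2 = chi2, p = 1 - pchisq(chi2, 1))
}

# exact hypergeometric upper tail by enumeration: overlap >= k when n_hits
# are drawn from a background of size N containing a set of size K
oracle_hyper_tail <- function(k, K, n_hits, N) {
  j <- k:min(K, n_hits)
  sum(choose(K, j) * choose(N - K, n_hits - j)) / choose(N, n_hits)
}

# brute-force quantile normalization: substitute the row-means of the sorted
# columns at each value's within-column rank, averaging tied ranks' targets
oracle_quantile_normalize <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    (target[floor(r)] + target[ceiling(r)]) / 2
  })
}

# construct a vector of length n with exactly the given mean and sd
vector_with_moments <- function(mean, sd, n) {
  base <- seq_len(n)
  base <- (base - mean(base)) / sd(base)
  mean + sd * base
}
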