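# Independent brute-force oracles used to cross-check the main
# implementations. These deliberately take the slow, definitional route.

# Mann-Whitney U / (n1 n2) with half-credit for ties, by pairwise counting.
auc_by_pairwise_count <- function(pos, neg) {
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# ICC(2,1) from explicitly accumulated two-way ANOVA sums of squares.
icc21_brute <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(m[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(m[, j]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (m[i, j] - grand)^2
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Clopper-Pearson bounds by direct bisection on the binomial tail.
cp_by_tail_inversion <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  # both tail functions are decreasing in p: move right while f > 0
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    bisect(function(p) stats::pbinom(x - 1, n, p) - (1 - alpha / 2), 0, 1)
  upper <- if (x == n) 1 else
    bisect(function(p) stats::pbinom(x, n, p) - alpha / 2, 0, 1)
  c(lower = lower, upper = upper)
}
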