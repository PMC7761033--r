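# Independent brute-force oracles, kept free of the package's code paths.

# Exact two-sided rank-sum p-value by full enumeration of all C(m+n, m)
# group assignments of the pooled ranks.
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  m <- length(a)
  w_obs <- sum(r[seq_len(m)])
  sets <- utils::combn(length(pooled), m)
  w_all <- apply(sets, 2L, function(idx) sum(r[idx]))
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

# Step-up BH adjustment written from the definition.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# Cohen's kappa from two label vectors, straight from the two-rater formula.
brute_kappa <- function(truth, pred) {
  classes <- union(truth, pred)
  p_o <- mean(truth == pred)
  p_e <- sum(vapply(classes, function(cl) {
    mean(truth == cl) * mean(pred == cl)
  }, numeric(1)))
  (p_o - p_e) / (1 - p_e)
}
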