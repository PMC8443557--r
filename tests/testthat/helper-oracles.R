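# Independent brute-force oracles used to pin expected values.

# All permutations of 1..n (n small).
perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))))
}

# Exhaustive two-sample KS permutation p-value: all assignments of the
# pooled sample into groups of the original sizes.
ks_perm_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); nb <- length(b)
  d_stat <- function(u, v) {
    grid <- sort(unique(c(u, v)))
    max(abs(vapply(grid, function(g) mean(u <= g) - mean(v <= g), numeric(1))))
  }
  d_obs <- d_stat(a, b)
  splits <- utils::combn(na + nb, na)
  hits <- apply(splits, 2, function(ix)
    d_stat(pooled[ix], pooled[-ix]) >= d_obs - 1e-12)
  mean(hits)
}

# Exhaustive Spearman two-sided permutation p-value (tie-free samples).
spearman_perm_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  pm <- perms(n)
  rhos <- apply(pm, 1, function(p) stats::cor(rx, ry[p]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# One-sided (greater) Fisher p by hypergeometric enumeration for the table
# rbind(c(a, b), c(c_, d)).
fisher_hyper_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  ks <- max(0, k - n):min(m, k)
  sum(stats::dhyper(ks[ks >= a], m, n, k))
}

# One-sided (greater) exact binomial p at null 0.5 by enumeration.
binom_enum_p <- function(k, n) {
  sum(choose(n, k:n)) / 2^n
}

# Random point on the simplex over m categories.
rand_simplex <- function(m) {
  e <- stats::rexp(m)
  e / sum(e)
}

# Match detected event peaks against planted event times within a
# tolerance; events peak ~1.3 ms after kernel onset. Returns recall and
# precision.
match_events <- function(truth_times, det_peaks, tol_s = 0.005,
                         peak_lag_s = 0.0013) {
  expected <- truth_times + peak_lag_s
  if (!length(det_peaks))
    return(c(recall = 0, precision = NA_real_))
  recall <- mean(vapply(expected, function(t0)
    any(abs(det_peaks - t0) <= tol_s), logical(1)))
  precision <- mean(vapply(det_peaks, function(t0)
    any(abs(expected - t0) <= tol_s), logical(1)))
  c(recall = recall, precision = precision)
}
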