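# Shared fixture builders; everything is generated in code at test time.

# seeded random array with given mode sizes
random_tensor <- function(dims, seed = 1) {
  set.seed(seed)
  array(rnorm(prod(dims)), dim = dims)
}

# small 6-mode expression tensor with dimnames, for io/pipeline plumbing
small_expression_tensor <- function(n_probes = 8, seed = 1) {
  set.seed(seed)
  expression_tensor(array(rnorm(n_probes * 2 * 2 * 2 * 2 * 2),
                          dim = c(n_probes, 2, 2, 2, 2, 2)))
}

# direct mode-n unfolding by index arithmetic only (oracle, independent of
# unfold()): entry (i_n, linear index over the other modes in order)
naive_unfold <- function(x, mode) {
  d <- dim(x)
  others <- seq_along(d)[-mode]
  out <- matrix(0, d[mode], prod(d[others]))
  idx_grid <- as.matrix(expand.grid(lapply(d[others], seq_len)))
  for (r in seq_len(d[mode])) {
    for (cc in seq_len(nrow(idx_grid))) {
      full <- integer(length(d))
      full[mode] <- r
      full[others] <- idx_grid[cc, ]
      out[r, cc] <- x[matrix(full, nrow = 1)]
    }
  }
  out
}

# brute-force Benjamini-Hochberg step-up (oracle for p.adjust usage)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exhaustive hypergeometric upper tail: P[X >= a] by direct summation
hyper_tail_oracle <- function(a, N, K, n) {
  upper <- min(K, n)
  if (a > upper) return(0)
  sum(vapply(a:upper, function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))) / choose(N, n)
}

relative_frobenius_error <- function(a, b) {
  sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
}
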