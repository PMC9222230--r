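# minimal tissue_matrix constructor for hand fixtures
toy_tissue_matrix <- function(values, treatment, tissue = "toy") {
  structure(list(values = values,
                 design = data.frame(sample_id = colnames(values),
                                     treatment = treatment),
                 tissue = tissue),
            class = "tissue_matrix")
}

test_that("Welch t matches the closed-form oracle on a hand dataset", {
  vals <- rbind(p1 = c(1, 2, 3, 6, 7, 8))
  colnames(vals) <- sprintf("s%d", 1:6)
  tm <- toy_tissue_matrix(vals, c(1, 1, 1, 2, 2, 2))
  res <- ttest_select(tm)
  expect_equal(res$stats$statistic, -6.123724, tolerance = 1e-6)
  expect_equal(res$stats$p_raw, 0.003602233, tolerance = 1e-6)
  # agreement with stats::t.test to full precision
  tt <- t.test(c(1, 2, 3), c(6, 7, 8))
  expect_equal(res$stats$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$stats$p_raw, tt$p.value, tolerance = 1e-10)
  expect_equal(res$stats$df, unname(tt$parameter), tolerance = 1e-10)
})

test_that("equal group means give statistic 0 and flat probes are floored, not NaN", {
  vals <- rbind(flat = rep(5, 8), null = c(1, 2, 1, 2, 1, 2, 1, 2))
  colnames(vals) <- sprintf("s%d", 1:8)
  tm <- toy_tissue_matrix(vals, rep(1:2, each = 4))
  res <- ttest_select(tm)
  expect_true(all(is.finite(res$stats$statistic)))
  expect_true(res$stats$var_floored[1])
  expect_equal(res$stats$statistic[1], 0)
  expect_equal(res$stats$p_raw[1], 1)
})

test_that("SAM-like statistic stays finite for vanishing within-probe variance", {
  set.seed(1)
  vals <- rbind(matrix(rnorm(20 * 8), 20), tight = c(rep(0, 4), rep(1, 4)) + 1e-9 * rnorm(8))
  rownames(vals) <- sprintf("p%02d", 1:21)
  colnames(vals) <- sprintf("s%d", 1:8)
  tm <- toy_tissue_matrix(vals, rep(1:2, each = 4))
  res <- sam_like_select(tm, seed = 4, n_permutations = 60)
  expect_true(all(is.finite(res$stats$statistic)))
  expect_gt(res$s0, 0)
})

test_that("exact SAM-like enumeration equals the brute-force permutation oracle", {
  set.seed(3)
  vals <- matrix(rnorm(12 * 8), 12, dimnames = list(sprintf("p%02d", 1:12),
                                                    sprintf("s%d", 1:8)))
  vals[1:2, 5:8] <- vals[1:2, 5:8] + 2
  tm <- toy_tissue_matrix(vals, rep(1:2, each = 4))
  res <- sam_like_select(tm, exact = TRUE)

  # oracle: enumerate all 70 label splits from scratch
  d_of <- function(x, i1) {
    i2 <- setdiff(1:8, i1)
    m1 <- rowMeans(x[, i1]); m2 <- rowMeans(x[, i2])
    sp2 <- (rowSums((x[, i1] - m1)^2) + rowSums((x[, i2] - m2)^2)) / 6
    s <- sqrt(sp2 * (1 / 4 + 1 / 4))
    list(d = (m1 - m2) / (s + s0_obs), s = s)
  }
  m1 <- rowMeans(vals[, 1:4]); m2 <- rowMeans(vals[, 5:8])
  sp2 <- (rowSums((vals[, 1:4] - m1)^2) + rowSums((vals[, 5:8] - m2)^2)) / 6
  s0_obs <- median(sqrt(sp2 * 0.5))
  combs <- combn(8, 4)
  null_pool <- abs(as.numeric(vapply(seq_len(ncol(combs)), function(j)
    d_of(vals, combs[, j])$d, numeric(12))))
  d_obs <- d_of(vals, 1:4)$d
  p_oracle <- vapply(d_obs, function(d) mean(null_pool >= abs(d) - 1e-12), numeric(1))
  expect_equal(res$stats$p_raw, unname(p_oracle), tolerance = 1e-12)
  expect_equal(res$stats$statistic, unname(d_obs), tolerance = 1e-12)
})

test_that("requesting more permutations than distinct splits points to exact mode", {
  vals <- matrix(rnorm(5 * 6), 5, dimnames = list(sprintf("p%d", 1:5),
                                                  sprintf("s%d", 1:6)))
  tm <- toy_tissue_matrix(vals, rep(1:2, each = 3))
  expect_error(sam_like_select(tm, n_permutations = 50, seed = 1), "exact")
  expect_error(sam_like_select(tm, n_permutations = 10, seed = 1), ">= 50")
})

test_that("SAM-like selection controls false positives on null data", {
  sim <- generate_dataset(simulation_config(n_probes = 800, frac_deg = 0.1,
                                            effect_size = 0, seed = 3))
  tm <- extract_tissue_matrix(sim$tensor, 1)
  res <- sam_like_select(tm, threshold = 0.01, n_permutations = 100, seed = 5)
  expect_lte(mean(res$stats$selected), 0.02)
})

test_that("moderated t matches an independently coded two-step EB oracle", {
  set.seed(6)
  n1 <- 4; n2 <- 4
  vals <- matrix(rnorm(150 * (n1 + n2), sd = rep(sqrt(rchisq(150, 5) / 5), n1 + n2)),
                 150, dimnames = list(sprintf("p%03d", 1:150), sprintf("s%d", 1:8)))
  tm <- toy_tissue_matrix(vals, rep(1:2, each = 4))
  res <- moderated_t_select(tm)

  # oracle: restate the moment equations directly
  m1 <- rowMeans(vals[, 1:4]); m2 <- rowMeans(vals[, 5:8])
  df <- n1 + n2 - 2
  s2 <- (rowSums((vals[, 1:4] - m1)^2) + rowSums((vals[, 5:8] - m2)^2)) / df
  r <- var(s2) / mean(s2)^2
  d0 <- (4 * r * df + 2 * df - 4) / (r * df - 2)
  s02 <- mean(s2) * (d0 - 2) / d0
  shrunk <- (d0 * s02 + df * s2) / (d0 + df)
  t_oracle <- (m1 - m2) / sqrt(shrunk * (1 / n1 + 1 / n2))
  p_oracle <- 2 * pt(abs(t_oracle), df = df + d0, lower.tail = FALSE)
  expect_equal(res$stats$statistic, unname(t_oracle), tolerance = 1e-8)
  expect_equal(res$stats$p_raw, unname(p_oracle), tolerance = 1e-8)
})

test_that("moderated t has the right limiting behaviour in the prior weight", {
  set.seed(8)
  vals <- matrix(rnorm(100 * 10), 100, dimnames = list(sprintf("p%03d", 1:100),
                                                       sprintf("s%d", 1:10)))
  tm <- toy_tissue_matrix(vals, rep(1:2, each = 5))
  res <- moderated_t_select(tm)
  d0 <- res$prior$d0
  df <- 8
  # shrunk variances lie between each probe's variance and the prior scale
  m1 <- rowMeans(vals[, 1:5]); m2 <- rowMeans(vals[, 6:10])
  s2 <- (rowSums((vals[, 1:5] - m1)^2) + rowSums((vals[, 6:10] - m2)^2)) / df
  shrunk <- if (is.infinite(d0)) rep(res$prior$s02, 100) else
    (d0 * res$prior$s02 + df * s2) / (d0 + df)
  expect_true(all(shrunk >= pmin(s2, res$prior$s02) - 1e-12))
  expect_true(all(shrunk <= pmax(s2, res$prior$s02) + 1e-12))
  # d0 -> 0 limit of the formula is the ordinary t; d0 -> Inf is pooled variance
  fv <- tensorDE:::fit_variance_prior
  expect_equal(((0 * 1 + df * s2) / (0 + df)), s2)
  big <- fv(rep(2, 100) + rnorm(100, sd = 1e-8), df)   # nearly constant s2
  expect_true(is.infinite(big$d0) || big$d0 > 1e3)
  expect_error(moderated_t_select(toy_tissue_matrix(vals[1:2, ], rep(1:2, each = 5))),
               "3 probes")
})

test_that("moderated t ranks probes like limma's eBayes on simulated data", {
  skip_if_not_installed("limma")
  set.seed(12)
  n <- 60
  vals <- matrix(rnorm(300 * n, sd = rep(sqrt(rchisq(300, 4) / 4), n)), 300)
  vals[1:30, seq_len(n / 2)] <- vals[1:30, seq_len(n / 2)] + 1
  rownames(vals) <- sprintf("p%03d", 1:300)
  colnames(vals) <- sprintf("s%d", seq_len(n))
  tm <- toy_tissue_matrix(vals, rep(1:2, each = n / 2))
  res <- moderated_t_select(tm)
  design <- cbind(1, rep(c(1, 0), each = n / 2))
  fit <- limma::eBayes(limma::lmFit(vals, design))
  expect_gt(cor(abs(res$stats$statistic), abs(fit$t[, 2]), method = "spearman"), 0.95)
})

test_that("ComBat-style adjustment removes a pure additive batch shift", {
  set.seed(20)
  base <- matrix(rnorm(50 * 6), 50, dimnames = list(sprintf("p%02d", 1:50),
                                                    sprintf("a%d", 1:6)))
  offset <- rnorm(50, sd = 2)
  b2 <- base + offset
  colnames(b2) <- sprintf("b%d", 1:6)
  tm1 <- toy_tissue_matrix(base, rep(1:2, 3), tissue = "one")
  tm2 <- toy_tissue_matrix(b2, rep(1:2, 3), tissue = "two")
  adj <- combat_adjust(list(tm1, tm2))
  batch <- adj$design$tissue
  m1 <- rowMeans(adj$values[, batch == "one"])
  m2 <- rowMeans(adj$values[, batch == "two"])
  # residual batch separation is strongly reduced (EB shrinkage with only
  # 6 samples per batch leaves some residual; exactness holds noise-free)
  expect_lt(mean(abs(m1 - m2)), 0.5 * mean(abs(offset)))
  # planted offsets are recovered by the estimated location effects (data units)
  gamma <- attr(adj, "gamma_star")
  est_offset <- (gamma[, 2] - gamma[, 1]) * sqrt(attr(adj, "var_pooled"))
  expect_gt(cor(est_offset, offset), 0.95)
})

test_that("ComBat-style adjustment is near a no-op without batch effects", {
  set.seed(21)
  v1 <- matrix(rnorm(200 * 20), 200, dimnames = list(sprintf("p%03d", 1:200),
                                                     sprintf("a%d", 1:20)))
  v2 <- matrix(rnorm(200 * 20), 200, dimnames = list(sprintf("p%03d", 1:200),
                                                     sprintf("b%d", 1:20)))
  adj <- combat_adjust(list(toy_tissue_matrix(v1, rep(1:2, 10)),
                            toy_tissue_matrix(v2, rep(1:2, 10))))
  input <- cbind(v1, v2)
  expect_lt(mean(abs(adj$values - input)), 0.15)
  expect_gt(cor(as.numeric(adj$values), as.numeric(input)), 0.98)
})

test_that("exact location batch effect removal in the no-noise limit", {
  probes <- sprintf("p%02d", 1:30)
  base <- matrix(rep(rnorm(30), 4), 30, dimnames = list(probes, sprintf("a%d", 1:4)))
  shift <- matrix(rep(rnorm(30), 4), 30, dimnames = list(probes, sprintf("b%d", 1:4)))
  tm1 <- toy_tissue_matrix(base, rep(1:2, 2), tissue = "one")
  tm2 <- toy_tissue_matrix(base + shift, rep(1:2, 2), tissue = "two")
  adj <- combat_adjust(list(tm1, tm2))
  b <- adj$design$tissue
  m1 <- rowMeans(adj$values[, b == "one"])
  m2 <- rowMeans(adj$values[, b == "two"])
  expect_lt(max(abs(m1 - m2)), 1e-8)
})

test_that("planted batch offsets are recovered in a larger simulation", {
  set.seed(22)
  n_probes <- 500
  probes <- sprintf("p%03d", seq_len(n_probes))
  v1 <- matrix(rnorm(n_probes * 10), n_probes, dimnames = list(probes, sprintf("a%d", 1:10)))
  offs <- rnorm(n_probes, sd = 1.5)
  v2 <- matrix(rnorm(n_probes * 10), n_probes, dimnames = list(probes, sprintf("b%d", 1:10))) + offs
  adj <- combat_adjust(list(toy_tissue_matrix(v1, rep(1:2, 5), tissue = "one"),
                            toy_tissue_matrix(v2, rep(1:2, 5), tissue = "two")))
  gamma <- attr(adj, "gamma_star")
  est <- (gamma[, 2] - gamma[, 1]) * sqrt(attr(adj, "var_pooled"))
  expect_gt(cor(est, offs), 0.95)
})

test_that("adjusted values agree with sva::ComBat", {
  skip_if_not_installed("sva")
  set.seed(23)
  probes <- sprintf("p%03d", 1:200)
  v1 <- matrix(rnorm(200 * 12), 200, dimnames = list(probes, sprintf("a%d", 1:12)))
  v2 <- matrix(rnorm(200 * 12, mean = 0.5, sd = 1.4), 200,
               dimnames = list(probes, sprintf("b%d", 1:12)))
  adj <- combat_adjust(list(toy_tissue_matrix(v1, rep(1:2, 6)),
                            toy_tissue_matrix(v2, rep(1:2, 6))))
  ref <- sva::ComBat(cbind(v1, v2), batch = rep(1:2, each = 12))
  expect_gt(cor(as.numeric(adj$values), as.numeric(ref)), 0.99)
  expect_lt(mean(abs(adj$values - ref)), 0.1)
})

test_that("batches with a single sample are rejected", {
  v1 <- matrix(rnorm(10 * 4), 10, dimnames = list(sprintf("p%d", 1:10), sprintf("a%d", 1:4)))
  v2 <- matrix(rnorm(10), 10, dimnames = list(sprintf("p%d", 1:10), "b1"))
  expect_error(combat_adjust(list(toy_tissue_matrix(v1, rep(1:2, 2)),
                                  structure(list(values = v2,
                                                 design = data.frame(sample_id = "b1",
                                                                     treatment = 1)),
                                            class = "tissue_matrix"))),
               "> 1 sample")
})
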