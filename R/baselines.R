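#' Extract one tissue's probe-by-sample matrix from the tensor
#'
#' Flattens the (time, replicate, treatment, strain) cells of a single
#' tissue into sample columns, the per-sample design kept alongside.
#' This is the input shape of the per-tissue baseline selectors, which
#' pool time points and replicates as i.i.d. samples and compare the two
#' treatment arms.
#'
#' @param tensor an [expression_tensor()].
#' @param tissue tissue label or index.
#' @return object of class `tissue_matrix`: list with `values` (probe x
#'   sample matrix) and `design` (data.frame `sample_id`, `time`,
#'   `replicate`, `treatment`, `strain`).
#' @export
extract_tissue_matrix <- function(tensor, tissue) {
  d <- dim(tensor)
  tissues <- dimnames(tensor)[[6L]]
  ti <- if (is.character(tissue)) match(tissue, tissues) else as.integer(tissue)
  if (is.na(ti) || ti < 1L || ti > d[6L]) {
    stop(sprintf("unknown tissue '%s'", tissue), call. = FALSE)
  }
  slab <- as_plain_array(tensor)[, , , , , ti]
  dim(slab) <- c(d[1L], prod(d[2:5]))
  design <- expand.grid(time = seq_len(d[2L]), replicate = seq_len(d[3L]),
                        treatment = seq_len(d[4L]), strain = seq_len(d[5L]),
                        KEEP.OUT.ATTRS = FALSE)
  design <- cbind(sample_id = sprintf("%s_%03d", tissues[ti], seq_len(nrow(design))),
                  design, stringsAsFactors = FALSE)
  rownames(slab) <- dimnames(tensor)[[1L]]
  colnames(slab) <- design$sample_id
  structure(list(values = slab, design = design, tissue = tissues[ti]),
            class = "tissue_matrix")
}

baseline_result <- function(method, stats, threshold) {
  structure(list(method = method, stats = stats, threshold = threshold,
                 selected_ids = stats$probe_id[stats$selected]),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("baseline '%s': %d of %d probes selected (BH < %g)\n",
              x$method, length(x$selected_ids), nrow(x$stats), x$threshold))
  invisible(x)
}

split_treatment_groups <- function(tm) {
  g1 <- which(tm$design$treatment == 1L)
  g2 <- which(tm$design$treatment != 1L)
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("each treatment group needs >= 2 samples", call. = FALSE)
  }
  list(g1 = g1, g2 = g2)
}

# vectorized two-group moments with a variance floor for flat probes
group_moments <- function(x, idx, floor = 1e-12) {
  n <- length(idx)
  m <- rowMeans(x[, idx, drop = FALSE])
  v <- rowSums((x[, idx, drop = FALSE] - m)^2) / (n - 1L)
  floored <- v < floor
  v[floored] <- floor
  list(mean = m, var = v, n = n, floored = floored)
}

#' Per-probe Welch t-test probe selection
#'
#' Two-sided Welch (unequal-variance) t-test between the two treatment
#' arms, time points and replicates pooled as i.i.d. samples; BH
#' correction across probes.  Probes whose within-group variance
#' underflows are computed with a variance floor of 1e-12 and flagged in
#' the `var_floored` column.
#'
#' @param tm a `tissue_matrix` (or any list with `values` and a `design`
#'   containing a `treatment` column).
#' @param threshold BH-adjusted p-value cutoff (default 0.05).
#' @return a `baseline_result`; `stats` has columns `probe_id`,
#'   `statistic`, `df`, `p_raw`, `p_adj`, `selected`, `var_floored`.
#' @export
ttest_select <- function(tm, threshold = 0.05) {
  g <- split_treatment_groups(tm)
  a <- group_moments(tm$values, g$g1)
  b <- group_moments(tm$values, g$g2)
  se2 <- a$var / a$n + b$var / b$n
  tstat <- (a$mean - b$mean) / sqrt(se2)
  df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1L) + (b$var / b$n)^2 / (b$n - 1L))
  p_raw <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  stats <- data.frame(probe_id = rownames(tm$values), statistic = tstat,
                      df = df, p_raw = p_raw, p_adj = p_adj,
                      selected = p_adj < threshold,
                      var_floored = a$floored | b$floored,
                      stringsAsFactors = FALSE)
  baseline_result("ttest", stats, threshold)
}

sam_d_stat <- function(x, g1, g2, s0 = NULL) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  sp2 <- (rowSums((x[, g1, drop = FALSE] - m1)^2) +
            rowSums((x[, g2, drop = FALSE] - m2)^2)) / (n1 + n2 - 2L)
  s <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (is.null(s0)) s0 <- stats::median(s)
  list(d = (m1 - m2) / (s + s0), s = s, s0 = s0)
}

#' SAM-like permutation probe selection
#'
#' A regularized t-type statistic in the spirit of significance analysis
#' of microarrays: \eqn{d_i = (\bar x_{1i} - \bar x_{2i})/(s_i + s_0)}
#' with the fudge constant \eqn{s_0} set to the median of the per-probe
#' standard errors, so \eqn{|d_i|} stays finite as \eqn{s_i \to 0}.
#' Significance comes from permuting treatment labels and pooling the
#' permuted statistics across all probes into one null distribution
#' (\eqn{s_0} held fixed at its observed value); p-values are
#' BH-adjusted.  This is an approximation of SAM's statistic and
#' permutation scheme, not a replication of the `samr` package.
#'
#' @param tm a `tissue_matrix`.
#' @param threshold BH-adjusted cutoff (default 0.05).
#' @param n_permutations random label permutations (>= 50) when
#'   `exact = FALSE`.
#' @param seed mandatory RNG seed for the permutations.
#' @param exact enumerate all distinct label assignments instead of
#'   sampling (group sizes must keep the count below 10^5).
#' @return a `baseline_result`; `stats` has `probe_id`, `statistic`
#'   (d_i), `p_raw`, `p_adj`, `selected`.
#' @export
sam_like_select <- function(tm, threshold = 0.05, n_permutations = 300L,
                            seed, exact = FALSE) {
  g <- split_treatment_groups(tm)
  n <- length(g$g1) + length(g$g2)
  obs <- sam_d_stat(tm$values, g$g1, g$g2)
  n_splits <- choose(n, length(g$g1))
  if (exact) {
    if (n_splits > 1e5) {
      stop(sprintf("exact enumeration infeasible: %g label splits", n_splits),
           call. = FALSE)
    }
    combs <- utils::combn(n, length(g$g1))
    null_d <- vapply(seq_len(ncol(combs)), function(j) {
      i1 <- combs[, j]
      sam_d_stat(tm$values, i1, setdiff(seq_len(n), i1), s0 = obs$s0)$d
    }, numeric(nrow(tm$values)))
  } else {
    if (missing(seed)) stop("`seed` is required for random permutations", call. = FALSE)
    if (n_permutations < 50L) stop("n_permutations must be >= 50", call. = FALSE)
    if (n_splits < n_permutations) {
      stop(sprintf(
        "only %g distinct label assignments exist (< %d requested); use exact = TRUE to enumerate them",
        n_splits, n_permutations), call. = FALSE)
    }
    set.seed(seed)
    null_d <- vapply(seq_len(n_permutations), function(j) {
      i1 <- sample.int(n, length(g$g1))
      sam_d_stat(tm$values, i1, setdiff(seq_len(n), i1), s0 = obs$s0)$d
    }, numeric(nrow(tm$values)))
  }
  pooled <- sort(abs(as.numeric(null_d)))
  exceed <- length(pooled) - findInterval(abs(obs$d) - 1e-12, pooled)
  p_raw <- if (exact) {
    exceed / length(pooled)
  } else {
    (exceed + 1) / (length(pooled) + 1)
  }
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  stats <- data.frame(probe_id = rownames(tm$values), statistic = obs$d,
                      p_raw = p_raw, p_adj = p_adj, selected = p_adj < threshold,
                      stringsAsFactors = FALSE)
  res <- baseline_result("sam_like", stats, threshold)
  res$s0 <- obs$s0
  res
}

# method-of-moments fit of the scaled-F variance prior: s^2 ~ s0^2 F(df, d0)
fit_variance_prior <- function(s2, df) {
  m <- mean(s2)
  v <- stats::var(s2)
  r <- v / m^2
  # r = 2 (df + d0 - 2) / (df (d0 - 4)); solve for d0
  if (r * df <= 2) {
    d0 <- Inf
    s02 <- m
  } else {
    d0 <- (4 * r * df + 2 * df - 4) / (r * df - 2)
    if (d0 <= 4) {          # heavier tail than the model allows; cap
      d0 <- 4 + 1e-8
    }
    s02 <- m * (d0 - 2) / d0
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated t probe selection
#'
#' A moderated t-statistic in the style of the limma empirical-Bayes
#' approach, fit by method of moments rather than limma's
#' marginal-likelihood machinery (an approximation, labelled as such):
#' per-probe residual variances are modelled as \eqn{s_i^2 \sim s_0^2
#' F(d, d_0)}, the prior \eqn{(d_0, s_0^2)} is matched to the first two
#' moments of the observed \eqn{s_i^2}, each variance is shrunk to
#' \eqn{\tilde s_i^2 = (d_0 s_0^2 + d s_i^2)/(d_0 + d)}, and the t-test
#' is re-done with \eqn{\tilde s_i} on \eqn{d + d_0} degrees of freedom.
#'
#' @param tm a `tissue_matrix`.
#' @param threshold BH-adjusted cutoff (default 0.05).
#' @return a `baseline_result`; `stats` has `probe_id`, `statistic`,
#'   `df`, `p_raw`, `p_adj`, `selected`; the result also carries the
#'   fitted prior as `prior` (`d0`, `s02`).
#' @export
moderated_t_select <- function(tm, threshold = 0.05) {
  if (nrow(tm$values) < 3L) {
    stop("prior estimation needs at least 3 probes", call. = FALSE)
  }
  g <- split_treatment_groups(tm)
  n1 <- length(g$g1); n2 <- length(g$g2)
  df <- n1 + n2 - 2L
  m1 <- rowMeans(tm$values[, g$g1, drop = FALSE])
  m2 <- rowMeans(tm$values[, g$g2, drop = FALSE])
  s2 <- (rowSums((tm$values[, g$g1, drop = FALSE] - m1)^2) +
           rowSums((tm$values[, g$g2, drop = FALSE] - m2)^2)) / df
  prior <- fit_variance_prior(s2, df)
  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s02, length(s2))
  } else {
    (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
  }
  df_total <- df + prior$d0
  tstat <- (m1 - m2) / sqrt(s2_post * (1 / n1 + 1 / n2))
  p_raw <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  stats <- data.frame(probe_id = rownames(tm$values), statistic = tstat,
                      df = df_total, p_raw = p_raw, p_adj = p_adj,
                      selected = p_adj < threshold, stringsAsFactors = FALSE)
  res <- baseline_result("moderated_t", stats, threshold)
  res$prior <- prior
  res
}

#' ComBat-style cross-tissue batch adjustment
#'
#' Parametric empirical-Bayes location/scale batch correction with tissue
#' as batch, for the naive integrated analysis: per probe the data are
#' standardized by the grand mean and pooled variance, per-batch additive
#' (`gamma`) and multiplicative (`delta^2`) effects are estimated,
#' shrunk toward normal / inverse-gamma batch-level priors by the
#' standard iterative EB solution, and divided out.  The output matrix
#' pools all tissues' samples and feeds the same selectors
#' ([ttest_select()], [sam_like_select()], [moderated_t_select()]).
#'
#' @param tms list of `tissue_matrix` objects sharing a probe set
#'   (intersection taken, first matrix's order).
#' @param conv convergence tolerance of the EB iteration.
#' @return a `tissue_matrix` whose `design` gains `tissue`, with
#'   attributes `gamma_star` and `delta_star` (probe x batch matrices of
#'   the shrunken batch effects, on the standardized scale) plus
#'   `var_pooled` and `grand_mean` (the per-probe standardization; the
#'   additive batch effect in data units is `gamma_star *
#'   sqrt(var_pooled)`).
#' @export
combat_adjust <- function(tms, conv = 1e-4) {
  if (length(tms) < 2L) stop("need at least two batches (tissues)", call. = FALSE)
  probes <- rownames(tms[[1L]]$values)
  for (tm in tms[-1L]) probes <- probes[probes %in% rownames(tm$values)]
  if (!length(probes)) stop("empty probe intersection across batches", call. = FALSE)
  mats <- lapply(tms, function(tm) tm$values[probes, , drop = FALSE])
  nb <- vapply(mats, ncol, integer(1L))
  if (any(nb <= 1L)) stop("every batch needs > 1 sample", call. = FALSE)
  X <- do.call(cbind, mats)
  batch <- rep(seq_along(mats), nb)
  N <- ncol(X)
  B <- length(mats)

  batch_means <- vapply(seq_len(B), function(b)
    rowMeans(X[, batch == b, drop = FALSE]), numeric(nrow(X)))
  grand_mean <- as.numeric(batch_means %*% (nb / N))
  var_pooled <- rowSums((X - grand_mean)^2) / N
  if (any(var_pooled <= 0)) {
    stop("probe with zero pooled variance; cannot standardize", call. = FALSE)
  }
  Z <- (X - grand_mean) / sqrt(var_pooled)

  gamma_hat <- vapply(seq_len(B), function(b)
    rowMeans(Z[, batch == b, drop = FALSE]), numeric(nrow(Z)))
  delta_hat <- vapply(seq_len(B), function(b) {
    zb <- Z[, batch == b, drop = FALSE]
    rowSums((zb - rowMeans(zb))^2) / (ncol(zb) - 1L)
  }, numeric(nrow(Z)))

  gamma_bar <- colMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 2L, stats::var)
  # inverse-gamma prior on delta^2 by moments
  dm <- colMeans(delta_hat)
  dv <- apply(delta_hat, 2L, stats::var)
  a_prior <- (2 * dv + dm^2) / dv
  b_prior <- (dm * dv + dm^3) / dv

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(B)) {
    zb <- Z[, batch == b, drop = FALSE]
    n <- ncol(zb)
    g_old <- gamma_hat[, b]
    d_old <- delta_hat[, b]
    if (!is.finite(dv[b]) || dv[b] <= 0) {
      # within-batch variances (nearly) identical across probes: the
      # inverse-gamma prior is unidentifiable, so leave delta unshrunken
      # and take one location-shrinkage step
      gamma_star[, b] <- (tau2[b] * n * gamma_hat[, b] + d_old * gamma_bar[b]) /
        (tau2[b] * n + d_old)
      delta_star[, b] <- pmax(d_old, 1e-12)
      next
    }
    repeat {
      g_new <- (tau2[b] * n * gamma_hat[, b] + d_old * gamma_bar[b]) /
        (tau2[b] * n + d_old)
      ss <- rowSums((zb - g_new)^2)
      d_new <- (b_prior[b] + 0.5 * ss) / (n / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
      if (change < conv) break
    }
    gamma_star[, b] <- g_old
    delta_star[, b] <- d_old
  }

  Zadj <- Z
  for (b in seq_len(B)) {
    Zadj[, batch == b] <- (Z[, batch == b, drop = FALSE] - gamma_star[, b]) /
      sqrt(delta_star[, b])
  }
  Xadj <- Zadj * sqrt(var_pooled) + grand_mean

  design <- do.call(rbind, lapply(seq_along(tms), function(b) {
    de <- tms[[b]]$design
    de$tissue <- if (!is.null(tms[[b]]$tissue)) tms[[b]]$tissue else as.character(b)
    de
  }))
  design$sample_id <- make.unique(design$sample_id)
  colnames(Xadj) <- design$sample_id
  out <- structure(list(values = Xadj, design = design, tissue = "combined"),
                   class = "tissue_matrix")
  attr(out, "gamma_star") <- gamma_star
  attr(out, "delta_star") <- delta_star
  attr(out, "var_pooled") <- var_pooled
  attr(out, "grand_mean") <- grand_mean
  out
}
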