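# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately avoid the code paths they verify.

# BH step-up by hand: sort, multiply by m/rank, cumulative minimum from the
# largest p, clip at 1, restore order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail P(X >= k) as an explicit sum of choose() terms.
oracle_hyper_tail <- function(k, term_size, universe_size, list_size) {
  kk <- k:min(term_size, list_size)
  sum(choose(term_size, kk) * choose(universe_size - term_size,
                                     list_size - kk)) /
    choose(universe_size, list_size)
}

# Phase-grid cosinor oracle: for each candidate acrophase on a fine grid,
# regress y on cos(w*(t - phi)) (mesor + amplitude linear in that basis)
# and keep the phase minimising residual SSE. Returns phase and its SSE.
oracle_cosinor_grid <- function(y, zt, period = 24, step = 0.1) {
  w <- 2 * pi / period
  grid <- seq(0, period - step, by = step)
  best <- c(phase = NA_real_, sse = Inf)
  for (phi in grid) {
    X <- cbind(1, cos(w * (zt - phi)))
    fit <- lm.fit(X, y)
    sse <- sum(fit$residuals^2)
    if (sse < best["sse"] ||
        (sse == best["sse"] && fit$coefficients[2] >= 0)) {
      # negative fitted amplitude means the true peak is antipodal
      phase <- if (fit$coefficients[2] >= 0) phi else (phi + period / 2)
      best <- c(phase = phase %% period, sse = sse)
    }
  }
  best
}

# Z-score protein caller, recomputed from first principles.
oracle_protein_calls <- function(mean_test, mean_ctrl, loq, z_threshold = 2) {
  lfc <- ifelse(mean_test > 0 & mean_ctrl > 0,
                log2(mean_test / mean_ctrl), NA_real_)
  z <- (lfc - mean(lfc, na.rm = TRUE)) / sd(lfc, na.rm = TRUE)
  out <- character(length(lfc))
  for (i in seq_along(lfc)) {
    if (is.na(lfc[i]) || mean_test[i] <= loq || mean_ctrl[i] <= loq) {
      out[i] <- "not_evaluable"
    } else if (z[i] > z_threshold) {
      out[i] <- "up"
    } else if (z[i] < -z_threshold) {
      out[i] <- "down"
    } else {
      out[i] <- "unchanged"
    }
  }
  out
}

# Median-of-ratios size factors, loop form.
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(x) all(x > 0))
  geo <- apply(counts[keep, , drop = FALSE], 1,
               function(x) exp(mean(log(x))))
  sapply(seq_len(ncol(counts)), function(j)
    median(counts[keep, j] / geo))
}

# Pairwise-complete Pearson correlation recomputed per pair.
oracle_pairwise_cor <- function(x, min_obs = 3) {
  p <- ncol(x)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  for (i in 1:p) for (j in 1:p) {
    ok <- is.finite(x[, i]) & is.finite(x[, j])
    if (sum(ok) >= min_obs) r[i, j] <- cor(x[ok, i], x[ok, j])
  }
  diag(r) <- 1
  r
}

# Adjusted Rand index from the pair-counting formula.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Circular mean absolute error between estimated and true phases (hours).
circ_mae <- function(est, truth, period = 24) {
  d <- (est - truth) %% period
  d <- ifelse(d > period / 2, period - d, d)
  mean(d)
}
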