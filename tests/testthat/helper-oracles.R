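# Shared oracle utilities for the sampler tests.

# Kolmogorov distance between empirical draws and a reference CDF
# evaluated on a fine grid.
ks_distance <- function(draws, cdf_fun, grid = NULL) {
  if (is.null(grid)) {
    grid <- seq(stats::quantile(draws, 0.001),
                stats::quantile(draws, 0.999), length.out = 2000)
  }
  max(abs(stats::ecdf(draws)(grid) - cdf_fun(grid)))
}

# CDF of a density known up to a constant on a grid (trapezoid rule).
grid_cdf <- function(log_dens, grid) {
  d <- exp(log_dens - max(log_dens))
  dx <- diff(grid)
  cum <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * dx))
  cum <- cum / cum[length(cum)]
  stats::approxfun(grid, cum, yleft = 0, yright = 1)
}

# Batch-means standard error of the mean for an autocorrelated chain.
batch_se <- function(x, n_batches = 50) {
  m <- length(x) %/% n_batches
  bm <- colMeans(matrix(x[seq_len(m * n_batches)], nrow = m))
  stats::sd(bm) / sqrt(n_batches)
}
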