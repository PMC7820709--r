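#' Prior hyperparameters for the multilevel IRT samplers
#'
#' Conjugate priors: \eqn{a_k \sim N(\mu_a, \sigma_a^2) I(a_k > 0)},
#' \eqn{b_k \sim N(\mu_b, \sigma_b^2)},
#' \eqn{\beta \sim N_q(\Lambda_{0\beta}, H_{0\beta})},
#' \eqn{\omega^{-1} \sim} Gamma\eqn{(\alpha_{0\omega}, \beta_{0\omega})}
#' for the quantile model, and
#' \eqn{\alpha^2 \sim} Inverse-Gamma\eqn{(a_0, b_0)} for the
#' mean-regression baseline.  Defaults follow the weakly informative
#' choices used throughout the package's simulation protocol
#' (`sigma_a = 200`, `sigma_b = 100`, `beta_cov = 100 I`,
#' `omega_shape = 28`, `omega_rate = 4`).  Note the \eqn{\omega} prior is
#' in fact informative about the structural scale; it is exposed here
#' precisely so it can be changed.
#'
#' @param mu_a,sigma_a prior mean and SD of discriminations.
#' @param mu_b,sigma_b prior mean and SD of difficulties.
#' @param beta_mean prior mean of regression coefficients (scalar is
#'   recycled to length q at fit time).
#' @param beta_cov prior covariance of coefficients: scalar `c` means
#'   `c * I`, or give a full q x q positive-definite matrix.
#' @param omega_shape,omega_rate gamma prior on \eqn{\omega^{-1}}.
#' @param alpha2_shape,alpha2_rate inverse-gamma prior on the baseline
#'   model's structural variance \eqn{\alpha^2}.
#' @return Object of class `"qmlirt_priors"` (a list).
#' @export
qmlirt_priors <- function(mu_a = 0, sigma_a = 200,
                          mu_b = 0, sigma_b = 100,
                          beta_mean = 0, beta_cov = 100,
                          omega_shape = 28, omega_rate = 4,
                          alpha2_shape = 1, alpha2_rate = 1) {
  stopifnot(sigma_a > 0, sigma_b > 0, omega_shape > 0, omega_rate > 0,
            alpha2_shape > 0, alpha2_rate > 0)
  if (is.matrix(beta_cov)) {
    if (!isSymmetric(unname(beta_cov)) ||
        any(eigen(beta_cov, symmetric = TRUE,
                  only.values = TRUE)$values <= 0)) {
      stop("'beta_cov' must be symmetric positive definite", call. = FALSE)
    }
  } else if (length(beta_cov) != 1L || beta_cov <= 0) {
    stop("scalar 'beta_cov' must be positive", call. = FALSE)
  }
  structure(list(mu_a = mu_a, sigma_a = sigma_a,
                 mu_b = mu_b, sigma_b = sigma_b,
                 beta_mean = beta_mean, beta_cov = beta_cov,
                 omega_shape = omega_shape, omega_rate = omega_rate,
                 alpha2_shape = alpha2_shape, alpha2_rate = alpha2_rate),
            class = "qmlirt_priors")
}

# Expand scalar beta prior specifications to dimension q.
resolve_beta_prior <- function(hyper, q) {
  m <- hyper$beta_mean
  if (length(m) == 1L) m <- rep(m, q)
  if (length(m) != q) stop("beta prior mean has wrong length", call. = FALSE)
  V <- hyper$beta_cov
  if (!is.matrix(V)) V <- diag(V, q)
  if (!all(dim(V) == q)) stop("beta prior covariance has wrong dimension",
                              call. = FALSE)
  list(mean = m, cov = V, prec = solve(V))
}

#' Chain configuration for the Gibbs samplers
#'
#' @param n_iterations total Gibbs iterations per chain (default 10000,
#'   the package's reference protocol).
#' @param burn_in discarded initial iterations (default 5000).
#' @param thin keep every `thin`-th post-burn-in draw (default 1).
#' @param n_chains number of independent chains (default 1).
#' @param seed optional integer seed; when given, the fit is fully
#'   reproducible.
#' @param fit_intercept prepend a column of ones to the covariates?
#'   Default `TRUE` (empirical-style fits); recovery studies on generated
#'   data with known zero intercept typically set `FALSE`.
#' @return Object of class `"chain_config"`.
#' @export
chain_config <- function(n_iterations = 10000L, burn_in = 5000L,
                         thin = 1L, n_chains = 1L, seed = NULL,
                         fit_intercept = TRUE) {
  n_iterations <- as.integer(n_iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  n_chains <- as.integer(n_chains)
  if (burn_in >= n_iterations) {
    stop("'burn_in' must be smaller than 'n_iterations'", call. = FALSE)
  }
  if (thin < 1L) stop("'thin' must be at least 1", call. = FALSE)
  if (n_chains < 1L) stop("'n_chains' must be at least 1", call. = FALSE)
  if ((n_iterations - burn_in) %/% thin < 1L) {
    stop("configuration leaves no post-burn-in draws", call. = FALSE)
  }
  structure(list(n_iterations = n_iterations, burn_in = burn_in,
                 thin = thin, n_chains = n_chains, seed = seed,
                 fit_intercept = fit_intercept),
            class = "chain_config")
}
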