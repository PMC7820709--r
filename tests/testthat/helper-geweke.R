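# "Getting it right" joint-consistency harness on a tiny model (n = 6
# persons, K = 3 items, one covariate).  If every full conditional is
# correct, a chain started from an exact draw of the prior joint
# p(parameters) x p(data | parameters) stays in that distribution after
# any number of sweeps of {parameter updates given data, data
# re-simulation given parameters}.  We therefore run many independent
# replicates, each advanced a fixed number of sweeps from an exact prior
# start, and compare functionals of the end state against plain prior
# sampling with two-sample z-scores (all replicates i.i.d., so plain
# standard errors apply; a single long chain is useless here because
# omega mixes through rare heavy-tailed excursions).

geweke_setup <- function() {
  list(n = 6L, K = 3L, tau = 0.25,
       X = matrix(c(-1.2, -0.5, -0.1, 0.3, 0.8, 1.4), ncol = 1,
                  dimnames = list(NULL, "X1")),
       # Tight proper priors so all compared moments exist and the test
       # has power.
       hyper = qmlirt_priors(mu_a = 1, sigma_a = 0.5,
                             mu_b = 0, sigma_b = 0.5,
                             beta_mean = 0, beta_cov = 0.25,
                             omega_shape = 3, omega_rate = 2))
}

# Bounded/low-moment functionals: omega itself has an inverse-gamma tail
# whose fourth moment diverges, so its tail is monitored through an
# indicator rather than a second moment.
geweke_functionals <- function(items, beta, omega, y) {
  c(a2 = items$a[2], a3 = items$a[3], b2 = items$b[2], b3 = items$b[3],
    beta = beta[1], omega = omega, om_lt1 = as.numeric(omega < 1),
    ybar = mean(y))
}

geweke_prior_draw <- function(su) {
  h <- su$hyper
  a <- qmlirt:::rtnorm_lower0(rep(h$mu_a, su$K), h$sigma_a)
  b <- stats::rnorm(su$K, h$mu_b, h$sigma_b)
  items <- item_bank(a, b, anchor = 1L)
  beta <- stats::rnorm(1, h$beta_mean, sqrt(h$beta_cov))
  omega <- 1 / stats::rgamma(1, h$omega_shape, rate = h$omega_rate)
  e <- stats::rexp(su$n, rate = 1 / omega)
  spec <- quantile_spec(su$tau)
  theta <- stats::rnorm(su$n, drop(su$X %*% beta) + spec$k1 * e,
                        sqrt(spec$k2 * omega * e))
  list(items = items, beta = beta, omega = omega, e = e, theta = theta)
}

geweke_marginal <- function(n_draws, su) {
  out <- NULL
  for (r in seq_len(n_draws)) {
    st <- geweke_prior_draw(su)
    y <- simulate_responses(st$theta, st$items)
    f <- geweke_functionals(st$items, st$beta, st$omega, y)
    if (is.null(out)) {
      out <- matrix(NA_real_, n_draws, length(f),
                    dimnames = list(NULL, names(f)))
    }
    out[r, ] <- f
  }
  out
}

geweke_successive <- function(n_draws, su, sweeps = 15L) {
  h <- su$hyper
  spec <- quantile_spec(su$tau)
  out <- NULL
  for (r in seq_len(n_draws)) {
    st <- geweke_prior_draw(su)
    items <- st$items; beta <- st$beta; omega <- st$omega
    e <- st$e; theta <- st$theta
    y <- simulate_responses(theta, items)
    for (ss in seq_len(sweeps)) {
      z <- sample_augmented_z(y, theta, items)
      items$a <- sample_discrimination(z, theta, items, h)
      items$b <- sample_difficulty(z, theta, items, h)
      theta <- sample_ability(z, items,
                              prior_mean = drop(su$X %*% beta) +
                                spec$k1 * e,
                              prior_var = spec$k2 * omega * e)
      omega <- sample_omega(theta, su$X, beta, spec, h)
      e <- sample_latent_e(theta, su$X, beta, omega, spec)
      beta <- sample_beta(theta, su$X, e, omega, spec, h)
      y <- simulate_responses(theta, items)
    }
    f <- geweke_functionals(items, beta, omega, y)
    if (is.null(out)) {
      out <- matrix(NA_real_, n_draws, length(f),
                    dimnames = list(NULL, names(f)))
    }
    out[r, ] <- f
  }
  out
}

# Two-sample z-scores on the first moments (both samples i.i.d.).
geweke_zscores <- function(marg, succ) {
  zs <- c()
  for (j in colnames(marg)) {
    se <- sqrt(stats::var(marg[, j]) / nrow(marg) +
                 stats::var(succ[, j]) / nrow(succ))
    zs[j] <- (mean(marg[, j]) - mean(succ[, j])) / se
  }
  zs
}
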