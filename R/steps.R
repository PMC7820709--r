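# Vectorized pure-R implementations of the full conditionals that make up
# one Gibbs sweep.  These are the reference implementations: each one is
# tested against a closed-form, moment, or grid-normalization oracle, and
# the compiled engine in src/ is cross-checked against chains built from
# these functions.  All of them draw from R's global random stream.

# N(0,1) truncated to (lo, Inf) shifted by mu: numerically stable
# inverse-CDF sampler for N(mu, sd^2) truncated below at 0.
rtnorm_lower0 <- function(mu, sd = 1) {
  u <- stats::runif(length(mu))
  p <- pmax(stats::pnorm(mu / sd), 1e-300)     # P(draw > 0)
  mu + sd * stats::qnorm(u * p, lower.tail = FALSE)
}

# N(mu, sd^2) truncated above at 0.
rtnorm_upper0 <- function(mu, sd = 1) {
  u <- stats::runif(length(mu))
  p <- pmax(stats::pnorm(-mu / sd), 1e-300)    # P(draw < 0)
  mu + sd * stats::qnorm(u * p)
}

# Inverse-Gaussian(mean, shape) draws; transformation-with-rejection
# scheme, with the small root computed through the product of roots to
# avoid catastrophic cancellation at large mean*y/shape.
rinvgauss <- function(n, mean, shape) {
  mean <- rep_len(mean, n); shape <- rep_len(shape, n)
  y <- stats::rnorm(n)^2
  xplus <- mean + mean^2 * y / (2 * shape) +
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  xminus <- mean^2 / xplus
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + xminus), xminus, xplus)
}

#' Gibbs step 1: augmented probit data z
#'
#' Each observed cell gets \eqn{z_{ik} \sim N(a_k(\theta_i - b_k), 1)}
#' truncated to \eqn{(0,\infty)} when \eqn{y_{ik} = 1} and to
#' \eqn{(-\infty,0]} when \eqn{y_{ik} = 0}; missing cells stay `NA`.
#'
#' @param responses 0/1/`NA` response matrix.
#' @param theta ability vector.
#' @param items an [item_bank()].
#' @return Matrix `z` with `NA` exactly at missing cells.
#' @export
sample_augmented_z <- function(responses, theta, items) {
  y <- as.matrix(responses)
  n <- nrow(y); K <- ncol(y)
  eta <- outer(theta, items$b, "-") * matrix(items$a, n, K, byrow = TRUE)
  z <- matrix(NA_real_, n, K)
  pos <- which(!is.na(y) & y == 1L)
  neg <- which(!is.na(y) & y == 0L)
  z[pos] <- rtnorm_lower0(eta[pos])
  z[neg] <- rtnorm_upper0(eta[neg])
  z
}

#' Gibbs step 2: discriminations
#'
#' Conjugate update \eqn{a_k \sim N(m_k, v_k) I(a_k > 0)} with
#' \eqn{v_k = (1/\sigma_a^2 + \sum_i (\theta_i - b_k)^2)^{-1}} and
#' \eqn{m_k = v_k(\mu_a/\sigma_a^2 + \sum_i z_{ik}(\theta_i - b_k))},
#' sums over persons with observed responses to item k.  The anchor item
#' is never updated.
#'
#' @param z augmented data matrix (`NA` at missing cells).
#' @param theta ability vector.
#' @param items current [item_bank()] (provides `b` and the anchor).
#' @param hyper a [qmlirt_priors()].
#' @param moments if `TRUE`, return the conditional means/SDs instead of
#'   a draw (used by the test oracles).
#' @return Updated discrimination vector, or `list(mean, sd)`.
#' @export
sample_discrimination <- function(z, theta, items, hyper = qmlirt_priors(),
                                  moments = FALSE) {
  obs <- !is.na(z)
  if (any(colSums(obs) == 0L)) {
    stop("degenerate item: no observed responses", call. = FALSE)
  }
  zz <- z; zz[!obs] <- 0
  D <- outer(theta, items$b, "-")
  sa2 <- hyper$sigma_a^2
  v <- 1 / (1 / sa2 + colSums(D^2 * obs))
  m <- v * (hyper$mu_a / sa2 + colSums(zz * D))
  if (moments) return(list(mean = m, sd = sqrt(v)))
  a <- rtnorm_lower0(m, sqrt(v))
  a[items$anchor] <- items$a[items$anchor]
  a
}

#' Gibbs step 3: difficulties
#'
#' Conjugate update \eqn{b_k \sim N(m_k, v_k)} with
#' \eqn{v_k = (1/\sigma_b^2 + n_k a_k^2)^{-1}} and
#' \eqn{m_k = v_k(\mu_b/\sigma_b^2 - a_k \sum_i (z_{ik} - a_k\theta_i))},
#' \eqn{n_k} the number of observed responses to item k.  Anchor skipped.
#'
#' @inheritParams sample_discrimination
#' @return Updated difficulty vector, or `list(mean, sd)`.
#' @export
sample_difficulty <- function(z, theta, items, hyper = qmlirt_priors(),
                              moments = FALSE) {
  obs <- !is.na(z)
  nk <- colSums(obs)
  if (any(nk == 0L)) {
    stop("degenerate item: no observed responses", call. = FALSE)
  }
  zz <- z; zz[!obs] <- 0
  a <- items$a
  sb2 <- hyper$sigma_b^2
  v <- 1 / (1 / sb2 + nk * a^2)
  s <- colSums(zz) - a * colSums(theta * obs)   # sum over obs of z - a*theta
  m <- v * (hyper$mu_b / sb2 - a * s)
  if (moments) return(list(mean = m, sd = sqrt(v)))
  b <- stats::rnorm(length(a), m, sqrt(v))
  b[items$anchor] <- items$b[items$anchor]
  b
}

#' Gibbs step 4: abilities
#'
#' Conjugate normal update for each person given a normal structural
#' prior \eqn{N(\mu_{\theta i}, \sigma^2_{\theta i})}:
#' \eqn{v_i = (1/\sigma^2_{\theta i} + \sum_k a_k^2)^{-1}},
#' \eqn{m_i = v_i(\mu_{\theta i}/\sigma^2_{\theta i} +
#'   \sum_k a_k(z_{ik} + a_k b_k))}, sums over the person's observed
#' items.  For the quantile model pass
#' \eqn{\mu_\theta = X\beta_\tau + k_1 e}, \eqn{\sigma^2_\theta = k_2
#' \omega e}; for the mean-regression baseline \eqn{\mu_\theta = X\beta},
#' \eqn{\sigma^2_\theta = \alpha^2}.
#'
#' @param z augmented data matrix.
#' @param items an [item_bank()].
#' @param prior_mean per-person structural prior means.
#' @param prior_var per-person structural prior variances (scalar
#'   recycled).
#' @param moments if `TRUE`, return conditional means/SDs.
#' @return Updated ability vector, or `list(mean, sd)`.
#' @export
sample_ability <- function(z, items, prior_mean, prior_var,
                           moments = FALSE) {
  obs <- !is.na(z)
  zz <- z; zz[!obs] <- 0
  a <- items$a; b <- items$b
  n <- nrow(z)
  prior_var <- rep_len(prior_var, n)
  Sa2 <- drop(obs %*% a^2)
  Szb <- drop(zz %*% a) + drop(obs %*% (a^2 * b))
  v <- 1 / (1 / prior_var + Sa2)
  m <- v * (prior_mean / prior_var + Szb)
  if (moments) return(list(mean = m, sd = sqrt(v)))
  stats::rnorm(n, m, sqrt(v))
}

#' Gibbs step 5: asymmetric-Laplace scale omega
#'
#' Collapsed (over the exponential mixing variables) conjugate update:
#' \eqn{\omega^{-1} \sim} Gamma\eqn{(n + \alpha_{0\omega},\;
#' \beta_{0\omega} + \sum_i \rho_\tau(\theta_i - X_i^T\beta_\tau))}.
#'
#' @param theta ability vector.
#' @param X covariate matrix (persons x q).
#' @param beta current regression coefficients.
#' @param spec a [quantile_spec()] or quantile level.
#' @param hyper a [qmlirt_priors()].
#' @param moments if `TRUE`, return the gamma `list(shape, rate)` of
#'   \eqn{\omega^{-1}}.
#' @return Updated scalar `omega`, or the shape/rate pair.
#' @export
sample_omega <- function(theta, X, beta, spec, hyper = qmlirt_priors(),
                         moments = FALSE) {
  spec <- as_quantile_spec(spec)
  resid <- theta - drop(X %*% beta)
  shape <- length(theta) + hyper$omega_shape
  rate <- hyper$omega_rate + sum(check_loss(resid, spec))
  if (moments) return(list(shape = shape, rate = rate))
  1 / stats::rgamma(1, shape = shape, rate = rate)
}

#' Gibbs step 6: latent exponential mixing variables e
#'
#' \eqn{e_i^{-1}} follows an inverse-Gaussian distribution with mean
#' \eqn{\sqrt{2k_2 + k_1^2}\,/\,|\theta_i - X_i^T\beta_\tau|} and shape
#' \eqn{(2k_2 + k_1^2)/(k_2\omega)}; \eqn{e_i} is the reciprocal of the
#' draw.  A residual of exactly zero (measure-zero event) is clamped to
#' `1e-8` in absolute value for numerical stability.
#'
#' @inheritParams sample_omega
#' @param omega current scale.
#' @param moments if `TRUE`, return the inverse-Gaussian
#'   `list(mean, shape)` for \eqn{e_i^{-1}}.
#' @return Updated vector `e` of positive mixing variables.
#' @export
sample_latent_e <- function(theta, X, beta, omega, spec,
                            moments = FALSE) {
  spec <- as_quantile_spec(spec)
  r <- pmax(abs(theta - drop(X %*% beta)), 1e-8)
  c2 <- 2 * spec$k2 + spec$k1^2
  mu <- sqrt(c2) / r
  lam <- c2 / (spec$k2 * omega)
  if (moments) return(list(mean = mu, shape = lam))
  1 / rinvgauss(length(r), mu, lam)
}

#' Gibbs step 7: quantile-regression coefficients
#'
#' Multivariate normal update with precision
#' \eqn{\Sigma_\beta = H_{0\beta}^{-1} + \sum_i X_i X_i^T/(k_2\omega e_i)}
#' and mean \eqn{\Sigma_\beta^{-1}(H_{0\beta}^{-1}\Lambda_{0\beta} +
#' \sum_i (\theta_i - k_1 e_i) X_i/(k_2\omega e_i))}.
#'
#' @inheritParams sample_latent_e
#' @param e current mixing variables.
#' @param moments if `TRUE`, return `list(mean, cov)`.
#' @return Updated coefficient vector.
#' @export
sample_beta <- function(theta, X, e, omega, spec,
                        hyper = qmlirt_priors(), moments = FALSE) {
  spec <- as_quantile_spec(spec)
  q <- ncol(X)
  pr <- resolve_beta_prior(hyper, q)
  w <- 1 / (spec$k2 * omega * e)
  prec <- pr$prec + crossprod(X, X * w)
  rhs <- drop(pr$prec %*% pr$mean) + drop(crossprod(X, (theta - spec$k1 * e) * w))
  draw_mvn(prec, rhs, moments)
}

# Shared multivariate-normal draw from precision matrix and linear term.
draw_mvn <- function(prec, rhs, moments = FALSE) {
  U <- tryCatch(chol(prec), error = function(e) {
    stop("singular precision: collinear covariates", call. = FALSE)
  })
  m <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
  if (moments) return(list(mean = m, cov = chol2inv(U)))
  m + backsolve(U, stats::rnorm(length(rhs)))
}

#' Baseline structural update: linear-regression coefficients
#'
#' Standard conjugate normal update for the mean-regression model:
#' precision \eqn{H_{0\beta}^{-1} + X^TX/\alpha^2}, linear term
#' \eqn{H_{0\beta}^{-1}\Lambda_{0\beta} + X^T\theta/\alpha^2}.
#'
#' @inheritParams sample_omega
#' @param alpha2 current structural error variance.
#' @param moments if `TRUE`, return `list(mean, cov)`.
#' @return Updated coefficient vector.
#' @export
sample_beta_lr <- function(theta, X, alpha2, hyper = qmlirt_priors(),
                           moments = FALSE) {
  pr <- resolve_beta_prior(hyper, ncol(X))
  prec <- pr$prec + crossprod(X) / alpha2
  rhs <- drop(pr$prec %*% pr$mean) + drop(crossprod(X, theta)) / alpha2
  draw_mvn(prec, rhs, moments)
}

#' Baseline structural update: error variance
#'
#' \eqn{\alpha^2 \sim} Inverse-Gamma\eqn{(a_0 + n/2,\;
#' b_0 + \sum_i(\theta_i - X_i^T\beta)^2/2)}.
#'
#' @inheritParams sample_beta_lr
#' @param beta current coefficients.
#' @param moments if `TRUE`, return `list(shape, rate)`.
#' @return Updated scalar variance.
#' @export
sample_alpha2 <- function(theta, X, beta, hyper = qmlirt_priors(),
                          moments = FALSE) {
  resid <- theta - drop(X %*% beta)
  shape <- hyper$alpha2_shape + length(theta) / 2
  rate <- hyper$alpha2_rate + sum(resid^2) / 2
  if (moments) return(list(shape = shape, rate = rate))
  1 / stats::rgamma(1, shape = shape, rate = rate)
}

#' Baseline ability update
#'
#' The normal-prior specialization of [sample_ability()] with
#' \eqn{\mu_\theta = X\beta}, \eqn{\sigma^2_\theta = \alpha^2}.
#'
#' @inheritParams sample_ability
#' @param X covariate matrix.
#' @param beta current coefficients.
#' @param alpha2 structural error variance.
#' @export
sample_ability_lr <- function(z, items, X, beta, alpha2,
                              moments = FALSE) {
  sample_ability(z, items, prior_mean = drop(X %*% beta),
                 prior_var = alpha2, moments = moments)
}
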