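#' Quantile specification with asymmetric-Laplace mixture constants
#'
#' For a quantile level \eqn{\tau \in (0,1)} the asymmetric Laplace
#' distribution (ALD) admits a normal-exponential mixture representation:
#' conditional on a latent exponential variable \eqn{e} with mean
#' \eqn{\omega}, an ALD\eqn{(\mu,\omega,\tau)} variate is
#' \eqn{N(\mu + k_1 e,\; k_2 \omega e)}, where
#' \deqn{k_1 = \frac{1-2\tau}{\tau(1-\tau)}, \qquad
#'       k_2 = \frac{2}{\tau(1-\tau)}.}
#' This object carries \eqn{\tau} together with the two derived constants;
#' every sampler and density in the package takes one.
#'
#' @param tau quantile level, a single number strictly between 0 and 1.
#' @return An object of class `"quantile_spec"`: a list with elements
#'   `tau`, `k1`, `k2`.
#' @examples
#' quantile_spec(0.5)   # k1 = 0, k2 = 8
#' quantile_spec(0.25)  # k1 = 8/3, k2 = 32/3
#' @export
quantile_spec <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau <= 0 || tau >= 1) {
    stop("'tau' must be a single number in the open interval (0, 1)",
         call. = FALSE)
  }
  kk <- mixture_constants(tau)
  structure(list(tau = tau, k1 = kk[["k1"]], k2 = kk[["k2"]]),
            class = "quantile_spec")
}

#' @export
print.quantile_spec <- function(x, ...) {
  cat(sprintf("Quantile level tau = %g (k1 = %.6g, k2 = %.6g)\n",
              x$tau, x$k1, x$k2))
  invisible(x)
}

as_quantile_spec <- function(x) {
  if (inherits(x, "quantile_spec")) x else quantile_spec(x)
}

#' Mixture constants of the asymmetric Laplace representation
#'
#' @param tau quantile level in (0, 1).
#' @return Named numeric vector `c(k1 = , k2 = )` with
#'   \eqn{k_1 = (1-2\tau)/(\tau(1-\tau))} and
#'   \eqn{k_2 = 2/(\tau(1-\tau))}.
#' @export
mixture_constants <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau <= 0 || tau >= 1) {
    stop("'tau' must be a single number in the open interval (0, 1)",
         call. = FALSE)
  }
  d <- tau * (1 - tau)
  c(k1 = (1 - 2 * tau) / d, k2 = 2 / d)
}

#' Quantile-regression check loss
#'
#' The check (pinball) function
#' \eqn{\rho_\tau(u) = u\,(\tau - I(u < 0))}, i.e. \eqn{u\tau} for
#' \eqn{u \ge 0} and \eqn{u(\tau - 1)} for \eqn{u < 0}.  Vectorized in `u`.
#'
#' @param u numeric vector of residuals.
#' @param spec a [quantile_spec()] or a bare quantile level.
#' @return Nonnegative numeric vector, same length as `u`.
#' @export
check_loss <- function(u, spec) {
  spec <- as_quantile_spec(spec)
  u * (spec$tau - (u < 0))
}

#' Asymmetric Laplace log-density
#'
#' Density \eqn{f(u) = \frac{\tau(1-\tau)}{\omega}
#' \exp\{-\rho_\tau(u-\mu)/\omega\}}; its \eqn{\tau}th quantile equals
#' `location`.  This parameterization is the one under which the latent
#' scale \eqn{\omega} has a conjugate gamma update for \eqn{\omega^{-1}}.
#'
#' @param u numeric vector of evaluation points.
#' @param location ALD location \eqn{\mu} (the \eqn{\tau}th quantile).
#' @param scale positive scale \eqn{\omega}.
#' @param spec a [quantile_spec()] or quantile level.
#' @return Numeric vector of log-densities.
#' @export
ald_logpdf <- function(u, location = 0, scale = 1, spec = 0.5) {
  spec <- as_quantile_spec(spec)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("'scale' must be a single positive number", call. = FALSE)
  }
  log(spec$tau * (1 - spec$tau) / scale) -
    check_loss(u - location, spec) / scale
}

#' Sample from the asymmetric Laplace distribution
#'
#' Draws via the normal-exponential mixture: \eqn{e \sim} Exponential with
#' mean \eqn{\omega}, then \eqn{u \sim N(\mu + k_1 e,\; k_2 \omega e)}.
#' Uses R's global random stream, so draws are reproducible under
#' [set.seed()].
#'
#' @inheritParams ald_logpdf
#' @param n number of draws.
#' @return Numeric vector of `n` i.i.d. draws.
#' @export
sample_ald <- function(n, location = 0, scale = 1, spec = 0.5) {
  spec <- as_quantile_spec(spec)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("'scale' must be a single positive number", call. = FALSE)
  }
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  e <- stats::rexp(n, rate = 1 / scale)
  stats::rnorm(n, mean = location + spec$k1 * e,
               sd = sqrt(spec$k2 * scale * e))
}
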