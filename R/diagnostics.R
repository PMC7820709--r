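# Scale-comparison, convergence, and model-comparison diagnostics.

#' Cosine similarity of discrimination vectors
#'
#' Uncentered cosine \eqn{\sum_k a_k a^*_k / (\|a\|\,\|a^*\|)}.  Item
#' parameters estimated on two latent scales related by
#' \eqn{\theta^* = p\theta + t} satisfy \eqn{a^*_k = a_k / p}, under
#' which this metric is exactly 1 — so it compares discrimination
#' patterns while ignoring the arbitrary scale unit.
#'
#' @param a,a_star numeric vectors of equal length (at least 2) with
#'   nonzero norms.
#' @return Scalar in \eqn{[-1, 1]}.
#' @export
cos_similarity_discrimination <- function(a, a_star) {
  if (length(a) != length(a_star) || length(a) < 2L) {
    stop("'a' and 'a_star' must have equal length >= 2", call. = FALSE)
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(a_star^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  }
  sum(a * a_star) / (na * nb)
}

#' Cosine similarity of difficulty vectors
#'
#' Centered cosine (numerically the Pearson correlation):
#' \deqn{\frac{\sum_k (b_k - \bar b)(b^*_k - \bar b^*)}
#'  {\sqrt{\sum_k (b_k - \bar b)^2}\sqrt{\sum_k (b^*_k - \bar b^*)^2}}.}
#' Under an affine scale change \eqn{b^*_k = p\,b_k + t} with
#' \eqn{p > 0} this is exactly 1 (and \eqn{-1} for \eqn{p < 0}), so it
#' compares difficulty orderings across latent scales.
#'
#' @param b,b_star numeric vectors of equal length (at least 2), neither
#'   constant.
#' @return Scalar in \eqn{[-1, 1]}.
#' @export
cos_similarity_difficulty <- function(b, b_star) {
  if (length(b) != length(b_star) || length(b) < 2L) {
    stop("'b' and 'b_star' must have equal length >= 2", call. = FALSE)
  }
  db <- b - mean(b); ds <- b_star - mean(b_star)
  nb <- sqrt(sum(db^2)); ns <- sqrt(sum(ds^2))
  if (nb == 0 || ns == 0) {
    stop("cosine similarity undefined for a constant vector",
         call. = FALSE)
  }
  sum(db * ds) / (nb * ns)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' For m chains of n draws each, with within-chain variance W (mean of
#' the chain sample variances) and between-chain variance
#' \eqn{B = n \cdot \mathrm{Var}(\bar x_j)}:
#' \deqn{\widehat R = \sqrt{\frac{(n-1)W/n + B/n}{W}}.}
#' Values near 1 indicate convergence; the package's working threshold
#' is 1.10.  A single chain is split into halves.  Zero within-chain
#' variance (e.g. the fixed anchor item) is undefined and yields `NA`.
#'
#' @param x a list of numeric vectors (one per chain), a draws x chains
#'   matrix, a single numeric vector (split in two), or a fitted
#'   [qmlirt()]/[mmlirt()] object (returns one value per parameter).
#' @param ... unused.
#' @return Scalar PSRF, or a named vector for fit objects.
#' @export
psrf <- function(x, ...) UseMethod("psrf")

#' @export
psrf.default <- function(x, ...) {
  if (is.matrix(x)) x <- lapply(seq_len(ncol(x)), function(j) x[, j])
  if (is.numeric(x)) {
    n2 <- length(x) %/% 2L
    x <- list(x[seq_len(n2)], x[seq_len(n2) + n2])
  }
  if (!is.list(x) || length(x) < 2L) {
    stop("need at least 2 chains (or one chain to split)", call. = FALSE)
  }
  n <- unique(lengths(x))
  if (length(n) != 1L || n < 2L) {
    stop("chains must have equal length >= 2", call. = FALSE)
  }
  W <- mean(vapply(x, stats::var, numeric(1)))
  if (W == 0) return(NA_real_)
  B <- n * stats::var(vapply(x, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
psrf.mlirt_fit <- function(x, include_theta = TRUE, ...) {
  scale_name <- if (x$model == "qmlirt") "omega" else "alpha2"
  blocks <- list(beta = lapply(x$chains, `[[`, "beta"),
                 a = lapply(x$chains, `[[`, "a"),
                 b = lapply(x$chains, `[[`, "b"))
  blocks[[scale_name]] <- lapply(x$chains, function(ch) {
    matrix(ch[[scale_name]], ncol = 1)
  })
  if (include_theta && !is.null(x$chains[[1]]$theta)) {
    blocks$theta <- lapply(x$chains, `[[`, "theta")
  }
  out <- c()
  for (nm in names(blocks)) {
    mats <- blocks[[nm]]
    p <- ncol(mats[[1]])
    vals <- vapply(seq_len(p), function(j) {
      chains <- lapply(mats, function(m) m[, j])
      if (length(chains) == 1L) chains <- chains[[1]]
      psrf(chains)
    }, numeric(1))
    names(vals) <- if (p == 1L) nm else paste0(nm, "[", seq_len(p), "]")
    out <- c(out, vals)
  }
  out
}

#' Joint deviance of the quantile model at one parameter configuration
#'
#' Evaluates \eqn{-2\log f(\theta, Z \mid \xi, \beta_\tau, \omega, e)}
#' with \eqn{f(Z|\theta,\xi)} the product of \eqn{N(a_k(\theta_i-b_k),1)}
#' densities over observed cells and \eqn{f(\theta|\beta_\tau,\omega,e)}
#' the conditional normal \eqn{N(X^T\beta_\tau + k_1 e, k_2\omega e)} of
#' the ALD mixture representation.
#'
#' @param responses 0/1/`NA` matrix.
#' @param X covariate matrix.
#' @param z augmented-data matrix.
#' @param theta,a,b,beta,omega,e parameter values.
#' @param spec a [quantile_spec()] or quantile level.
#' @param anchor anchor item index (for reconstructing the item bank).
#' @return Scalar deviance.
#' @export
joint_deviance_q <- function(responses, X, z, theta, a, b, beta, omega,
                             e, spec, anchor = 1L) {
  spec <- as_quantile_spec(spec)
  items <- item_bank(a, b, anchor, identified = FALSE)
  m <- drop(X %*% beta) + spec$k1 * e
  s <- sqrt(spec$k2 * omega * e)
  aug_meas_deviance(responses, z, theta, items) -
    2 * sum(stats::dnorm(theta, m, s, log = TRUE))
}

#' Joint deviance of the mean-regression baseline
#'
#' As [joint_deviance_q()] but with the normal structural density
#' \eqn{f(\theta \mid \beta, \alpha^2) = N(X^T\beta, \alpha^2)}.
#'
#' @inheritParams joint_deviance_q
#' @param alpha2 structural error variance.
#' @export
joint_deviance_m <- function(responses, X, z, theta, a, b, beta, alpha2,
                             anchor = 1L) {
  items <- item_bank(a, b, anchor, identified = FALSE)
  aug_meas_deviance(responses, z, theta, items) -
    2 * sum(stats::dnorm(theta, drop(X %*% beta), sqrt(alpha2),
                         log = TRUE))
}

#' Joint deviance information criterion
#'
#' Computes \eqn{\bar D} (posterior mean deviance), \eqn{\hat D}
#' (deviance at the posterior means of all conditioned quantities,
#' including the augmented data), \eqn{p_D = \bar D - \hat D}, and
#' \eqn{DIC = \bar D + p_D = 2\bar D - \hat D}, using the joint
#' (hierarchical) likelihood conditioned on parameters at all levels.
#' The headline number evaluates the measurement level on the
#' augmented-data scale; `scale = "observed"` substitutes the Bernoulli
#' likelihood of the observed responses as a sensitivity check.
#'
#' @param fit a fitted [qmlirt()] or [mmlirt()] object.
#' @param scale `"augmented"` (default) or `"observed"`.
#' @return Object of class `"dic_report"`: list with `dic`, `dbar`,
#'   `dhat`, `pd`, `model`, `scale`, and `pd_negative` (flags the
#'   irregular case \eqn{p_D < 0}).
#' @export
joint_dic <- function(fit, scale = c("augmented", "observed")) {
  scale <- match.arg(scale)
  if (!inherits(fit, "mlirt_fit")) {
    stop("'fit' must be a qmlirt/mmlirt fit", call. = FALSE)
  }
  dev_name <- if (scale == "augmented") "deviance" else "deviance_obs"
  devs <- unlist(lapply(fit$chains, `[[`, dev_name))
  if (is.null(devs)) {
    stop("fit does not carry the stored deviance draws", call. = FALSE)
  }
  dbar <- mean(devs)
  m <- fit$means
  struct_dev <- if (fit$model == "qmlirt") {
    -2 * sum(stats::dnorm(m$theta,
                          drop(fit$X %*% m$beta) + fit$spec$k1 * m$e,
                          sqrt(fit$spec$k2 * m$omega * m$e), log = TRUE))
  } else {
    -2 * sum(stats::dnorm(m$theta, drop(fit$X %*% m$beta),
                          sqrt(m$alpha2), log = TRUE))
  }
  meas_dev <- if (scale == "augmented") {
    items <- item_bank(m$a, m$b, fit$anchor, identified = FALSE)
    zbar <- m$z
    zbar[is.na(fit$responses)] <- NA_real_
    aug_meas_deviance(fit$responses, zbar, m$theta, items)
  } else {
    items <- item_bank(m$a, m$b, fit$anchor, identified = FALSE)
    -2 * response_loglik(fit$responses, m$theta, items)
  }
  dhat <- meas_dev + struct_dev
  pd <- dbar - dhat
  structure(list(dic = dbar + pd, dbar = dbar, dhat = dhat, pd = pd,
                 model = fit$model, scale = scale,
                 pd_negative = pd < 0),
            class = "dic_report")
}

#' @export
print.dic_report <- function(x, ...) {
  cat(sprintf("Joint DIC (%s, %s scale)\n", x$model, x$scale))
  cat(sprintf("  DIC = %.1f  (Dbar = %.1f, Dhat = %.1f, pD = %.1f)\n",
              x$dic, x$dbar, x$dhat, x$pd))
  if (x$pd_negative) {
    cat("  warning: pD < 0 (irregular posterior geometry)\n")
  }
  invisible(x)
}
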