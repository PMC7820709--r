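#' Fit the quantile multilevel IRT model
#'
#' Runs the seven-step Gibbs sampler for the two-level model
#' \deqn{P(Y_{ik} = 1 \mid \theta_i) = \Phi(a_k(\theta_i - b_k)), \qquad
#'       \theta_i = X_i^T\beta_\tau + \delta_i,}
#' where the structural error \eqn{\delta_i} carries the asymmetric
#' Laplace working likelihood ALD\eqn{(0, \omega, \tau)} so that
#' \eqn{X_i^T\beta_\tau} is the \eqn{\tau}th conditional quantile of the
#' latent trait.  One item (the anchor) has its parameters fixed at
#' \eqn{(a, b) = (1, 0)} to identify the latent scale.  Each sweep
#' updates, in order: the augmented probit data \eqn{z}, discriminations
#' \eqn{a}, difficulties \eqn{b}, abilities \eqn{\theta}, the ALD scale
#' \eqn{\omega} (collapsed over the mixing variables), the exponential
#' mixing variables \eqn{e}, and the coefficients \eqn{\beta_\tau}.
#'
#' @param responses persons x items 0/1/`NA` matrix (see
#'   [response_matrix()]).
#' @param covariates persons x q numeric matrix or data frame of
#'   person-level covariates (an intercept column is added when
#'   `config$fit_intercept` is `TRUE`).
#' @param tau quantile level in (0, 1), or a [quantile_spec()].
#' @param config a [chain_config()].
#' @param hyper a [qmlirt_priors()].
#' @param anchor index of the item fixed at \eqn{(a,b) = (1,0)}.
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation built from the exported `sample_*` steps; identical
#'   model, much slower — used for cross-validation).
#' @param store_theta keep per-draw ability vectors (needed for PSRF on
#'   \eqn{\theta}; posterior means/SDs are always returned).
#' @return Object of class `c("qmlirt_fit", "mlirt_fit")` with elements
#'   `posterior` (summary data frame), `chains` (per-chain draws),
#'   `means` (posterior means of all blocks, including the augmented
#'   data needed for DIC), and the inputs.
#' @seealso [mmlirt()], [joint_dic()], [psrf()]
#' @examples
#' \donttest{
#' set.seed(1)
#' dat <- simulate_study_data(case = 1, tau = 0.5, n = 150, K = 10)
#' fit <- qmlirt(dat$responses, dat$covariates, tau = 0.5,
#'               config = chain_config(600, 300, seed = 1,
#'                                     fit_intercept = FALSE))
#' coef(fit)
#' }
#' @export
qmlirt <- function(responses, covariates, tau = 0.5,
                   config = chain_config(), hyper = qmlirt_priors(),
                   anchor = 1L, engine = c("cpp", "R"),
                   store_theta = FALSE) {
  engine <- match.arg(engine)
  spec <- as_quantile_spec(tau)
  fit_mlirt(responses, covariates, spec, config, hyper, anchor, engine,
            store_theta, model = "qmlirt")
}

#' Fit the mean-regression multilevel IRT baseline
#'
#' Identical 2PNO measurement level, but the structural model is ordinary
#' linear regression \eqn{\theta_i = X_i^T\beta + \delta_i},
#' \eqn{\delta_i \sim N(0, \alpha^2)}, with conjugate
#' normal/inverse-gamma updates.  With symmetric structural errors its
#' coefficient posterior agrees with the quantile model at
#' \eqn{\tau = 0.5}.
#'
#' @inheritParams qmlirt
#' @return Object of class `c("mmlirt_fit", "mlirt_fit")`.
#' @export
mmlirt <- function(responses, covariates, config = chain_config(),
                   hyper = qmlirt_priors(), anchor = 1L,
                   engine = c("cpp", "R"), store_theta = FALSE) {
  engine <- match.arg(engine)
  fit_mlirt(responses, covariates, spec = NULL, config, hyper, anchor,
            engine, store_theta, model = "mmlirt")
}

# Shared driver for both model families.
fit_mlirt <- function(responses, covariates, spec, config, hyper, anchor,
                      engine, store_theta, model) {
  y <- response_matrix(responses)
  X <- prepare_covariates(covariates, nrow(y), config$fit_intercept)
  n <- nrow(y); K <- ncol(y); q <- ncol(X)
  anchor <- as.integer(anchor)
  if (anchor < 1L || anchor > K) stop("'anchor' out of range", call. = FALSE)
  pr <- resolve_beta_prior(hyper, q)
  hyper_resolved <- hyper
  hyper_resolved$beta_mean <- pr$mean
  hyper_resolved$beta_cov <- pr$cov

  if (!is.null(config$seed)) set.seed(config$seed)
  chains <- vector("list", config$n_chains)
  for (j in seq_len(config$n_chains)) {
    init <- init_state(n, K, q, anchor, jitter = j > 1L)
    chains[[j]] <- if (model == "qmlirt") {
      run_q_chain(y, X, spec, hyper_resolved, anchor, config,
                  store_theta, init, engine)
    } else {
      run_m_chain(y, X, hyper_resolved, anchor, config,
                  store_theta, init, engine)
    }
  }

  scale_name <- if (model == "qmlirt") "omega" else "alpha2"
  par_names <- c(paste0("beta[", colnames(X), "]"), scale_name,
                 paste0("a[", seq_len(K), "]"), paste0("b[", seq_len(K), "]"))
  draw_mat <- function(ch) {
    cbind(ch$beta, ch[[scale_name]], ch$a, ch$b)
  }
  pooled <- do.call(rbind, lapply(chains, draw_mat))
  colnames(pooled) <- par_names
  post <- data.frame(parameter = par_names,
                     mean = colMeans(pooled),
                     sd = apply(pooled, 2, stats::sd),
                     row.names = NULL)
  if (config$n_chains >= 2L) {
    post$psrf <- vapply(seq_along(par_names), function(p) {
      psrf(lapply(chains, function(ch) draw_mat(ch)[, p]))
    }, numeric(1))
  }

  means <- list(beta = stats::setNames(colMeans(do.call(
                  rbind, lapply(chains, function(ch) ch$beta))), colnames(X)),
                a = colMeans(do.call(rbind, lapply(chains, `[[`, "a"))),
                b = colMeans(do.call(rbind, lapply(chains, `[[`, "b"))),
                theta = Reduce(`+`, lapply(chains, `[[`, "theta_mean")) /
                  length(chains),
                z = Reduce(`+`, lapply(chains, `[[`, "z_mean")) /
                  length(chains))
  means[[scale_name]] <- mean(unlist(lapply(chains, `[[`, scale_name)))
  if (model == "qmlirt") {
    means$e <- Reduce(`+`, lapply(chains, `[[`, "e_mean")) / length(chains)
  }

  structure(list(model = model, spec = spec, posterior = post,
                 chains = chains, means = means, responses = y, X = X,
                 anchor = anchor, config = config, hyper = hyper_resolved,
                 engine = engine, n = n, K = K, q = q),
            class = c(paste0(substr(model, 1, 1), "mlirt_fit"),
                      "mlirt_fit"))
}

prepare_covariates <- function(covariates, n, fit_intercept) {
  X <- as.matrix(covariates)
  if (!is.numeric(X)) stop("covariates must be numeric", call. = FALSE)
  if (nrow(X) != n) {
    stop(sprintf("covariates have %d rows but responses have %d persons",
                 nrow(X), n), call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (fit_intercept) {
    X <- cbind("(Intercept)" = 1, X)
  }
  X
}

# Starting values: neutral for all blocks except theta, which must start
# dispersed -- with theta identically 0 the first discrimination update
# has an empty likelihood term and the diffuse prior (sigma_a = 200)
# launches a_k into the hundreds, trapping the chain in a collapsed-scale
# mode.  Later chains are additionally jittered so multi-chain PSRF
# starts are mildly overdispersed.
init_state <- function(n, K, q, anchor, jitter = FALSE) {
  init <- list(theta = stats::rnorm(n), a = rep(1, K), b = numeric(K),
               beta = numeric(q), omega = 1, alpha2 = 1, e = rep(1, n))
  if (jitter) {
    # a few posterior-scale units of dispersion: enough for PSRF to be
    # an honest between-chain diagnostic, small enough that the default
    # burn-in absorbs the transient
    init$beta <- stats::rnorm(q, 0, 0.15)
    init$omega <- exp(stats::rnorm(1, 0, 0.3))
    init$alpha2 <- exp(stats::rnorm(1, 0, 0.3))
    init$a <- pmax(0.3, 1 + stats::rnorm(K, 0, 0.1))
    init$b <- stats::rnorm(K, 0, 0.15)
  }
  init$a[anchor] <- 1
  init$b[anchor] <- 0
  init
}

run_q_chain <- function(y, X, spec, hyper, anchor, config, store_theta,
                        init, engine) {
  ch <- if (engine == "cpp") {
    qmlirt_chain_cpp(y, X, spec$tau, hyper, anchor, config$n_iterations,
                     config$burn_in, config$thin, store_theta, init)
  } else {
    run_q_chain_r(y, X, spec, hyper, anchor, config, store_theta, init)
  }
  normalize_chain(ch)
}

run_m_chain <- function(y, X, hyper, anchor, config, store_theta, init,
                        engine) {
  ch <- if (engine == "cpp") {
    mmlirt_chain_cpp(y, X, hyper, anchor, config$n_iterations,
                     config$burn_in, config$thin, store_theta, init)
  } else {
    run_m_chain_r(y, X, hyper, anchor, config, store_theta, init)
  }
  normalize_chain(ch)
}

# The compiled engine wraps arma::vec results as n x 1 matrices; flatten
# the vector-valued components so both engines return the same shapes.
normalize_chain <- function(ch) {
  for (nm in c("omega", "alpha2", "deviance", "deviance_obs",
               "theta_mean", "theta_sd", "e_mean")) {
    if (!is.null(ch[[nm]])) ch[[nm]] <- drop(ch[[nm]])
  }
  ch
}

# Pure-R chain built from the exported step functions; same sweep order
# and outputs as the compiled engine.
run_q_chain_r <- function(y, X, spec, hyper, anchor, config, store_theta,
                          init) {
  n <- nrow(y); K <- ncol(y); q <- ncol(X)
  theta <- init$theta; beta <- init$beta; omega <- init$omega; e <- init$e
  items <- item_bank(init$a, init$b, anchor)
  n_keep <- (config$n_iterations - config$burn_in) %/% config$thin
  keep <- list(beta = matrix(NA_real_, n_keep, q),
               a = matrix(NA_real_, n_keep, K),
               b = matrix(NA_real_, n_keep, K),
               omega = numeric(n_keep), deviance = numeric(n_keep),
               deviance_obs = numeric(n_keep))
  if (store_theta) keep$theta <- matrix(NA_real_, n_keep, n)
  sum_theta <- sumsq_theta <- numeric(n); sum_e <- numeric(n)
  sum_z <- matrix(0, n, K)
  kept <- 0L
  for (it in seq_len(config$n_iterations)) {
    z <- sample_augmented_z(y, theta, items)
    items$a <- sample_discrimination(z, theta, items, hyper)
    items$b <- sample_difficulty(z, theta, items, hyper)
    xb <- drop(X %*% beta)
    theta <- sample_ability(z, items, prior_mean = xb + spec$k1 * e,
                            prior_var = spec$k2 * omega * e)
    omega <- sample_omega(theta, X, beta, spec, hyper)
    e <- sample_latent_e(theta, X, beta, omega, spec)
    beta <- sample_beta(theta, X, e, omega, spec, hyper)
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      keep$beta[kept, ] <- beta
      keep$a[kept, ] <- items$a
      keep$b[kept, ] <- items$b
      keep$omega[kept] <- omega
      if (store_theta) keep$theta[kept, ] <- theta
      sum_theta <- sum_theta + theta
      sumsq_theta <- sumsq_theta + theta^2
      sum_e <- sum_e + e
      zz <- z; zz[is.na(zz)] <- 0
      sum_z <- sum_z + zz
      dev_s <- -2 * sum(stats::dnorm(theta, drop(X %*% beta) + spec$k1 * e,
                                     sqrt(spec$k2 * omega * e), log = TRUE))
      keep$deviance[kept] <- aug_meas_deviance(y, z, theta, items) + dev_s
      keep$deviance_obs[kept] <-
        -2 * response_loglik(y, theta, items) + dev_s
    }
  }
  keep$theta_mean <- sum_theta / kept
  keep$theta_sd <- sqrt(pmax(sumsq_theta / kept - (sum_theta / kept)^2, 0))
  keep$e_mean <- sum_e / kept
  keep$z_mean <- sum_z / kept
  keep
}

run_m_chain_r <- function(y, X, hyper, anchor, config, store_theta, init) {
  n <- nrow(y); K <- ncol(y); q <- ncol(X)
  theta <- init$theta; beta <- init$beta; alpha2 <- init$alpha2
  items <- item_bank(init$a, init$b, anchor)
  n_keep <- (config$n_iterations - config$burn_in) %/% config$thin
  keep <- list(beta = matrix(NA_real_, n_keep, q),
               a = matrix(NA_real_, n_keep, K),
               b = matrix(NA_real_, n_keep, K),
               alpha2 = numeric(n_keep), deviance = numeric(n_keep),
               deviance_obs = numeric(n_keep))
  if (store_theta) keep$theta <- matrix(NA_real_, n_keep, n)
  sum_theta <- sumsq_theta <- numeric(n)
  sum_z <- matrix(0, n, K)
  kept <- 0L
  for (it in seq_len(config$n_iterations)) {
    z <- sample_augmented_z(y, theta, items)
    items$a <- sample_discrimination(z, theta, items, hyper)
    items$b <- sample_difficulty(z, theta, items, hyper)
    theta <- sample_ability_lr(z, items, X, beta, alpha2)
    alpha2 <- sample_alpha2(theta, X, beta, hyper)
    beta <- sample_beta_lr(theta, X, alpha2, hyper)
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      keep$beta[kept, ] <- beta
      keep$a[kept, ] <- items$a
      keep$b[kept, ] <- items$b
      keep$alpha2[kept] <- alpha2
      if (store_theta) keep$theta[kept, ] <- theta
      sum_theta <- sum_theta + theta
      sumsq_theta <- sumsq_theta + theta^2
      zz <- z; zz[is.na(zz)] <- 0
      sum_z <- sum_z + zz
      dev_s <- -2 * sum(stats::dnorm(theta, drop(X %*% beta),
                                     sqrt(alpha2), log = TRUE))
      keep$deviance[kept] <- aug_meas_deviance(y, z, theta, items) + dev_s
      keep$deviance_obs[kept] <-
        -2 * response_loglik(y, theta, items) + dev_s
    }
  }
  keep$theta_mean <- sum_theta / kept
  keep$theta_sd <- sqrt(pmax(sumsq_theta / kept - (sum_theta / kept)^2, 0))
  keep$z_mean <- sum_z / kept
  keep
}

# -2 log f(Z | theta, xi): augmented measurement deviance at observed cells.
aug_meas_deviance <- function(y, z, theta, items) {
  eta <- outer(theta, items$b, "-") *
    matrix(items$a, nrow(z), ncol(z), byrow = TRUE)
  obs <- !is.na(as.matrix(y))
  -2 * sum(stats::dnorm(z[obs], eta[obs], 1, log = TRUE))
}

#' @export
print.mlirt_fit <- function(x, ...) {
  label <- if (x$model == "qmlirt") {
    sprintf("Quantile MLIRT fit (tau = %g)", x$spec$tau)
  } else "Mean-regression MLIRT fit"
  cat(label, "\n")
  cat(sprintf("  %d persons, %d items (anchor %d), %d covariate column(s)\n",
              x$n, x$K, x$anchor, x$q))
  cat(sprintf("  %d chain(s) x %d iterations (burn-in %d, thin %d)\n",
              x$config$n_chains, x$config$n_iterations, x$config$burn_in,
              x$config$thin))
  cat("Structural coefficients (posterior mean +/- sd):\n")
  bet <- x$posterior[grepl("^beta", x$posterior$parameter), ]
  for (r in seq_len(nrow(bet))) {
    cat(sprintf("  %-22s %8.4f +/- %.4f\n", bet$parameter[r],
                bet$mean[r], bet$sd[r]))
  }
  invisible(x)
}

#' @export
summary.mlirt_fit <- function(object, ...) {
  object$posterior
}

#' @export
coef.mlirt_fit <- function(object, ...) {
  object$means$beta
}
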