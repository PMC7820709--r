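# Synthetic-data generation and the parameter-recovery study harness.
#
# The generator reproduces a three-case design for the structural errors
# of the latent trait, with true slopes beta = (0.5, 0.5) on two
# independent standard-normal covariates:
#   case 1: delta ~ N(0, variance 0.5)            (normal, homoscedastic)
#   case 2: theta = v - rho_tau |v| + |v| delta,  delta ~ N(0,1),
#           v = 0.5 X1 + 0.5 X2, rho_tau = qnorm(tau)   (heteroscedastic;
#           its tau-th conditional quantile is exactly v for every tau)
#   case 3: delta ~ Gamma(shape 0.5, scale 1) - 0.5      (skewed)
# Throughout, "N(mean, v)" is read as variance v (SD sqrt(v)).

#' Generate standard-normal covariates
#'
#' @param n number of persons.
#' @return n x 2 matrix with columns `X1`, `X2`, i.i.d. N(0, 1).
#' @export
gen_covariates <- function(n) {
  stopifnot(n >= 1)
  matrix(stats::rnorm(2 * n), n, 2, dimnames = list(NULL, c("X1", "X2")))
}

#' Generate item parameters
#'
#' Discriminations \eqn{a_k \sim U(0.5, 1.5)} and difficulties
#' \eqn{b_k \sim N(0, \mathrm{var}\ 0.5)}; item 1 is then set to the
#' anchor values \eqn{(a, b) = (1, 0)}, so the data-generating truth and
#' the identification constraint coincide.
#'
#' @param K number of items (at least 2).
#' @param b_var difficulty variance (default 0.5; exposed so the
#'   SD-versus-variance reading of the design can be probed).
#' @return An [item_bank()] with anchor item 1.
#' @export
gen_item_params <- function(K, b_var = 0.5) {
  stopifnot(K >= 2)
  a <- stats::runif(K, 0.5, 1.5)
  b <- stats::rnorm(K, 0, sqrt(b_var))
  item_bank(a, b, anchor = 1L)
}

#' Generate latent abilities under one structural case
#'
#' @param case structural case, 1, 2 or 3 (see the case formulas above).
#' @param covariates n x 2 matrix from [gen_covariates()].
#' @param tau quantile level; used only by case 2, whose construction
#'   centers the \eqn{\tau}th conditional quantile at
#'   \eqn{0.5 X_1 + 0.5 X_2}.
#' @param beta_true true slopes (default `c(0.5, 0.5)`).
#' @param error_var case-1 error variance (default 0.5).
#' @return Numeric vector of abilities.
#' @export
gen_ability <- function(case, covariates, tau = 0.5,
                        beta_true = c(0.5, 0.5), error_var = 0.5) {
  v <- drop(covariates %*% beta_true)
  n <- length(v)
  switch(as.character(case),
    "1" = v + stats::rnorm(n, 0, sqrt(error_var)),
    "2" = {
      rho <- stats::qnorm(tau)
      delta <- stats::rnorm(n)
      v - rho * abs(v) + abs(v) * delta
    },
    "3" = v + stats::rgamma(n, shape = 0.5, scale = 1) - 0.5,
    stop("unknown structural case: ", case, call. = FALSE)
  )
}

#' True quantile-regression coefficients of each structural case
#'
#' The slopes are (0.5, 0.5) for every \eqn{\tau}; the intercept is the
#' \eqn{\tau}th quantile of the case's error law (identically 0 for
#' case 2 by construction).
#'
#' @param case structural case id.
#' @param tau quantile level.
#' @param error_var case-1 error variance.
#' @return Named vector `c(beta0, beta1, beta2)`.
#' @export
true_quantile_coefs <- function(case, tau, error_var = 0.5) {
  b0 <- switch(as.character(case),
    "1" = stats::qnorm(tau, 0, sqrt(error_var)),
    "2" = 0,
    "3" = stats::qgamma(tau, shape = 0.5, scale = 1) - 0.5,
    stop("unknown structural case: ", case, call. = FALSE)
  )
  c(beta0 = b0, beta1 = 0.5, beta2 = 0.5)
}

#' Simulate one complete study dataset
#'
#' Covariates, item parameters, abilities under the chosen structural
#' case, and 2PNO responses, bundled with the generating truth.
#'
#' @inheritParams gen_ability
#' @param n persons; K items.
#' @param K number of items.
#' @param missing_mask optional logical matrix forwarded to
#'   [simulate_responses()].
#' @return List with `responses`, `covariates`, `theta`, `items`,
#'   `truth` (the [true_quantile_coefs()]), `case`, `tau`.
#' @export
simulate_study_data <- function(case, tau, n, K, beta_true = c(0.5, 0.5),
                                error_var = 0.5, missing_mask = NULL) {
  X <- gen_covariates(n)
  items <- gen_item_params(K)
  theta <- gen_ability(case, X, tau, beta_true, error_var)
  y <- simulate_responses(theta, items, missing_mask)
  list(responses = y, covariates = X, theta = theta, items = items,
       truth = true_quantile_coefs(case, tau, error_var),
       case = case, tau = tau)
}

#' Run one replication of the recovery study
#'
#' Simulates a dataset and fits the quantile model at the condition's
#' \eqn{\tau} (and the mean-regression baseline when requested) on the
#' same data.  The fitted structural model has no intercept: the slopes
#' are the recovery targets, any \eqn{\tau}-dependent location shift is
#' absorbed by the item difficulties, and item recovery is judged by the
#' affine-invariant cosine metrics.
#'
#' @inheritParams simulate_study_data
#' @param seed integer seed for this replication (data generation and
#'   both fits consume one stream seeded here).
#' @param methods subset of `c("Q", "M")`.
#' @param n_iterations,burn_in chain protocol (defaults 3000/1500, the
#'   desk-scale protocol; the reference protocol is 10000/5000).
#' @return One-row data frame per method with slope estimates, item
#'   summaries, and cosine similarities against the generating truth.
#' @export
run_replication <- function(case, tau, n, K, seed,
                            methods = c("Q", "M"),
                            n_iterations = 3000L, burn_in = 1500L,
                            beta_true = c(0.5, 0.5), error_var = 0.5) {
  set.seed(as.integer(seed))
  dat <- simulate_study_data(case, tau, n, K, beta_true, error_var)
  cfg <- chain_config(n_iterations, burn_in, fit_intercept = FALSE)
  rows <- list()
  for (mth in methods) {
    fit <- if (mth == "Q") {
      qmlirt(dat$responses, dat$covariates, tau = tau, config = cfg)
    } else {
      mmlirt(dat$responses, dat$covariates, config = cfg)
    }
    est_a <- fit$means$a; est_b <- fit$means$b
    rows[[mth]] <- data.frame(
      case = case, tau = tau, n = n, K = K, method = mth, seed = seed,
      beta1_hat = unname(fit$means$beta[1]),
      beta2_hat = unname(fit$means$beta[2]),
      cos_a = cos_similarity_discrimination(dat$items$a, est_a),
      cos_b = cos_similarity_difficulty(dat$items$b, est_b),
      bias_a = mean(est_a - dat$items$a),
      bias_b = mean(est_b - dat$items$b),
      rmse_a = sqrt(mean((est_a - dat$items$a)^2)),
      rmse_b = sqrt(mean((est_b - dat$items$b)^2)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run a parameter-recovery study over replications
#'
#' Replication r uses seed `base_seed + r`, so any row can be reproduced
#' in isolation and Q/M comparisons within a replication share the same
#' simulated data.
#'
#' @inheritParams run_replication
#' @param n_replications number of replications.
#' @param base_seed base integer seed.
#' @param progress print a line per replication.
#' @return Data frame of per-replication rows (see [run_replication()]).
#' @export
run_study <- function(case, tau, n, K, n_replications = 20L,
                      base_seed = 1L, methods = c("Q", "M"),
                      n_iterations = 3000L, burn_in = 1500L,
                      beta_true = c(0.5, 0.5), error_var = 0.5,
                      progress = FALSE) {
  reps <- lapply(seq_len(n_replications), function(r) {
    if (progress) {
      message(sprintf("replication %d/%d (case %s, tau %g, n %d, K %d)",
                      r, n_replications, case, tau, n, K))
    }
    run_replication(case, tau, n, K, seed = base_seed + r,
                    methods = methods, n_iterations = n_iterations,
                    burn_in = burn_in, beta_true = beta_true,
                    error_var = error_var)
  })
  do.call(rbind, reps)
}

#' Summarize a recovery study
#'
#' Per (case, n, K, method, tau) cell: average bias and RMSE of the
#' slope estimates about the truth 0.5, the item bias/RMSE averaged over
#' items and replications, and the average cosine similarities.
#'
#' @param replications data frame from [run_study()] (possibly several
#'   bound together).
#' @param beta_truth true slope value (default 0.5).
#' @return Data frame, one row per condition cell.
#' @export
summarize_study <- function(replications, beta_truth = 0.5) {
  key <- interaction(replications$case, replications$n, replications$K,
                     replications$method, replications$tau, drop = TRUE)
  cells <- split(replications, key)
  out <- lapply(cells, function(d) {
    e1 <- d$beta1_hat - beta_truth
    e2 <- d$beta2_hat - beta_truth
    data.frame(case = d$case[1], n = d$n[1], K = d$K[1],
               method = d$method[1], tau = d$tau[1],
               n_replications = nrow(d),
               bias_beta1 = mean(e1), rmse_beta1 = sqrt(mean(e1^2)),
               bias_beta2 = mean(e2), rmse_beta2 = sqrt(mean(e2^2)),
               cos_a = mean(d$cos_a), cos_b = mean(d$cos_b),
               bias_a = mean(d$bias_a), rmse_a = mean(d$rmse_a),
               bias_b = mean(d$bias_b), rmse_b = mean(d$rmse_b))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$case, out$n, out$K, out$method, out$tau), ]
}
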