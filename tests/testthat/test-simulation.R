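# Synthetic-data generator and study-summary machinery.

test_that("covariates are independent standard normals", {
  set.seed(91)
  X <- gen_covariates(1e5)
  expect_equal(dim(X), c(1e5, 2))
  expect_lt(max(abs(colMeans(X))), 0.02)
  expect_lt(max(abs(apply(X, 2, var) - 1)), 0.02)
  expect_lt(abs(cor(X[, 1], X[, 2])), 0.02)
  set.seed(5); a <- gen_covariates(10)
  set.seed(5); b <- gen_covariates(10)
  expect_identical(a, b)
})

test_that("item parameters follow the design with a fixed anchor", {
  set.seed(92)
  items <- gen_item_params(1e4)
  expect_true(all(items$a >= 0.5 & items$a <= 1.5))
  expect_equal(items$a[1], 1)
  expect_equal(items$b[1], 0)
  expect_equal(var(items$b[-1]), 0.5, tolerance = 0.06)
})

test_that("ability generation honors each case's quantile structure", {
  set.seed(93)
  X <- gen_covariates(2e5)
  v <- drop(X %*% c(0.5, 0.5))
  # case 1: symmetric errors, conditional median at v
  th1 <- gen_ability(1, X)
  expect_lt(abs(median(th1 - v)), 0.01)
  expect_equal(var(th1 - v), 0.5, tolerance = 0.02)
  # case 2: P(theta <= v) = tau for every tau, by construction
  for (tau in c(0.25, 0.5, 0.75)) {
    th2 <- gen_ability(2, X, tau)
    expect_equal(mean(th2 <= v), tau, tolerance = 0.01)
  }
  # case 3: centered gamma errors have mean zero
  th3 <- gen_ability(3, X)
  expect_lt(abs(mean(th3 - v)), 0.01)
  expect_error(gen_ability(4, X), "unknown structural case")
})

test_that("true quantile coefficients match independent quantile oracles", {
  expect_equal(true_quantile_coefs(1, 0.5), c(beta0 = 0, beta1 = 0.5,
                                              beta2 = 0.5))
  for (tau in c(0.25, 0.5, 0.75)) {
    expect_equal(unname(true_quantile_coefs(2, tau)), c(0, 0.5, 0.5))
    # case 1: root-find the normal CDF rather than trust qnorm reuse
    q1 <- uniroot(function(x) pnorm(x, 0, sqrt(0.5)) - tau,
                  c(-5, 5), tol = 1e-10)$root
    expect_equal(true_quantile_coefs(1, tau)[["beta0"]], q1,
                 tolerance = 1e-7)
    # case 3: root-find the gamma CDF
    q3 <- uniroot(function(x) pgamma(x, 0.5, scale = 1) - tau,
                  c(1e-12, 20), tol = 1e-12)$root
    expect_equal(true_quantile_coefs(3, tau)[["beta0"]], q3 - 0.5,
                 tolerance = 1e-7)
  }
})

test_that("study summaries satisfy their algebraic identities", {
  rep_row <- function(b1, b2) {
    data.frame(case = 1, tau = 0.5, n = 100, K = 5, method = "Q",
               seed = 1, beta1_hat = b1, beta2_hat = b2,
               cos_a = 1, cos_b = 1, bias_a = 0, bias_b = 0,
               rmse_a = 0, rmse_b = 0)
  }
  # estimates identical to the truth
  perfect <- do.call(rbind, replicate(5, rep_row(0.5, 0.5),
                                      simplify = FALSE))
  s <- summarize_study(perfect)
  expect_equal(s$bias_beta1, 0)
  expect_equal(s$rmse_beta1, 0)
  expect_equal(s$cos_a, 1)
  # constant offset c: bias c, RMSE |c|
  off <- do.call(rbind, replicate(4, rep_row(0.5 - 0.03, 0.5 + 0.02),
                                  simplify = FALSE))
  s2 <- summarize_study(off)
  expect_equal(s2$bias_beta1, -0.03)
  expect_equal(s2$rmse_beta1, 0.03)
  expect_equal(s2$bias_beta2, 0.02)
  # RMSE^2 = bias^2 + population variance
  set.seed(94)
  est <- 0.5 + rnorm(40, 0.01, 0.05)
  rows <- do.call(rbind, lapply(est, function(b) rep_row(b, b)))
  s3 <- summarize_study(rows)
  e <- est - 0.5
  expect_equal(s3$rmse_beta1^2, s3$bias_beta1^2 + mean((e - mean(e))^2),
               tolerance = 1e-12)
  expect_true(all(s3$rmse_beta1 >= abs(s3$bias_beta1)))
})

test_that("replications are reproducible and well-formed", {
  r1 <- run_replication(case = 1, tau = 0.5, n = 60, K = 5, seed = 42,
                        methods = c("Q", "M"), n_iterations = 400,
                        burn_in = 200)
  r2 <- run_replication(case = 1, tau = 0.5, n = 60, K = 5, seed = 42,
                        methods = c("Q", "M"), n_iterations = 400,
                        burn_in = 200)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2)
  expect_true(all(is.finite(unlist(r1[, c("beta1_hat", "beta2_hat",
                                          "cos_a", "cos_b")]))))
  expect_true(all(r1$cos_a <= 1 & r1$cos_a >= -1))
})

test_that("error shrinks with sample size on matched seeds", {
  # scaled-down check of the n = 500 -> 2000 monotone trend: 3
  # replications per size with short chains, compared through RMSE
  r_small <- run_study(1, 0.5, 500, 10, n_replications = 3,
                       base_seed = 500, methods = "Q",
                       n_iterations = 1200, burn_in = 600)
  r_large <- run_study(1, 0.5, 2000, 10, n_replications = 3,
                       base_seed = 500, methods = "Q",
                       n_iterations = 1200, burn_in = 600)
  expect_lt(summarize_study(r_large)$rmse_beta1,
            summarize_study(r_small)$rmse_beta1)
})
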