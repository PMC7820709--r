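# Full-conditional oracles and chain-level contracts for the quantile
# sampler.

test_that("augmented-data draws respect truncation and their law", {
  items <- item_bank(1, 0)
  # y = 1 at linear predictor 0: left-truncated standard normal
  set.seed(51)
  y1 <- matrix(1L, 1e5, 1)
  z1 <- sample_augmented_z(y1, rep(0, 1e5), items)
  expect_true(all(z1 > 0))
  # half-normal mean sqrt(2/pi), 4-sigma band
  expect_equal(mean(z1), sqrt(2 / pi),
               tolerance = 4 * sqrt(1 - 2 / pi) / sqrt(1e5) / sqrt(2 / pi))
  # y = 0 at linear predictor -1.3: Kolmogorov distance against the
  # truncated-normal CDF
  y0 <- matrix(0L, 1e5, 1)
  z0 <- sample_augmented_z(y0, rep(-1.3, 1e5), items)
  expect_true(all(z0 <= 0))
  cdf <- function(z) pnorm(pmin(z, 0), -1.3, 1) / pnorm(0, -1.3, 1)
  expect_lt(ks_distance(z0, cdf), 0.01)
  # missing cells stay missing
  ym <- matrix(c(1L, NA, 0L, 1L), 2)
  zm <- sample_augmented_z(ym, c(0, 0), item_bank(c(1, 1), c(0, 0)))
  expect_identical(is.na(zm), is.na(ym))
})

test_that("discrimination update matches the conjugate closed form", {
  items <- item_bank(c(1, 1), c(0, 0), identified = FALSE)
  z <- matrix(c(2, -2), 2, 2)        # two persons, two items
  theta <- c(1, -1)                  # theta - b = (1, -1)
  # flat-prior limit: posterior mean -> least-squares slope = 2
  mom <- sample_discrimination(z, theta, items,
                               qmlirt_priors(sigma_a = 1e6),
                               moments = TRUE)
  expect_equal(mom$mean[2], 2, tolerance = 1e-6)
  # default prior (sigma_a = 200): hand plug-in of the update
  mom2 <- sample_discrimination(z, theta, items, qmlirt_priors(),
                                moments = TRUE)
  v <- 1 / (1 / 200^2 + 2)
  expect_equal(mom2$mean[2], v * 4, tolerance = 1e-12)
  expect_equal(mom2$sd[2], sqrt(v), tolerance = 1e-12)
  # positivity of the truncated draw even when the mean is negative
  set.seed(52)
  zneg <- matrix(rep(c(-3, 3), 50), 100, 2)
  a <- sample_discrimination(zneg, rep(c(1, -1), 50),
                             item_bank(c(1, 1), c(0, 0)), qmlirt_priors())
  expect_true(all(a > 0))
  # anchor invariance across repeated updates
  items3 <- item_bank(c(1, 1.2), c(0, 0.1))
  set.seed(53)
  zz <- matrix(rnorm(200), 100, 2)
  for (r in 1:50) {
    items3$a <- sample_discrimination(zz, rnorm(100), items3,
                                      qmlirt_priors())
    expect_identical(items3$a[1], 1)
  }
  expect_error(sample_discrimination(matrix(NA_real_, 2, 1), 1:2,
                                     item_bank(1, 0)), "degenerate item")
})

test_that("difficulty update matches the conjugate closed form", {
  items <- item_bank(c(1, 1), c(0, 0), identified = FALSE)
  # flat prior: mean -> mean(theta - z / a) = 1
  mom <- sample_difficulty(matrix(-1, 2, 2), c(0, 0), items,
                           qmlirt_priors(sigma_b = 1e6), moments = TRUE)
  expect_equal(mom$mean[2], 1, tolerance = 1e-6)
  # hand plug-in: sigma_b = 100, n = 2, a = 2, sum(z - a theta) = -4,
  # so v = 1/(1e-4 + n a^2) and m = v * (0 - a * (-4)) = 8v
  items2 <- item_bank(c(2, 2), c(0, 0), identified = FALSE)
  mom2 <- sample_difficulty(matrix(-2, 2, 2), c(0, 0), items2,
                            qmlirt_priors(), moments = TRUE)
  v <- 1 / (1e-4 + 8)
  expect_equal(mom2$mean[2], v * 8, tolerance = 1e-12)
  expect_equal(mom2$sd[2], sqrt(v), tolerance = 1e-12)
  # posterior variance decreases with the number of observed responses
  v_small <- sample_difficulty(matrix(0, 2, 2), rep(0, 2), items,
                               qmlirt_priors(), moments = TRUE)$sd[1]
  v_large <- sample_difficulty(matrix(0, 20, 2), rep(0, 20), items,
                               qmlirt_priors(), moments = TRUE)$sd[1]
  expect_lt(v_large, v_small)
})

test_that("ability update matches conjugacy and a grid oracle", {
  # one item (a=1, b=0), prior N(0,1), z = 1: posterior N(0.5, 0.5)
  mom <- sample_ability(matrix(1, 1, 1), item_bank(1, 0), 0, 1,
                        moments = TRUE)
  expect_equal(mom$mean, 0.5)
  expect_equal(mom$sd, sqrt(0.5))
  # person with no observed items draws from the structural prior
  mom0 <- sample_ability(matrix(NA_real_, 1, 2),
                         item_bank(c(1, 1), c(0, 0)), 0.7, 1.3,
                         moments = TRUE)
  expect_equal(mom0$mean, 0.7)
  expect_equal(mom0$sd, sqrt(1.3))
  # grid-normalization oracle: one person, three items
  items <- item_bank(c(1, 1.4, 0.7), c(0.2, -0.5, 0.1),
                     identified = FALSE)
  z <- matrix(c(0.5, -0.3, 1.2), 1)
  grid <- seq(-6, 6, length.out = 4001)
  logd <- vapply(grid, function(t) {
    sum(dnorm(drop(z), items$a * (t - items$b), 1, log = TRUE)) +
      dnorm(t, 0.3, sqrt(0.8), log = TRUE)
  }, numeric(1))
  cdf <- grid_cdf(logd, grid)
  set.seed(54)
  draws <- replicate(2e4, sample_ability(z, items, 0.3, 0.8))
  expect_lt(ks_distance(draws, cdf), 0.015)
})

test_that("omega update is the collapsed gamma conditional", {
  # no-data limit: the prior itself
  mom0 <- sample_omega(numeric(0), matrix(0, 0, 1), 0, 0.5,
                       qmlirt_priors(), moments = TRUE)
  expect_equal(mom0$shape, 28)
  expect_equal(mom0$rate, 4)
  # residuals (1, -1) at tau = 0.5: shape 30, rate 5
  mom <- sample_omega(c(1, -1), matrix(0, 2, 1), 0, 0.5,
                      qmlirt_priors(), moments = TRUE)
  expect_equal(mom$shape, 30)
  expect_equal(mom$rate, 5)
  # moment oracle on 1/omega
  set.seed(55)
  v <- replicate(2e4, 1 / sample_omega(c(1, -1), matrix(0, 2, 1), 0, 0.5,
                                       qmlirt_priors()))
  se <- sqrt(30 / 25 / 2e4)
  expect_equal(mean(v), 6, tolerance = 4 * se / 6)
})

test_that("latent mixing update matches Eq.-style inverse-Gaussian law", {
  # tau = 0.5 (k1 = 0, k2 = 8), residual 2, omega = 1: IG(mean 2, shape 2)
  mom <- sample_latent_e(2, matrix(0, 1, 1), 0, 1, 0.5, moments = TRUE)
  expect_equal(mom$mean, 2)
  expect_equal(mom$shape, 2)
  # moment oracle: 1/e has mean 2
  set.seed(56)
  inv_e <- 1 / sample_latent_e(rep(2, 1e5), matrix(0, 1e5, 1), 0, 1, 0.5)
  se <- sqrt(2^3 / 2 / 1e5)          # IG variance mu^3 / lambda
  expect_equal(mean(inv_e), 2, tolerance = 4 * se / 2)
  # grid oracle for the full conditional of e itself (asymmetric tau)
  s <- quantile_spec(0.25)
  r <- 0.7; om <- 0.8
  grid <- seq(1e-4, 15, length.out = 6000)
  logd <- -0.5 * log(grid) -
    (r - s$k1 * grid)^2 / (2 * s$k2 * om * grid) - grid / om
  cdf <- grid_cdf(logd, grid)
  set.seed(57)
  e <- sample_latent_e(rep(r, 1e5), matrix(0, 1e5, 1), 0, om, s)
  expect_lt(ks_distance(e, cdf), 0.01)
})

test_that("beta update matches weighted least squares and hand plug-in", {
  # q = 1, X = ones, theta = (1,3), e = 1, tau = 0.5, omega = 1, flat
  # prior: mean 2, variance k2*omega/2 = 4
  X <- matrix(1, 2, 1)
  mom <- sample_beta(c(1, 3), X, c(1, 1), 1, 0.5,
                     qmlirt_priors(beta_cov = 1e8), moments = TRUE)
  expect_equal(drop(mom$mean), 2, tolerance = 1e-6)
  expect_equal(drop(mom$cov), 4, tolerance = 1e-4)
  # k1 = 0, e = 1, omega = 1/k2: posterior mean -> OLS
  set.seed(58)
  X2 <- cbind(rnorm(20), rnorm(20))
  th <- rnorm(20)
  mom2 <- sample_beta(th, X2, rep(1, 20), 1 / 8, 0.5,
                      qmlirt_priors(beta_cov = 1e8), moments = TRUE)
  expect_equal(drop(mom2$mean), unname(coef(lm(th ~ X2 - 1))),
               tolerance = 1e-5)
  # informative prior shrinks toward zero
  mom3 <- sample_beta(th, X2, rep(1, 20), 1 / 8, 0.5,
                      qmlirt_priors(beta_cov = 0.05), moments = TRUE)
  expect_true(all(abs(mom3$mean) < abs(mom2$mean)))
  # an exactly singular precision is reported as collinearity
  expect_error(qmlirt:::draw_mvn(matrix(1, 2, 2), c(1, 1)), "collinear")
})

test_that("chains are seed-deterministic with invariant anchors", {
  set.seed(61)
  dat <- simulate_study_data(case = 1, tau = 0.5, n = 60, K = 5)
  cfg <- chain_config(400, 200, seed = 9, fit_intercept = FALSE)
  f1 <- qmlirt(dat$responses, dat$covariates, 0.5, cfg)
  f2 <- qmlirt(dat$responses, dat$covariates, 0.5, cfg)
  expect_identical(f1$posterior, f2$posterior)
  expect_true(all(f1$chains[[1]]$a[, 1] == 1))
  expect_true(all(f1$chains[[1]]$b[, 1] == 0))
  # degenerate configurations are refused up front
  expect_error(chain_config(100, 100), "burn_in")
  expect_error(chain_config(100, 50, thin = 0), "thin")
  expect_error(chain_config(10, 8, thin = 5), "no post-burn-in draws")
})

test_that("thinning and draw-count bookkeeping agree across engines", {
  set.seed(62)
  dat <- simulate_study_data(case = 1, tau = 0.5, n = 40, K = 4)
  cfg <- chain_config(105, 45, thin = 4, seed = 3, fit_intercept = FALSE)
  fc <- qmlirt(dat$responses, dat$covariates, 0.5, cfg)
  fr <- qmlirt(dat$responses, dat$covariates, 0.5, cfg, engine = "R")
  expect_equal(nrow(fc$chains[[1]]$beta), (105 - 45) %/% 4)
  expect_equal(nrow(fr$chains[[1]]$beta), (105 - 45) %/% 4)
})

test_that("compiled and pure-R engines agree on a small instance", {
  set.seed(63)
  dat <- simulate_study_data(case = 1, tau = 0.5, n = 80, K = 6)
  cfg <- chain_config(1500, 500, seed = 17, fit_intercept = FALSE)
  fc <- qmlirt(dat$responses, dat$covariates, 0.5, cfg)
  fr <- qmlirt(dat$responses, dat$covariates, 0.5, cfg, engine = "R")
  expect_equal(unname(coef(fc)), unname(coef(fr)), tolerance = 0.12)
  expect_equal(fc$means$omega, fr$means$omega, tolerance = 0.2)
  expect_equal(fc$means$a, fr$means$a, tolerance = 0.15)
})

test_that("the sampler recovers generating parameters", {
  set.seed(64)
  dat <- simulate_study_data(case = 1, tau = 0.5, n = 500, K = 20)
  fit <- qmlirt(dat$responses, dat$covariates, 0.5,
                chain_config(3000, 1500, seed = 2, fit_intercept = FALSE))
  sds <- fit$posterior$sd[1:2]
  expect_true(all(abs(coef(fit) - 0.5) < 3 * sds + 0.06))
  expect_gt(cos_similarity_discrimination(dat$items$a, fit$means$a), 0.97)
  expect_gt(cos_similarity_difficulty(dat$items$b, fit$means$b), 0.97)
})
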