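test_that("the logistic curve evaluates and degenerates correctly", {
  expect_equal(curve_ratio(1, 0, 0, 7), 0.5)
  expect_equal(curve_ratio(0.8, -2, 1, 20), 0.8 / (1 + exp(2 - log(20))))
  expect_equal(curve_ratio(0.8, -2, 1, 1e12), 0.8, tolerance = 1e-9)
  # age-0 limits by sign of the slope
  expect_equal(curve_ratio(0.9, 2, 1.5, 0), 0)
  expect_equal(curve_ratio(0.9, 2, -1.5, 0), 0.9)
  expect_equal(curve_ratio(0.9, 2, 0, 0), 0.9 * plogis(2))
  # monotonicity by sign of beta1
  ages <- c(0.5, 2, 10, 40)
  expect_true(all(diff(curve_ratio(0.8, -1, 2, ages)) > 0))
  expect_true(all(diff(curve_ratio(0.8, -1, -2, ages)) < 0))
  expect_equal(diff(curve_ratio(0.8, -1, 0, ages)), rep(0, 3))
})

test_that("curve and age inversion round-trip to 1e-9 relative tolerance", {
  withr::with_seed(17, {
    for (i in 1:50) {
      rmax <- exp(rnorm(1, 0, 1))
      beta0 <- rnorm(1, 0, 3)
      beta1 <- abs(rnorm(1, 0, 1.5)) + 0.05
      a <- exp(runif(1, log(0.1), log(60)))
      r <- curve_ratio(rmax, beta0, beta1, a)
      expect_equal(age_at_ratio(rmax, beta0, beta1, r), a,
                   tolerance = 1e-9)
    }
  })
  # the matched example pair
  expect_equal(age_at_ratio(0.8, -2, 1, curve_ratio(0.8, -2, 1, 20)), 20,
               tolerance = 1e-9)
  expect_equal(age_at_ratio(1, 0, 1, 0.5), 1)
  expect_identical(age_at_ratio(0.8, -2, 1, 0.8), Inf)   # target at Rmax
  expect_identical(age_at_ratio(0.8, -2, 1, 0.9), Inf)   # above Rmax
  expect_error(age_at_ratio(0.8, -2, 0, 0.5), "flat curve")
})

test_that("log likelihood matches the normal density on the log ratio", {
  # residual exactly zero: the density constant
  expect_equal(log_likelihood(1, 0, 0, 1, ratio = 0.5, age_yr = 1),
               -0.5 * log(2 * pi))
  # symmetry in log space
  expect_equal(log_likelihood(1, 0, 0, 1, 0.5 * exp(1), 1),
               log_likelihood(1, 0, 0, 1, 0.5 / exp(1), 1))
  # numerically stable at extreme parameters
  expect_true(is.finite(log_likelihood(1, -745, 0, 1, 0.5, 1)))
  expect_true(is.finite(log_likelihood(1, 745, 0, 1, 0.5, 1)))
  expect_error(log_likelihood(-1, 0, 0, 1, 0.5, 1), "support")
})

test_that("likelihood is invariant to common scaling of both stocks", {
  withr::with_seed(23, {
    cd <- runif(20, 10, 200); cu <- runif(20, 50, 300)
    age <- runif(20, 1, 40)
    for (c in c(0.01, 7, 500)) {
      expect_equal(
        log_likelihood(0.8, -2, 1, 0.3, cd / cu, age),
        log_likelihood(0.8, -2, 1, 0.3, (c * cd) / (c * cu), age),
        tolerance = 1e-9)
    }
  })
})

test_that("log prior sums the three normal densities and is flat in sigma", {
  expect_equal(log_prior(1, 0, 0, 1),
               2 * dnorm(0, 0, 2.5, log = TRUE) + dnorm(0, 0, 5, log = TRUE))
  expect_equal(log_prior(1, 0, 0, 1), -6.19884, tolerance = 1e-5)
  expect_equal(log_prior(1, 0, 0, 0.01), log_prior(1, 0, 0, 100))
  expect_identical(log_prior(-1, 0, 0, 1), -Inf)
  expect_identical(log_prior(1, 0, 0, -1), -Inf)
  expect_identical(log_prior(1, 0, 0, exp(11)), -Inf)  # outside ln-sigma box
})

test_that("prior interval masses agree with the normal CDF and Monte Carlo", {
  expect_equal(prior_interval_mass(5, -10, 10), 0.9544997, tolerance = 1e-6)
  expect_equal(prior_interval_mass(2.5, -5, 5), 0.9544997, tolerance = 1e-6)
  expect_equal(prior_interval_mass(2.5, 0.001, 148, scale = "exp"),
               0.9743269, tolerance = 1e-6)
  expect_equal(prior_interval_mass(2.5, 0.08, 12, scale = "exp"),
               0.6837016, tolerance = 1e-6)
  expect_equal(prior_interval_mass(5, -Inf, Inf), 1)
  expect_equal(prior_interval_mass(2.5, -1, 148, scale = "exp"),
               pnorm(log(148) / 2.5))
  # Monte-Carlo agreement within 3 standard errors
  withr::with_seed(41, {
    draws <- rnorm(1e6, 0, 2.5)
    for (iv in list(c(0.001, 148), c(0.08, 12))) {
      p_hat <- mean(exp(draws) >= iv[1] & exp(draws) <= iv[2])
      p <- prior_interval_mass(2.5, iv[1], iv[2], scale = "exp")
      se <- sqrt(p * (1 - p) / 1e6)
      expect_lt(abs(p_hat - p), 3 * se)
    }
  })
})

test_that("the sampler recovers generating parameters and is deterministic", {
  theta <- list(rmax = 0.75, beta0 = -3, beta1 = 1.5, sigma = 0.2)
  obs <- make_model_obs(theta, n = 250, seed = 99)
  fit <- fit_posterior(obs, cfg = fit_config(seed = 42), stratum = "bgb:all")
  expect_s3_class(fit, "buildup_fit")
  expect_lte(max(fit$diagnostics$rhat), 1.01)
  expect_gte(min(fit$diagnostics$ess), 100)
  for (p in names(theta)) {
    v <- fit$draws[[p]]
    expect_lt(abs(mean(v) - theta[[p]]), 3 * sd(v))
  }
  fit2 <- fit_posterior(obs, cfg = fit_config(seed = 42), stratum = "bgb:all")
  expect_identical(fit$draws, fit2$draws)
  fit3 <- fit_posterior(obs, cfg = fit_config(seed = 43))
  expect_false(identical(fit$draws, fit3$draws))
})

test_that("posterior means agree with an importance-sampling oracle", {
  theta <- list(rmax = 0.7, beta0 = -2.5, beta1 = 1.2, sigma = 0.25)
  obs <- make_model_obs(theta, n = 150, seed = 7)
  fit <- fit_posterior(obs, cfg = fit_config(seed = 11))
  oracle <- oracle_posterior_means(obs, n_is = 2e5, seed = 12)
  expect_gt(oracle$ess, 1000)
  for (p in c("rmax", "beta0", "beta1", "sigma")) {
    mcmc_se <- sd(fit$draws[[p]]) /
      sqrt(fit$diagnostics$ess[match(p, c("rmax", "beta0", "beta1", "sigma"))])
    tol <- 4 * (oracle$se[[p]] + sd(fit$draws[[p]]) / sqrt(1000))
    expect_lt(abs(mean(fit$draws[[p]]) - oracle$mean[[p]]), tol)
  }
})

test_that("an empty-data fit reproduces the prior analytically", {
  fit <- fit_posterior(data.frame(ratio = numeric(0), age_yr = numeric(0)),
                       cfg = fit_config(seed = 7))
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  n_eff <- min(fit$diagnostics$ess)
  for (par in list(list(col = "beta0", sd = 5),
                   list(col = "log_rmax", sd = 2.5),
                   list(col = "beta1", sd = 2.5))) {
    emp <- quantile(fit$draws[[par$col]], qs)
    ana <- qnorm(qs, 0, par$sd)
    # MC error of an empirical quantile: sqrt(q(1-q)/n)/density
    se <- sqrt(qs * (1 - qs) / n_eff) / dnorm(ana, 0, par$sd)
    expect_true(all(abs(emp - ana) < 4 * se))
  }
  # flat ln-sigma explores its whole box
  expect_lt(min(fit$draws$log_sigma), -9)
  expect_gt(max(fit$draws$log_sigma), 9)
})

test_that("non-convergence fails loudly with diagnostics attached", {
  theta <- list(rmax = 0.75, beta0 = -3, beta1 = 1.5, sigma = 0.2)
  obs <- make_model_obs(theta, n = 100, seed = 3)
  cfg <- fit_config(seed = 5, warmup = 60, samples = 40, rhat_max = 1.0001,
                    ess_min = 1e6)
  err <- tryCatch(fit_posterior(obs, cfg = cfg), error = function(e) e)
  expect_s3_class(err, "buildup_convergence_error")
  expect_true(is.data.frame(err$diagnostics))
  # and can be bypassed for inspection
  fit <- fit_posterior(obs, cfg = cfg, check_convergence = FALSE)
  expect_s3_class(fit, "buildup_fit")
})

test_that("curve summaries are correct on enumerable draws", {
  draws <- data.frame(rmax = c(0.6, 0.8), beta0 = c(50, 50), beta1 = c(0, 0))
  s <- summarize_curve(draws, ages = c(1, 10, 40))
  expect_equal(s$mean, rep(0.7, 3), tolerance = 1e-10)
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  # identical draws give zero-width intervals on the point curve
  one <- data.frame(rmax = 0.8, beta0 = -2, beta1 = 1)
  many <- one[rep(1, 200), ]
  s2 <- summarize_curve(many, ages = c(5, 20))
  expect_equal(s2$lower, s2$upper)
  expect_equal(s2$mean, curve_ratio(0.8, -2, 1, c(5, 20)))
})

test_that("slope probabilities are draw counts", {
  d <- data.frame(beta1 = c(rep(-1, 13), rep(1, 87)))
  p <- slope_probability(d)
  expect_equal(p$tail, 0.13)
  expect_equal(p$p_positive, 0.87)
  expect_equal(slope_probability(data.frame(beta1 = rep(1, 150)))$tail, 0)
  sym <- data.frame(beta1 = c(seq(-1, -0.01, length.out = 75),
                              seq(0.01, 1, length.out = 75)))
  expect_equal(slope_probability(sym)$p_positive, 0.5)
})

test_that("Bayesian R2 is the fitted-over-total variance ratio", {
  # observations exactly on the curve: R2 = 1
  draws <- data.frame(log_rmax = log(0.8), beta0 = -2, beta1 = 1,
                      rmax = 0.8, sigma = 0.1)
  ages <- c(1, 5, 20, 40)
  obs <- data.frame(ratio = curve_ratio(0.8, -2, 1, ages), age_yr = ages)
  expect_equal(bayes_r2(draws, obs), 1)
  # residual variance equal to fitted variance: R2 = 1/2
  d2 <- data.frame(log_rmax = 0, beta0 = 0, beta1 = 1, rmax = 1, sigma = 1)
  a2 <- c(1, 3)
  mu <- -log1p(exp(-(0 + log(a2))))
  dev <- diff(mu) / 2
  y <- mu + c(-dev, dev)
  obs2 <- data.frame(ratio = exp(y), age_yr = a2)
  expect_equal(bayes_r2(d2, obs2), 0.5, tolerance = 1e-12)
})
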