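# Independent oracles used to cross-check the package's implementations.

# Brute-force gram accounting for soil stocks: slice the profile into 1-mm
# slabs, accumulate grams of C per cm^2 of surface, convert at the end
# (1 g cm^-2 = 100 Mg ha^-1).
brute_force_soil_stock <- function(profile, max_depth_cm = 100) {
  grams <- 0
  step <- 0.1
  depths <- seq(0, max_depth_cm - step, by = step)
  for (z in depths) {
    lay <- which(profile$top_cm <= z & profile$bottom_cm > z)
    if (length(lay) == 1) {
      grams <- grams + profile$bulk_density_gcm3[lay] * step *
        profile$carbon_pct[lay] / 100
    }
  }
  grams * 100
}

# Self-contained log posterior of the buildup model (written independently
# of the package's sampler path; shares only the model definition).
oracle_log_post <- function(par, y, la) {
  lr <- par[1]; b0 <- par[2]; b1 <- par[3]; ls <- par[4]
  if (ls < -10 || ls > 10) return(-Inf)
  mu <- lr + log(plogis(b0 + b1 * la))
  sum(dnorm(y, mu, exp(ls), log = TRUE)) +
    dnorm(lr, 0, 2.5, log = TRUE) + dnorm(b0, 0, 5, log = TRUE) +
    dnorm(b1, 0, 2.5, log = TRUE)
}

# Importance-sampling estimate of posterior means (and their Monte-Carlo
# standard errors) from a Gaussian proposal at the numerically located
# mode, with doubled covariance for tail coverage.
oracle_posterior_means <- function(obs, n_is = 2e5, seed = 1,
                                   age_floor = 0.25) {
  y <- log(obs$ratio)
  la <- log(pmax(obs$age_yr, age_floor))
  opt <- optim(c(0, 0, 0, 0), function(p) -oracle_log_post(p, y, la),
               method = "BFGS", hessian = TRUE)
  S <- 2 * solve(opt$hessian)
  withr::with_seed(seed, {
    Z <- MASS::mvrnorm(n_is, opt$par, S)
  })
  lq <- -0.5 * mahalanobis(Z, opt$par, S) -
    0.5 * determinant(S)$modulus[1] - 2 * log(2 * pi)
  lp <- apply(Z, 1, oracle_log_post, y = y, la = la)
  w <- exp(lp - lq - max(lp - lq, na.rm = TRUE))
  w[!is.finite(w)] <- 0
  w <- w / sum(w)
  vals <- cbind(rmax = exp(Z[, 1]), beta0 = Z[, 2], beta1 = Z[, 3],
                sigma = exp(Z[, 4]))
  est <- colSums(vals * w)
  ess <- 1 / sum(w^2)
  se <- sqrt(colSums(w^2 * sweep(vals, 2, est)^2))
  list(mean = est, se = se, ess = ess)
}

# Ratio observations generated straight from the statistical model (not via
# the stand-level generator), for sampler checks.
make_model_obs <- function(theta, n, seed, age_range = c(0.5, 40)) {
  withr::with_seed(seed, {
    age <- exp(runif(n, log(age_range[1]), log(age_range[2])))
    r <- curve_ratio(theta$rmax, theta$beta0, theta$beta1, age) *
      exp(rnorm(n, 0, theta$sigma))
  })
  data.frame(ratio = r, age_yr = age)
}

# Minimal well-formed stands table used across I/O tests.
make_stand_rows <- function() {
  data.frame(
    stand_id = c("p1", "p2", "u1"),
    role = c("planted", "planted", "intact"),
    origin = c("restored", "afforested", "intact"),
    latitude = c(1.01, 1.02, 1.015),
    longitude = c(103.5, 103.51, 103.505),
    site_id = c("siteA", "siteA", "siteA"),
    geomorphic_class = c("delta", "delta", "delta"),
    age_yr = c(5, 12, NA),
    composition = c("Rhizophora", "mixed", "mixed"),
    agb_c_mgha = c(30, 60, 100),
    bgb_c_mgha = c(15, 30, 50),
    soil_c_mgha = c(150, 200, 280),
    soil_depth_cm = c(100, 100, 100),
    n_samples = c(3L, 4L, 5L),
    study_id = c("s1", "s1", "s1"),
    stringsAsFactors = FALSE
  )
}
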