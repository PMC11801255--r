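# Bayesian nonlinear logistic buildup model for planted-to-intact carbon
# stock ratios.
#
# Curve:      R(age) = Rmax / (1 + exp(-beta0 - beta1 * ln(age)))
# Likelihood: ln(R_i) ~ Normal(ln Rmax - log1p(exp(-beta0 - beta1*ln age_i)),
#                              sigma)
# Priors:     ln Rmax ~ N(0, 2.5), beta0 ~ N(0, 5), beta1 ~ N(0, 2.5),
#             ln sigma flat (realized as uniform on [-10, 10] for sampling).
#
# All logs are natural; the age-at-ratio inversion below depends on that.

#' Prior specification
#'
#' @param log_rmax_sd Normal sd of the prior on ln Rmax (default 2.5).
#' @param beta0_sd Normal sd of the prior on the curve-location parameter
#'   (default 5: 95% of prior mass within log-odds -10..10 at age 1 yr).
#' @param beta1_sd Normal sd of the prior on the log-age slope (default 2.5).
#' @param log_sigma_bounds Bounds of the uniform prior on ln sigma standing
#'   in for the flat Jeffreys prior (default c(-10, 10)).
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(log_rmax_sd = 2.5, beta0_sd = 5, beta1_sd = 2.5,
                       log_sigma_bounds = c(-10, 10)) {
  stopifnot(log_rmax_sd > 0, beta0_sd > 0, beta1_sd > 0,
            length(log_sigma_bounds) == 2,
            log_sigma_bounds[1] < log_sigma_bounds[2])
  structure(list(log_rmax_sd = log_rmax_sd, beta0_sd = beta0_sd,
                 beta1_sd = beta1_sd, log_sigma_bounds = log_sigma_bounds),
            class = "prior_spec")
}

#' Sampler configuration
#'
#' @param chains Number of MCMC chains (default 4).
#' @param warmup Adaptation iterations discarded per chain (default 1500).
#' @param samples Retained iterations per chain (default 2500).
#' @param seed Integer seed controlling all randomness of the fit.
#' @param age_floor_yr Ages below this are raised to it before taking logs
#'   (default 0.25 yr); makes age-0 observations usable.
#' @param rhat_max Convergence gate on split-Rhat (default 1.01).
#' @param ess_min Convergence gate on effective sample size (default 100).
#' @return A `fit_config` list.
#' @export
fit_config <- function(chains = 4, warmup = 1500, samples = 2500, seed = 1,
                       age_floor_yr = 0.25, rhat_max = 1.01, ess_min = 100) {
  stopifnot(chains >= 2, warmup > 0, samples > 0, age_floor_yr > 0,
            rhat_max > 1, ess_min > 0)
  structure(list(chains = chains, warmup = warmup, samples = samples,
                 seed = as.integer(seed), age_floor_yr = age_floor_yr,
                 rhat_max = rhat_max, ess_min = ess_min),
            class = "fit_config")
}

# log(1 + exp(x)) without overflow.
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  mid <- x > 18 & x < 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

#' Logistic buildup curve
#'
#' Planted-to-intact ratio at a given age:
#' `Rmax / (1 + exp(-beta0 - beta1 * ln(age)))`. At age 0 the analytic
#' limit is used: 0 when `beta1 > 0`, `Rmax * plogis(beta0)` when
#' `beta1 == 0`, and `Rmax` when `beta1 < 0`.
#'
#' @param rmax Asymptotic ratio (> 0). `rmax`, `beta0`, `beta1` may be
#'   vectors of draws (recycled against `age_yr`).
#' @param beta0 Location of the curve on the log-age axis (log-odds at age
#'   1 yr).
#' @param beta1 Slope with respect to ln(age).
#' @param age_yr Stand age(s) in years (>= 0).
#' @return Ratio(s), strictly inside (0, Rmax) for positive finite ages.
#' @export
curve_ratio <- function(rmax, beta0, beta1, age_yr) {
  n <- max(length(rmax), length(beta0), length(beta1), length(age_yr))
  rmax <- rep_len(rmax, n); beta0 <- rep_len(beta0, n)
  beta1 <- rep_len(beta1, n); age_yr <- rep_len(age_yr, n)
  stopifnot(all(rmax > 0), all(age_yr >= 0))
  out <- numeric(n)
  zero <- age_yr == 0
  la <- suppressWarnings(log(age_yr))
  out[!zero] <- rmax[!zero] *
    stats::plogis(beta0[!zero] + beta1[!zero] * la[!zero])
  if (any(zero)) {
    b1 <- beta1[zero]
    lim <- ifelse(b1 > 0, 0,
                  ifelse(b1 < 0, rmax[zero],
                         rmax[zero] * stats::plogis(beta0[zero])))
    out[zero] <- lim
  }
  out
}

#' Log likelihood of ratio observations under one parameter draw
#'
#' Normal log density of `ln(ratio)` at mean
#' `ln Rmax - log(1 + exp(-beta0 - beta1 ln age))` with sd `sigma`,
#' computed with a numerically stable log1p-exp so extreme `beta0`/`beta1`
#' never overflow. Ages below `age_floor_yr` are floored.
#'
#' @param rmax,beta0,beta1,sigma Scalar parameters (`rmax > 0`,
#'   `sigma > 0`).
#' @param ratio Observed ratios (> 0).
#' @param age_yr Observed ages (>= 0).
#' @param age_floor_yr Age floor in years (default 0.25).
#' @return Sum of log densities.
#' @export
log_likelihood <- function(rmax, beta0, beta1, sigma, ratio, age_yr,
                           age_floor_yr = 0.25) {
  if (!all(is.finite(c(rmax, beta0, beta1, sigma))) || rmax <= 0 ||
      sigma <= 0)
    stop("non-finite or out-of-support parameters")
  stopifnot(all(ratio > 0), all(age_yr >= 0))
  la <- log(pmax(age_yr, age_floor_yr))
  mu <- log(rmax) - log1pexp(-(beta0 + beta1 * la))
  sum(stats::dnorm(log(ratio), mu, sigma, log = TRUE))
}

#' Log prior density (up to the flat ln-sigma constant)
#'
#' Sum of the normal log densities of `ln Rmax`, `beta0` and `beta1` plus
#' the flat contribution of ln sigma (0 inside its bounds, `-Inf` outside).
#'
#' @param rmax,beta0,beta1,sigma Scalar parameters.
#' @param prior A [prior_spec()].
#' @return Log density; `-Inf` outside the support (`rmax <= 0`,
#'   `sigma <= 0`, or ln sigma outside its bounds).
#' @export
log_prior <- function(rmax, beta0, beta1, sigma, prior = prior_spec()) {
  if (rmax <= 0 || sigma <= 0) return(-Inf)
  ls <- log(sigma)
  if (ls < prior$log_sigma_bounds[1] || ls > prior$log_sigma_bounds[2])
    return(-Inf)
  stats::dnorm(log(rmax), 0, prior$log_rmax_sd, log = TRUE) +
    stats::dnorm(beta0, 0, prior$beta0_sd, log = TRUE) +
    stats::dnorm(beta1, 0, prior$beta1_sd, log = TRUE)
}

# Unnormalized log posterior on the unconstrained scale
# par = (log_rmax, beta0, beta1, log_sigma).
.make_log_post <- function(y, la, prior) {
  lb <- prior$log_sigma_bounds
  function(par) {
    if (any(!is.finite(par))) return(-Inf)
    if (par[4] < lb[1] || par[4] > lb[2]) return(-Inf)
    sigma <- exp(par[4])
    lp <- stats::dnorm(par[1], 0, prior$log_rmax_sd, log = TRUE) +
      stats::dnorm(par[2], 0, prior$beta0_sd, log = TRUE) +
      stats::dnorm(par[3], 0, prior$beta1_sd, log = TRUE)
    if (length(y) > 0) {
      mu <- par[1] - log1pexp(-(par[2] + par[3] * la))
      lp <- lp + sum(stats::dnorm(y, mu, sigma, log = TRUE))
    }
    lp
  }
}

# Laplace approximation of the posterior: mode by BFGS and a regularized
# inverse Hessian, used to seed the Metropolis proposal covariance and the
# overdispersed chain starts. Falls back to the prior scales when the
# Hessian is unusable (e.g. the flat ln-sigma direction of an empty-data
# fit).
.laplace_kernel <- function(log_post, prior) {
  fallback <- diag(c(prior$log_rmax_sd^2, prior$beta0_sd^2,
                     prior$beta1_sd^2,
                     diff(prior$log_sigma_bounds)^2 / 12))
  start <- c(0, 0, 0, 0)
  opt <- tryCatch(
    stats::optim(start, function(p) -log_post(p), method = "BFGS",
                 hessian = TRUE, control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt) || !all(is.finite(opt$par)) ||
      !all(is.finite(opt$hessian)))
    return(list(mode = start, cov = fallback))
  eg <- eigen(opt$hessian, symmetric = TRUE)
  if (any(eg$values <= 1e-8))
    return(list(mode = opt$par, cov = fallback))
  vals <- pmin(pmax(1 / eg$values, 1e-8), diag(fallback))
  cov <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
  list(mode = opt$par, cov = cov)
}

# Multivariate-t log density / sampler for the independence proposal.
.dmvt_log <- function(x, mode, L, df) {
  d <- length(mode)
  z <- forwardsolve(L, x - mode)
  lgamma((df + d) / 2) - lgamma(df / 2) - (d / 2) * log(df * pi) -
    sum(log(diag(L))) - ((df + d) / 2) * log1p(sum(z^2) / df)
}

.rmvt <- function(mode, L, df) {
  mode + drop(L %*% stats::rnorm(length(mode))) /
    sqrt(stats::rchisq(1, df) / df)
}

# One Metropolis chain mixing two kernels: an independence proposal from a
# heavy-tailed multivariate t centered at the Laplace mode (fast global
# mixing on the near-Gaussian posterior) and an adaptive random-walk step
# (local robustness where the Laplace approximation is poor). Random-walk
# scale and covariance adapt during warmup only, so retained draws target
# the exact posterior.
.run_chain <- function(log_post, init, warmup, samples, chol0, mode) {
  d <- length(init)
  t_df <- 4
  t_chol <- chol0 * 1.3
  cur <- init
  cur_lp <- log_post(cur)
  cur_lq <- .dmvt_log(cur, mode, t_chol, t_df)
  scale <- 1
  base <- 2.38 / sqrt(d)
  cov_chol <- chol0
  hist <- matrix(NA_real_, warmup, d)
  draws <- matrix(NA_real_, samples, d)
  n_acc <- 0
  win_acc <- 0
  total <- warmup + samples
  for (it in seq_len(total)) {
    if (it %% 2 == 0) {
      # independence step
      prop <- .rmvt(mode, t_chol, t_df)
      prop_lp <- log_post(prop)
      prop_lq <- .dmvt_log(prop, mode, t_chol, t_df)
      ratio <- (prop_lp - prop_lq) - (cur_lp - cur_lq)
    } else {
      prop <- cur + (scale * base) * drop(cov_chol %*% stats::rnorm(d))
      prop_lp <- log_post(prop)
      prop_lq <- .dmvt_log(prop, mode, t_chol, t_df)
      ratio <- prop_lp - cur_lp
    }
    if (is.finite(prop_lp) && log(stats::runif(1)) < ratio) {
      cur <- prop; cur_lp <- prop_lp; cur_lq <- prop_lq
      if (it > warmup) n_acc <- n_acc + 1
      else if (it %% 2 == 1) win_acc <- win_acc + 1
    }
    if (it <= warmup) {
      hist[it, ] <- cur
      if (it %% 50 == 0) {
        if (it >= 400) {
          # adapt the walk from the post-transient half of the history
          emp <- stats::cov(hist[floor(it / 2):it, , drop = FALSE])
          emp <- emp + diag(1e-8, d)
          ch <- tryCatch(t(chol(emp)), error = function(e) NULL)
          if (!is.null(ch)) cov_chol <- ch
        }
        scale <- scale * exp(0.7 * (win_acc / 25 - 0.30))
        scale <- min(max(scale, 0.05), 10)
        win_acc <- 0
      }
    } else {
      draws[it - warmup, ] <- cur
    }
  }
  list(draws = draws, accept = n_acc / samples)
}

# Split-Rhat (Gelman et al., BDA3) for a samples x chains matrix.
.split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  split <- cbind(mat[seq_len(half), , drop = FALSE],
                 mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split); nn <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  b <- nn * stats::var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

# Combined effective sample size with Geyer's initial-positive-sequence
# truncation of the chain-averaged autocorrelations.
.ess <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  vars <- apply(mat, 2, stats::var)
  w <- mean(vars)
  means <- colMeans(mat)
  var_plus <- (n - 1) / n * w + stats::var(means)
  if (var_plus == 0) return(m * n)
  max_lag <- min(n - 1, 500)
  acov <- sapply(seq_len(m), function(j) {
    x <- mat[, j] - means[j]
    stats::acf(x, lag.max = max_lag, plot = FALSE, type = "covariance",
               demean = FALSE)$acf[, 1, 1]
  })
  rho <- 1 - (w - rowMeans(acov[-1, , drop = FALSE])) / var_plus
  tau <- 1
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  m * n / tau
}

#' Fit the logistic buildup model by MCMC
#'
#' Samples the posterior of (Rmax, beta0, beta1, sigma) for one stratum by
#' adaptive random-walk Metropolis on the unconstrained scale
#' (ln Rmax, beta0, beta1, ln sigma), with covariance and scale adaptation
#' confined to warmup. Fails loudly (condition class
#' `"buildup_convergence_error"`, carrying the diagnostics table) when any
#' split-Rhat exceeds `rhat_max` or any effective sample size falls below
#' `ess_min`. Fully reproducible given `cfg$seed`. An empty observation set
#' is allowed and samples the (bounded) prior.
#'
#' @param obs Data frame with columns `ratio` and `age_yr` (one stratum), or
#'   a zero-row data frame.
#' @param prior A [prior_spec()].
#' @param cfg A [fit_config()].
#' @param stratum Optional stratum label stored with the fit.
#' @param check_convergence Set `FALSE` to return a non-converged fit for
#'   inspection instead of erroring.
#' @return A `buildup_fit`: list with `draws` (data frame: chain, iteration,
#'   log_rmax, beta0, beta1, log_sigma, rmax, sigma), `diagnostics` (rhat and
#'   ess per parameter), `accept_rate`, `seed`, `stratum`, `n_obs`.
#' @export
fit_posterior <- function(obs, prior = prior_spec(), cfg = fit_config(),
                          stratum = NA_character_, check_convergence = TRUE) {
  stopifnot(is.data.frame(obs))
  if (nrow(obs) > 0) {
    stopifnot(all(obs$ratio > 0), all(obs$age_yr >= 0))
    y <- log(obs$ratio)
    la <- log(pmax(obs$age_yr, cfg$age_floor_yr))
  } else {
    y <- numeric(0); la <- numeric(0)
  }
  log_post <- .make_log_post(y, la, prior)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  kern <- .laplace_kernel(log_post, prior)
  chol0 <- t(chol(kern$cov))
  chains <- vector("list", cfg$chains)
  for (ch in seq_len(cfg$chains)) {
    set.seed(cfg$seed + 1000L * ch)
    init <- kern$mode + 2 * drop(chol0 %*% stats::rnorm(4))
    if (!is.finite(log_post(init))) init <- kern$mode
    chains[[ch]] <- .run_chain(log_post, init, cfg$warmup, cfg$samples,
                               chol0, kern$mode)
  }

  pars <- c("log_rmax", "beta0", "beta1", "log_sigma")
  diag_tab <- data.frame(parameter = pars, rhat = NA_real_, ess = NA_real_)
  for (j in seq_along(pars)) {
    mat <- sapply(chains, function(c) c$draws[, j])
    diag_tab$rhat[j] <- .split_rhat(mat)
    diag_tab$ess[j] <- .ess(mat)
  }

  draws <- do.call(rbind, lapply(seq_along(chains), function(ch) {
    d <- as.data.frame(chains[[ch]]$draws)
    names(d) <- pars
    cbind(chain = ch, iteration = seq_len(nrow(d)), d)
  }))
  draws$rmax <- exp(draws$log_rmax)
  draws$sigma <- exp(draws$log_sigma)

  fit <- structure(list(
    draws = draws,
    diagnostics = diag_tab,
    accept_rate = mean(vapply(chains, `[[`, numeric(1), "accept")),
    seed = cfg$seed,
    stratum = stratum,
    n_obs = nrow(obs),
    prior = prior,
    config = cfg
  ), class = "buildup_fit")

  bad <- diag_tab$rhat > cfg$rhat_max | diag_tab$ess < cfg$ess_min
  if (check_convergence && any(bad)) {
    cond <- structure(
      class = c("buildup_convergence_error", "error", "condition"),
      list(message = paste0(
        "MCMC did not converge (",
        paste(sprintf("%s: rhat=%.3f ess=%.0f", diag_tab$parameter[bad],
                      diag_tab$rhat[bad], diag_tab$ess[bad]),
              collapse = "; "), ")"),
        call = sys.call(-1), diagnostics = diag_tab, fit = fit))
    stop(cond)
  }
  fit
}

#' @export
print.buildup_fit <- function(x, ...) {
  cat(sprintf("<buildup_fit> stratum=%s  n_obs=%d  draws=%d (%d chains)\n",
              x$stratum, x$n_obs, nrow(x$draws),
              length(unique(x$draws$chain))))
  s <- x$draws
  q <- function(v) sprintf("%.3f [%.3f, %.3f]", mean(v),
                           stats::quantile(v, 0.025),
                           stats::quantile(v, 0.975))
  cat("  Rmax  ", q(s$rmax), "\n")
  cat("  beta0 ", q(s$beta0), "\n")
  cat("  beta1 ", q(s$beta1), "\n")
  cat("  sigma ", q(s$sigma), "\n")
  cat(sprintf("  max split-Rhat %.4f, min ESS %.0f, accept %.2f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess),
              x$accept_rate))
  invisible(x)
}

#' Age at which the curve reaches a target ratio
#'
#' Inverts the logistic curve:
#' `age = exp[(ln(R / (Rmax - R)) - beta0) / beta1]` for `R < Rmax`; when
#' `R >= Rmax` the target is unreachable and `Inf` is returned. A flat
#' curve (`beta1 == 0`) has no solution and is an error.
#'
#' @param rmax,beta0,beta1 Curve parameters (vectors of draws allowed).
#' @param target_r Target ratio (> 0).
#' @return Age(s) in years, possibly `Inf`.
#' @export
age_at_ratio <- function(rmax, beta0, beta1, target_r) {
  stopifnot(all(target_r > 0))
  if (any(beta1 == 0)) stop("no solution: flat curve (beta1 = 0)")
  n <- max(length(rmax), length(beta0), length(beta1), length(target_r))
  rmax <- rep_len(rmax, n); beta0 <- rep_len(beta0, n)
  beta1 <- rep_len(beta1, n); target_r <- rep_len(target_r, n)
  out <- rep(Inf, n)
  ok <- target_r < rmax
  out[ok] <- exp((log(target_r[ok] / (rmax[ok] - target_r[ok])) -
                    beta0[ok]) / beta1[ok])
  out
}

#' Posterior summary of the buildup curve over ages
#'
#' Evaluates [curve_ratio()] at each requested age for every posterior draw
#' and reports the posterior mean and equal-tailed 95% credible interval.
#'
#' @param fit A `buildup_fit` (or a data frame of draws with columns `rmax`,
#'   `beta0`, `beta1`).
#' @param ages Ages in years.
#' @return Data frame with columns `age_yr`, `mean`, `lower`, `upper`.
#' @export
summarize_curve <- function(fit, ages) {
  draws <- if (inherits(fit, "buildup_fit")) fit$draws else fit
  out <- lapply(ages, function(a) {
    r <- curve_ratio(draws$rmax, draws$beta0, draws$beta1, a)
    data.frame(age_yr = a, mean = mean(r),
               lower = unname(stats::quantile(r, 0.025)),
               upper = unname(stats::quantile(r, 0.975)))
  })
  do.call(rbind, out)
}

#' Posterior probability statements about the slope
#'
#' Counts draws to report `p_positive = P(beta1 > 0)` and the one-sided
#' tail probability `min(P(beta1 <= 0), P(beta1 >= 0))` used to flag slopes
#' not notably different from zero.
#'
#' @param fit A `buildup_fit` (needs at least 100 draws).
#' @return List with `tail` and `p_positive`.
#' @export
slope_probability <- function(fit) {
  draws <- if (inherits(fit, "buildup_fit")) fit$draws else fit
  b1 <- draws$beta1
  stopifnot(length(b1) >= 100)
  list(tail = min(mean(b1 <= 0), mean(b1 >= 0)),
       p_positive = mean(b1 > 0))
}

#' Bayesian coefficient of determination
#'
#' For each posterior draw, the variance of the fitted values of ln(R) over
#' the variance of fitted plus residual ln(R); the posterior mean of that
#' ratio is returned (the standard Bayesian R-squared convention).
#'
#' @param fit A `buildup_fit`.
#' @param obs The observations the model was fit to (columns `ratio`,
#'   `age_yr`); at least 2 rows.
#' @return R-squared in `[0, 1]`.
#' @export
bayes_r2 <- function(fit, obs) {
  draws <- if (inherits(fit, "buildup_fit")) fit$draws else fit
  stopifnot(nrow(obs) >= 2)
  floor_yr <- if (inherits(fit, "buildup_fit")) fit$config$age_floor_yr else 0.25
  y <- log(obs$ratio)
  la <- log(pmax(obs$age_yr, floor_yr))
  r2 <- vapply(seq_len(nrow(draws)), function(s) {
    mu <- draws$log_rmax[s] -
      log1pexp(-(draws$beta0[s] + draws$beta1[s] * la))
    vf <- stats::var(mu)
    vr <- stats::var(y - mu)
    if (vf + vr == 0) return(NA_real_)
    vf / (vf + vr)
  }, numeric(1))
  if (all(is.na(r2))) stop("undefined R-squared: zero total variance")
  mean(r2, na.rm = TRUE)
}

#' Prior probability mass of an interval
#'
#' Mass a mean-zero normal prior with sd `sd` assigns to `[lo, hi]`, on the
#' parameter's own scale (`scale = "identity"`) or after exponentiation
#' (`scale = "exp"`, i.e. the interval is on exp(parameter); `lo <= 0` is
#' treated as an unbounded left tail).
#'
#' @param sd Prior standard deviation (> 0).
#' @param lo,hi Interval bounds, `lo < hi`.
#' @param scale `"identity"` or `"exp"`.
#' @return Probability in `[0, 1]`.
#' @export
prior_interval_mass <- function(sd, lo, hi, scale = c("identity", "exp")) {
  scale <- match.arg(scale)
  stopifnot(sd > 0, lo < hi)
  if (scale == "exp") {
    lo <- if (lo <= 0) -Inf else log(lo)
    hi <- log(hi)
  }
  stats::pnorm(hi / sd) - stats::pnorm(lo / sd)
}
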