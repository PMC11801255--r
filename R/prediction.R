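# Posterior ratios -> predicted absolute stocks and net carbon gains,
# against user-supplied sets of intact-stand stock values.

#' Intact-stock value set
#'
#' @param compartment `"agb"`, `"bgb"` or `"soil"`.
#' @param values Intact stock values, MgC ha^-1, all > 0.
#' @param source Free-text label of where the values come from.
#' @return An `intact_stock_set`.
#' @export
intact_stock_set <- function(compartment, values, source = "user") {
  compartment <- match.arg(compartment, COMPARTMENTS)
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty intact value set")
  if (any(!is.finite(values) | values <= 0))
    stop("intact stock values must be positive and finite")
  structure(list(compartment = compartment, values = values,
                 source = source),
            class = "intact_stock_set")
}

# Cross-product of draw-wise ratios with intact values; subsamples draws
# (seeded) only when the full product would exceed max_cells.
.cross_ratios <- function(draws, intact, age_yr, max_cells = 1e7,
                          seed = 1L) {
  nd <- nrow(draws)
  nv <- length(intact$values)
  if (nd * nv > max_cells) {
    keep <- ceiling(max_cells / nv)
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    draws <- draws[sample.int(nd, keep), , drop = FALSE]
  }
  r <- curve_ratio(draws$rmax, draws$beta0, draws$beta1, age_yr)
  outer(r, intact$values)
}

#' Predicted absolute stocks at given ages
#'
#' For each age, forms the distribution of `curve_ratio(draw, age) x v`
#' over all posterior draws crossed with all intact values, and reports its
#' mean and equal-tailed 95% interval. Linear in the intact values.
#'
#' @param fit A `buildup_fit` whose stratum compartment matches `intact`.
#' @param intact An [intact_stock_set()].
#' @param ages Ages in years (default `c(1, 5, 10, 20, 30, 40)`).
#' @param compartment Compartment of the fit; must equal
#'   `intact$compartment`. Defaults to the compartment encoded in
#'   `fit$stratum` (the part before `":"`), when present.
#' @return Data frame with `age_yr`, `mean`, `lower`, `upper` (MgC ha^-1).
#' @export
predict_stocks <- function(fit, intact, ages = c(1, 5, 10, 20, 30, 40),
                           compartment = NULL) {
  draws <- if (inherits(fit, "buildup_fit")) fit$draws else fit
  if (is.null(compartment) && inherits(fit, "buildup_fit") &&
      !is.na(fit$stratum))
    compartment <- strsplit(fit$stratum, ":", fixed = TRUE)[[1]][1]
  if (!is.null(compartment) && compartment != intact$compartment)
    stop("compartment mismatch: fit is ", compartment,
         ", intact values are ", intact$compartment)
  out <- lapply(ages, function(a) {
    g <- .cross_ratios(draws, intact, a)
    data.frame(age_yr = a, mean = mean(g),
               lower = unname(stats::quantile(g, 0.025)),
               upper = unname(stats::quantile(g, 0.975)))
  })
  do.call(rbind, out)
}

#' Net carbon gain between planting and a horizon age
#'
#' Distribution of `(R(t_end) - R(0+)) x v` over draws crossed with intact
#' values, where `R(0+)` uses the curve's age-zero limit rule. Equals
#' `predict_stocks` at `t_end` minus at `0`, draw by draw.
#'
#' @param fit A `buildup_fit`.
#' @param intact An [intact_stock_set()].
#' @param t_end Horizon in years (default 40).
#' @param compartment See [predict_stocks()].
#' @return List with `mean`, `lower`, `upper` (95% interval, MgC ha^-1) and
#'   `gains` (the draw x value matrix).
#' @export
net_gain <- function(fit, intact, t_end = 40, compartment = NULL) {
  stopifnot(t_end > 0)
  draws <- if (inherits(fit, "buildup_fit")) fit$draws else fit
  if (is.null(compartment) && inherits(fit, "buildup_fit") &&
      !is.na(fit$stratum))
    compartment <- strsplit(fit$stratum, ":", fixed = TRUE)[[1]][1]
  if (!is.null(compartment) && compartment != intact$compartment)
    stop("compartment mismatch")
  r_end <- curve_ratio(draws$rmax, draws$beta0, draws$beta1, t_end)
  r_0 <- curve_ratio(draws$rmax, draws$beta0, draws$beta1, 0)
  gains <- outer(r_end - r_0, intact$values)
  list(mean = mean(gains),
       lower = unname(stats::quantile(gains, 0.025)),
       upper = unname(stats::quantile(gains, 0.975)),
       gains = gains)
}

#' Ecosystem-level net gain by summing compartments draw-by-draw
#'
#' Adds per-compartment gain matrices with aligned draw indices, so the
#' ecosystem gain distribution respects the joint posterior draw ordering.
#' All matrices must share dimensions (fit the compartments with the same
#' sampler settings and supply equal-length intact sets, or pre-aggregate
#' the intact values to their means).
#'
#' @param ... Gain matrices (the `gains` element of [net_gain()] results).
#' @return List with `mean`, `lower`, `upper`, `gains`.
#' @export
combine_gains <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 1)
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1)
    stop("gain matrices must share dimensions to be combined draw-by-draw")
  total <- Reduce(`+`, mats)
  list(mean = mean(total),
       lower = unname(stats::quantile(total, 0.025)),
       upper = unname(stats::quantile(total, 0.975)),
       gains = total)
}
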