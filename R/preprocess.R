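# Soil carbon stock computation from layered cores and rescaling of sampled
# stocks to the 1-m reference depth.
#
# Unit analysis underlying the formulas: bulk density (g cm^-3) x depth (cm)
# x carbon fraction gives grams C per cm^2 of ground surface, and
# 1 g cm^-2 = 100 Mg ha^-1.

REFERENCE_DEPTH_CM <- 100

#' Soil carbon stock from a layered core profile
#'
#' Sums bulk density x layer thickness x carbon content over the profile's
#' layers, clipped at `max_depth_cm`; layers entirely below the clip depth
#' are ignored and a layer straddling it contributes only its part above.
#' The result is additive under any re-partition of the profile into finer
#' layers and monotone non-decreasing in `max_depth_cm`.
#'
#' @param profile Data frame of layers for one stand with columns `top_cm`,
#'   `bottom_cm`, `bulk_density_gcm3`, `carbon_pct` (as from
#'   [read_soil_profiles()]).
#' @param max_depth_cm Integration depth in cm (default 100, the reference
#'   depth).
#' @return Stock in MgC ha^-1, with attribute `shallow` set to `TRUE` when
#'   the profile does not reach `max_depth_cm` (the value then covers the
#'   available depth only) and attribute `depth_cm` giving the depth
#'   actually integrated.
#' @export
compute_soil_stock <- function(profile, max_depth_cm = REFERENCE_DEPTH_CM) {
  stopifnot(is.data.frame(profile), max_depth_cm > 0)
  top <- profile$top_cm
  bottom <- profile$bottom_cm
  thick <- pmax(0, pmin(bottom, max_depth_cm) - pmin(top, max_depth_cm))
  g_per_cm2 <- sum(profile$bulk_density_gcm3 * thick * profile$carbon_pct / 100)
  reached <- if (nrow(profile) > 0) max(bottom) else 0
  structure(g_per_cm2 * 100,
            shallow = reached < max_depth_cm,
            depth_cm = min(reached, max_depth_cm))
}

#' Rescale a sampled soil carbon stock to the 1-m reference depth
#'
#' Two methods are supported. `"depth_proportional"` assumes a uniform
#' stock density over depth: `stock / sampled_depth_cm * 100`. It is the
#' identity at 100 cm and is used both to extrapolate shallow cores and to
#' interpolate deep ones. `"bd_carbon"` reconstructs the 1-m stock from
#' core-average bulk density and carbon content as
#' `mean_bd * mean_c_pct * 100` (g cm^-3 x percent over 100 cm, in
#' MgC ha^-1); it needs `mean_bd` and `mean_c_pct` and is treated as the
#' secondary method (see [evaluate_scaling_methods()]).
#'
#' @param stock Sampled stock in MgC ha^-1 (>= 0).
#' @param sampled_depth_cm Depth over which `stock` was measured (cm > 0).
#' @param method `"depth_proportional"` (default) or `"bd_carbon"`.
#' @param mean_bd Core-average dry bulk density in g cm^-3 (bd_carbon only).
#' @param mean_c_pct Core-average carbon content in percent (bd_carbon only).
#' @return Stock rescaled to 100 cm, MgC ha^-1.
#' @export
scale_to_1m <- function(stock, sampled_depth_cm,
                        method = c("depth_proportional", "bd_carbon"),
                        mean_bd = NULL, mean_c_pct = NULL) {
  method <- match.arg(method)
  if (any(sampled_depth_cm <= 0)) stop("sampled_depth_cm must be > 0")
  if (any(stock < 0)) stop("stock must be >= 0")
  if (method == "depth_proportional") {
    stock / sampled_depth_cm * REFERENCE_DEPTH_CM
  } else {
    if (is.null(mean_bd) || is.null(mean_c_pct))
      stop("bd_carbon scaling needs mean_bd and mean_c_pct")
    # g cm^-3 x carbon fraction x 100 cm -> g cm^-2; x100 -> MgC ha^-1
    mean_bd * (mean_c_pct / 100) * REFERENCE_DEPTH_CM * 100
  }
}

# Depth-weighted core means used when full layer data are available.
.profile_means <- function(profile, max_depth_cm = REFERENCE_DEPTH_CM) {
  thick <- pmax(0, pmin(profile$bottom_cm, max_depth_cm) -
                  pmin(profile$top_cm, max_depth_cm))
  w <- thick / sum(thick)
  list(mean_bd = sum(w * profile$bulk_density_gcm3),
       mean_c_pct = sum(w * profile$carbon_pct))
}

#' Compare the two 1-m scaling methods by observed-vs-predicted regression
#'
#' For cores whose observed 1-m stock is known alongside a shallower or
#' deeper measurement, predicts the 1-m stock with each method and fits the
#' ordinary least-squares regression of observed (y) on predicted (x). The
#' method with the higher coefficient of determination is recommended.
#'
#' @param cores Data frame with columns `observed_1m` (MgC ha^-1),
#'   `stock` (stock at `depth_cm`), `depth_cm`, `mean_bd`, `mean_c_pct`.
#' @return A data frame with one row per method: `method`, `slope`,
#'   `intercept`, `r_squared`, plus attribute `recommended` naming the
#'   higher-R-squared method.
#' @export
evaluate_scaling_methods <- function(cores) {
  stopifnot(is.data.frame(cores))
  if (nrow(cores) < 3)
    stop("insufficient data: need at least 3 cores with observed 1-m stocks")
  pred <- list(
    depth_proportional = scale_to_1m(cores$stock, cores$depth_cm,
                                     "depth_proportional"),
    bd_carbon = scale_to_1m(cores$stock, cores$depth_cm, "bd_carbon",
                            mean_bd = cores$mean_bd,
                            mean_c_pct = cores$mean_c_pct)
  )
  rows <- lapply(names(pred), function(m) {
    y <- cores$observed_1m
    fit <- stats::lm(y ~ pred[[m]])
    data.frame(method = m,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = 1 - sum(stats::residuals(fit)^2) /
                 sum((y - mean(y))^2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "recommended") <- out$method[which.max(out$r_squared)]
  out
}

#' Harmonize a stands table to 1-m soil stocks
#'
#' Fills missing soil stocks from layered core profiles (when available) and
#' rescales all soil stocks to the 1-m reference depth with the
#' depth-proportional method. Stocks already sampled at exactly 100 cm pass
#' through untouched. Biomass compartments are left as is.
#'
#' @param stands A `stand_dataset`.
#' @param profiles Optional layered profiles from [read_soil_profiles()].
#' @param method Scaling method passed to [scale_to_1m()];
#'   `"bd_carbon"` requires `profiles` for the core means.
#' @return The stands data frame with `soil_c_mgha` at 1 m and
#'   `soil_depth_cm` set to 100 where scaling occurred.
#' @export
harmonize_stands <- function(stands, profiles = NULL,
                             method = "depth_proportional") {
  df <- as.data.frame(stands)
  if (!is.null(profiles)) {
    for (sid in unique(profiles$stand_id)) {
      i <- which(df$stand_id == sid)
      if (length(i) != 1) next
      if (!is.na(df$soil_c_mgha[i])) next
      prof <- profiles[profiles$stand_id == sid, , drop = FALSE]
      st <- compute_soil_stock(prof, REFERENCE_DEPTH_CM)
      df$soil_c_mgha[i] <- as.numeric(st)
      df$soil_depth_cm[i] <- attr(st, "depth_cm")
    }
  }
  needs <- which(!is.na(df$soil_c_mgha) & !is.na(df$soil_depth_cm) &
                   df$soil_depth_cm != REFERENCE_DEPTH_CM)
  for (i in needs) {
    if (method == "bd_carbon" && !is.null(profiles) &&
        df$stand_id[i] %in% profiles$stand_id) {
      prof <- profiles[profiles$stand_id == df$stand_id[i], , drop = FALSE]
      m <- .profile_means(prof, max_depth_cm = max(prof$bottom_cm))
      df$soil_c_mgha[i] <- scale_to_1m(df$soil_c_mgha[i], df$soil_depth_cm[i],
                                       "bd_carbon", m$mean_bd, m$mean_c_pct)
    } else {
      df$soil_c_mgha[i] <- scale_to_1m(df$soil_c_mgha[i], df$soil_depth_cm[i],
                                       "depth_proportional")
    }
    df$soil_depth_cm[i] <- REFERENCE_DEPTH_CM
  }
  attributes(df)$provenance <- attr(stands, "provenance")
  class(df) <- c("stand_dataset", "data.frame")
  df
}
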