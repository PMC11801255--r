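# End-to-end orchestration: simulate -> preprocess -> pair -> fit ->
# summarize -> predict, with file handoffs between stages and a JSON run
# manifest (seed, config hash, row counts) so runs are reproducible and
# auditable.

.config_hash <- function(config) {
  # stable digest of the config without external dependencies
  ser <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  sum(utf8ToInt(as.character(ser)) *
        (seq_along(utf8ToInt(as.character(ser))) %% 97 + 1)) %% 1e9
}

#' Run the full buildup-analysis pipeline
#'
#' Stages, each writing its output CSV into `out_dir`:
#' \enumerate{
#'   \item simulate (when no `stands` input is given): synthetic dataset via
#'     [simulate_dataset()] -> `stands.csv`
#'   \item preprocess: validation, exclusion filters, soil-stock
#'     harmonization -> `harmonized.csv`
#'   \item pair: reference matching and ratio construction ->
#'     `ratios.csv`
#'   \item fit: posterior sampling per retained stratum -> `posterior.csv`,
#'     `diagnostics.csv`
#'   \item summarize: curve summaries over ages -> `curve_summary.csv`
#'   \item predict (when intact value sets are given): predicted stocks ->
#'     `predicted.csv`
#' }
#' Exactly one `manifest.json` is written per run. Errors carry condition
#' classes: `pipeline_input_error` for missing inputs (suggested exit
#' status 2) and `buildup_convergence_error` for failed fits (status 3).
#'
#' @param config A list (or path to a YAML file) with optional entries:
#'   `seed` (default 1), `out_dir` (default `tempdir()`), `stands` /
#'   `profiles` (input CSV paths; omit `stands` to simulate),
#'   `scaling` (default `"depth_proportional"`), `pairing` (arguments to
#'   [pairing_config()]), `fit` (arguments to [fit_config()]), `strata`
#'   (keys to fit; default all retained), `ages` (default
#'   `c(1, 5, 10, 20, 30, 40)`), `intact` (named list
#'   `compartment -> CSV path` of single-column intact value sets),
#'   `synthetic` (arguments to [synthetic_config()]).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(structure(class = c("pipeline_input_error", "error", "condition"),
                     list(message = paste("config file not found:", config),
                          call = sys.call(-1))))
    config <- yaml::read_yaml(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) tempfile("pipeline") else
    config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ages <- if (is.null(config$ages)) c(1, 5, 10, 20, 30, 40) else config$ages
  counts <- list()

  # --- stage: input / simulate -------------------------------------------
  if (!is.null(config$stands)) {
    if (!file.exists(config$stands))
      stop(structure(class = c("pipeline_input_error", "error", "condition"),
                     list(message = paste("stands file not found:",
                                          config$stands),
                          call = sys.call(-1))))
    stands <- read_stands(config$stands)
  } else {
    syn_args <- if (is.null(config$synthetic)) list() else config$synthetic
    syn_args$seed <- seed
    sim <- simulate_dataset(do.call(synthetic_config, syn_args))
    stands <- sim$stands
    write_stands(stands, file.path(out_dir, "stands.csv"))
  }
  counts$stands <- nrow(stands)

  profiles <- NULL
  if (!is.null(config$profiles)) {
    if (!file.exists(config$profiles))
      stop(structure(class = c("pipeline_input_error", "error", "condition"),
                     list(message = paste("profiles file not found:",
                                          config$profiles),
                          call = sys.call(-1))))
    profiles <- read_soil_profiles(config$profiles)
  }

  # --- stage: preprocess -------------------------------------------------
  filtered <- apply_exclusion_filters(stands)
  scaling <- if (is.null(config$scaling)) "depth_proportional" else
    config$scaling
  harmonized <- harmonize_stands(filtered$data, profiles, method = scaling)
  write_stands(harmonized, file.path(out_dir, "harmonized.csv"))
  counts$harmonized <- nrow(harmonized)

  # --- stage: pair -------------------------------------------------------
  pair_args <- if (is.null(config$pairing)) list() else config$pairing
  pair_cfg <- do.call(pairing_config, pair_args)
  obs <- build_ratios(harmonized, pair_cfg)
  utils::write.csv(as.data.frame(obs), file.path(out_dir, "ratios.csv"),
                   row.names = FALSE, quote = FALSE)
  counts$ratios <- nrow(obs)
  st <- build_strata(obs, pair_cfg)

  # --- stage: fit --------------------------------------------------------
  keys <- if (is.null(config$strata)) names(st$strata) else
    intersect(config$strata, names(st$strata))
  fit_args <- if (is.null(config$fit)) list() else config$fit
  fit_args$seed <- seed
  base_fit_cfg <- do.call(fit_config, fit_args)
  fits <- list()
  post_rows <- list()
  diag_rows <- list()
  curve_rows <- list()
  for (key in keys) {
    fits[[key]] <- fit_posterior(st$strata[[key]], cfg = base_fit_cfg,
                                 stratum = key)
    d <- fits[[key]]$draws
    post_rows[[key]] <- cbind(stratum = key,
                              d[, c("chain", "iteration", "log_rmax",
                                    "beta0", "beta1", "log_sigma")])
    diag_rows[[key]] <- cbind(stratum = key, fits[[key]]$diagnostics)
    curve_rows[[key]] <- cbind(stratum = key,
                               summarize_curve(fits[[key]], ages))
  }
  if (length(fits) > 0) {
    utils::write.csv(do.call(rbind, post_rows),
                     file.path(out_dir, "posterior.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(do.call(rbind, diag_rows),
                     file.path(out_dir, "diagnostics.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(do.call(rbind, curve_rows),
                     file.path(out_dir, "curve_summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  counts$strata_fit <- length(fits)

  # --- stage: predict ----------------------------------------------------
  if (!is.null(config$intact) && length(fits) > 0) {
    pred_rows <- list()
    for (comp in names(config$intact)) {
      path <- config$intact[[comp]]
      if (!file.exists(path))
        stop(structure(class = c("pipeline_input_error", "error",
                                 "condition"),
                       list(message = paste("intact values file not found:",
                                            path),
                            call = sys.call(-1))))
      vals <- utils::read.csv(path)[[1]]
      iset <- intact_stock_set(comp, vals, source = path)
      key <- paste(comp, "all", sep = ":")
      if (is.null(fits[[key]])) next
      pred <- predict_stocks(fits[[key]], iset, ages = ages)
      pred_rows[[comp]] <- cbind(compartment = comp, pred)
    }
    if (length(pred_rows) > 0) {
      utils::write.csv(do.call(rbind, pred_rows),
                       file.path(out_dir, "predicted.csv"),
                       row.names = FALSE, quote = FALSE)
      counts$predicted <- sum(vapply(pred_rows, nrow, integer(1)))
    }
  }

  manifest <- list(
    command = "run_pipeline",
    seed = seed,
    config_hash = .config_hash(config),
    out_dir = out_dir,
    row_counts = counts,
    stratum_report = st$report,
    exclusion_report = filtered$report,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(manifest)
}
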