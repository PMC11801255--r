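# Planted-to-intact reference matching and buildup-ratio construction.
#
# A planted stand is compared with intact stands of the same geomorphic
# class: locally (all intact stands within the local distance threshold) or,
# failing that, remotely (nearest intact site cluster in the same climatic
# band of absolute latitude). Unmatched stands are dropped with a logged
# reason.

#' Pairing configuration
#'
#' @param local_threshold_km Maximum distance for a local match (default 10,
#'   the within-site scale of the largest geomorphic sites).
#' @param remote_max_km Maximum distance for a remote fallback match
#'   (default 400, covering the observed remote range of a few hundred km).
#' @param climatic_band_deg Width of the absolute-latitude bands used as the
#'   climatic-class proxy (default 10 degrees).
#' @param min_stratum_obs Minimum observations for a stratum to be modelled
#'   (default 30).
#' @param min_stratum_studies Minimum distinct studies per stratum (default
#'   6).
#' @param use_cluster_centroid Measure remote distances to the intact site
#'   cluster centroid (`TRUE`, default) or to the nearest individual stand.
#' @return A `pairing_config` list.
#' @export
pairing_config <- function(local_threshold_km = 10, remote_max_km = 400,
                           climatic_band_deg = 10, min_stratum_obs = 30,
                           min_stratum_studies = 6,
                           use_cluster_centroid = TRUE) {
  stopifnot(local_threshold_km > 0, remote_max_km > 0, climatic_band_deg > 0,
            min_stratum_obs > 0, min_stratum_studies > 0)
  structure(list(local_threshold_km = local_threshold_km,
                 remote_max_km = remote_max_km,
                 climatic_band_deg = climatic_band_deg,
                 min_stratum_obs = min_stratum_obs,
                 min_stratum_studies = min_stratum_studies,
                 use_cluster_centroid = use_cluster_centroid),
            class = "pairing_config")
}

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Vectorized over the second point.
#'
#' @param lat1,lon1 First point, decimal degrees.
#' @param lat2,lon2 Second point(s), decimal degrees.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(abs(lat1) <= 90, abs(lat2) <= 90,
            abs(lon1) <= 180, abs(lon2) <= 180)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088)
}

.climatic_band <- function(lat, band_deg) floor(abs(lat) / band_deg)

#' Match a planted stand to intact reference stands
#'
#' Rule (1): every intact stand of the same geomorphic class within
#' `local_threshold_km` forms the local reference set. Rule (2): otherwise,
#' intact stands of the same geomorphic class and the same climatic band of
#' absolute latitude are clustered by `site_id`, and the nearest cluster
#' within `remote_max_km` (centroid distance by default) is used whole.
#' Rule (3): otherwise the stand is unmatched. Deterministic given the
#' inputs: candidates are ordered by `stand_id` and cluster ties broken by
#' `site_id`.
#'
#' @param planted One-row data frame for the planted stand.
#' @param pool Data frame of intact stands.
#' @param cfg A [pairing_config()].
#' @return A list with `reference_ids`, `match_mode` (`"local"` or
#'   `"remote"`) and `distance_km`, or `NULL` when unmatched.
#' @export
match_references <- function(planted, pool, cfg = pairing_config()) {
  stopifnot(nrow(planted) == 1)
  pool <- pool[pool$role == "intact", , drop = FALSE]
  pool <- pool[order(pool$stand_id), , drop = FALSE]
  same_class <- pool[pool$geomorphic_class == planted$geomorphic_class, ,
                     drop = FALSE]
  if (nrow(same_class) == 0) return(NULL)
  d <- haversine_km(planted$latitude, planted$longitude,
                    same_class$latitude, same_class$longitude)
  local <- d <= cfg$local_threshold_km
  if (any(local)) {
    return(list(reference_ids = same_class$stand_id[local],
                match_mode = "local",
                distance_km = max(d[local])))
  }
  band <- .climatic_band(planted$latitude, cfg$climatic_band_deg)
  cand <- same_class[.climatic_band(same_class$latitude,
                                    cfg$climatic_band_deg) == band, ,
                     drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  sites <- sort(unique(cand$site_id))
  dist_to <- vapply(sites, function(s) {
    cl <- cand[cand$site_id == s, , drop = FALSE]
    if (cfg$use_cluster_centroid) {
      haversine_km(planted$latitude, planted$longitude,
                   mean(cl$latitude), mean(cl$longitude))
    } else {
      min(haversine_km(planted$latitude, planted$longitude,
                       cl$latitude, cl$longitude))
    }
  }, numeric(1))
  best <- which.min(dist_to)
  if (dist_to[best] > cfg$remote_max_km) return(NULL)
  cl <- cand[cand$site_id == sites[best], , drop = FALSE]
  list(reference_ids = cl$stand_id,
       match_mode = "remote",
       distance_km = unname(dist_to[best]))
}

#' Buildup ratio of one planted stand for one compartment
#'
#' Divides the planted stand's compartment stock by the arithmetic mean of
#' the reference stocks, ignoring references that do not report the
#' compartment (missing values are never zero-filled). Scale-invariant:
#' multiplying planted and reference stocks by a common factor leaves the
#' ratio unchanged.
#'
#' @param planted One-row data frame for the planted stand.
#' @param refs Data frame of matched intact stands.
#' @param compartment `"agb"`, `"bgb"` or `"soil"`.
#' @param match Optional match metadata from [match_references()].
#' @return One-row data frame (`ratio_observation`) or `NULL` when either
#'   side lacks the compartment.
#' @export
compute_ratio <- function(planted, refs, compartment, match = NULL) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  col <- paste0(compartment, "_c_mgha")
  cd <- planted[[col]]
  cu <- refs[[col]]
  cu <- cu[!is.na(cu)]
  if (is.na(cd) || length(cu) == 0) return(NULL)
  mu <- mean(cu)
  if (mu == 0) stop("undefined ratio: mean reference stock is zero for ",
                    planted$stand_id, " (", compartment, ")")
  data.frame(
    planted_id = planted$stand_id,
    compartment = compartment,
    ratio = cd / mu,
    age_yr = planted$age_yr,
    composition_group = planted$composition,
    match_mode = if (is.null(match)) NA_character_ else match$match_mode,
    reference_distance_km = if (is.null(match)) NA_real_ else match$distance_km,
    n_refs = length(cu),
    reference_ids = paste(refs$stand_id[!is.na(refs[[col]])], collapse = ";"),
    study_id = planted$study_id,
    stringsAsFactors = FALSE
  )
}

#' Build all buildup-ratio observations for a harmonized dataset
#'
#' Runs [match_references()] for every planted stand and [compute_ratio()]
#' for every compartment both sides report. Planted stands with no admissible
#' reference are listed in the `unmatched` attribute.
#'
#' @param stands A harmonized `stand_dataset` (soil stocks at 1 m).
#' @param cfg A [pairing_config()].
#' @return Data frame of ratio observations with attribute `unmatched`.
#' @export
build_ratios <- function(stands, cfg = pairing_config()) {
  df <- as.data.frame(stands)
  planted <- df[df$role == "planted", , drop = FALSE]
  pool <- df[df$role == "intact", , drop = FALSE]
  out <- list()
  unmatched <- character(0)
  for (i in seq_len(nrow(planted))) {
    p <- planted[i, , drop = FALSE]
    m <- match_references(p, pool, cfg)
    if (is.null(m)) {
      unmatched <- c(unmatched, p$stand_id)
      next
    }
    refs <- pool[pool$stand_id %in% m$reference_ids, , drop = FALSE]
    for (comp in COMPARTMENTS) {
      r <- compute_ratio(p, refs, comp, match = m)
      if (!is.null(r) && is.finite(r$ratio) && r$ratio > 0)
        out[[length(out) + 1]] <- r
    }
  }
  obs <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(planted_id = character(0), compartment = character(0),
               ratio = numeric(0), age_yr = numeric(0),
               composition_group = character(0), match_mode = character(0),
               reference_distance_km = numeric(0), n_refs = integer(0),
               reference_ids = character(0), study_id = character(0),
               stringsAsFactors = FALSE)
  rownames(obs) <- NULL
  structure(obs, unmatched = unmatched)
}

#' Group ratio observations into model strata
#'
#' A stratum is a compartment crossed with a composition group: each genus,
#' `"mixed"`, and the pooled `"all"` group containing every observation of
#' the compartment. Strata with fewer than `min_stratum_obs` observations or
#' fewer than `min_stratum_studies` distinct studies are excluded and
#' reported (with the defaults, a stratum of 27 observations from 5 studies
#' is dropped).
#'
#' @param obs Ratio observations from [build_ratios()].
#' @param cfg A [pairing_config()].
#' @return A list with `strata` (named list of observation data frames,
#'   names `compartment:group`) and `report` (data frame of per-stratum
#'   counts and the retained/excluded decision).
#' @export
build_strata <- function(obs, cfg = pairing_config()) {
  strata <- list()
  report <- list()
  if (nrow(obs) == 0)
    return(list(strata = strata,
                report = data.frame(stratum = character(0), n_obs = integer(0),
                                    n_studies = integer(0),
                                    retained = logical(0))))
  for (comp in intersect(COMPARTMENTS, unique(obs$compartment))) {
    sub <- obs[obs$compartment == comp, , drop = FALSE]
    groups <- c("all", intersect(COMPOSITION_GROUPS,
                                 unique(sub$composition_group)))
    for (g in groups) {
      sel <- if (g == "all") sub else
        sub[sub$composition_group == g, , drop = FALSE]
      n_obs <- nrow(sel)
      n_studies <- length(unique(sel$study_id))
      keep <- n_obs >= cfg$min_stratum_obs &&
        n_studies >= cfg$min_stratum_studies
      key <- paste(comp, g, sep = ":")
      report[[key]] <- data.frame(stratum = key, n_obs = n_obs,
                                  n_studies = n_studies, retained = keep,
                                  stringsAsFactors = FALSE)
      if (keep) strata[[key]] <- sel
    }
  }
  list(strata = strata,
       report = do.call(rbind, c(report, list(make.row.names = FALSE))))
}
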