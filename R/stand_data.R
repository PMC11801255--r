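# Stand-level carbon-stock records: schema, validation, exclusion filters.
#
# Units are fixed internally: stocks in MgC ha^-1, depths in cm, ages in
# years, coordinates in decimal degrees (WGS84). Conversion happens at the
# I/O boundary or not at all.

GEOMORPHIC_CLASSES <- c("delta", "estuary", "lagoon", "open_coast",
                        "oceanic_island")
COMPOSITION_GROUPS <- c("mixed", "Avicennia", "Kandelia", "Rhizophora",
                        "Sonneratia")
COMPARTMENTS <- c("agb", "bgb", "soil")

STANDS_COLUMNS <- c("stand_id", "role", "origin", "latitude", "longitude",
                    "site_id", "geomorphic_class", "age_yr", "composition",
                    "agb_c_mgha", "bgb_c_mgha", "soil_c_mgha",
                    "soil_depth_cm", "n_samples", "study_id")
PROFILES_COLUMNS <- c("stand_id", "top_cm", "bottom_cm", "bulk_density_gcm3",
                      "carbon_pct")

#' Column schema of a stands table
#'
#' @return Character vector of the required column names of `stands.csv`, in
#'   order.
#' @export
stands_schema <- function() STANDS_COLUMNS

#' Column schema of a soil-profiles table
#'
#' @return Character vector of the required column names of `profiles.csv`.
#' @export
profiles_schema <- function() PROFILES_COLUMNS

# Row-level invariant checks; returns character vector of violation reasons
# (empty when the row is valid).
.stand_row_problems <- function(row) {
  reasons <- character(0)
  num <- function(x) !is.na(x) && is.finite(x)
  if (is.na(row$stand_id) || !nzchar(row$stand_id))
    reasons <- c(reasons, "missing stand_id")
  if (!row$role %in% c("planted", "intact"))
    reasons <- c(reasons, "invalid role")
  if (!is.na(row$origin) && !row$origin %in% c("afforested", "restored", "intact"))
    reasons <- c(reasons, "invalid origin")
  if (!num(row$latitude) || abs(row$latitude) > 90)
    reasons <- c(reasons, "latitude out of range")
  if (!num(row$longitude) || abs(row$longitude) > 180)
    reasons <- c(reasons, "longitude out of range")
  if (is.na(row$geomorphic_class) ||
      !row$geomorphic_class %in% GEOMORPHIC_CLASSES)
    reasons <- c(reasons, "unknown geomorphic class")
  if (identical(row$role, "planted") && !num(row$age_yr))
    reasons <- c(reasons, "missing age")
  if (num(row$age_yr) && row$age_yr < 0)
    reasons <- c(reasons, "negative age")
  stocks <- c(row$agb_c_mgha, row$bgb_c_mgha, row$soil_c_mgha)
  if (all(is.na(stocks)))
    reasons <- c(reasons, "no compartment stock")
  if (any(stocks < 0, na.rm = TRUE))
    reasons <- c(reasons, "negative stock")
  if (!is.na(row$soil_c_mgha) &&
      (!num(row$soil_depth_cm) || row$soil_depth_cm <= 0))
    reasons <- c(reasons, "soil stock without sampled depth")
  if (!is.na(row$n_samples) && row$n_samples < 1)
    reasons <- c(reasons, "n_samples < 1")
  reasons
}

.as_character_cols <- c("stand_id", "role", "origin", "site_id",
                        "geomorphic_class", "composition", "study_id")
.as_numeric_cols <- c("latitude", "longitude", "age_yr", "agb_c_mgha",
                      "bgb_c_mgha", "soil_c_mgha", "soil_depth_cm",
                      "n_samples")

.coerce_stands <- function(df) {
  for (cc in .as_character_cols) {
    x <- as.character(df[[cc]])
    x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
    df[[cc]] <- trimws(x)
  }
  for (nc in .as_numeric_cols) {
    raw <- df[[nc]]
    suppressWarnings(val <- as.numeric(as.character(raw)))
    bad <- !is.na(raw) & nzchar(trimws(as.character(raw))) & is.na(val)
    attr(val, "unparseable") <- which(bad)
    df[[nc]] <- val
  }
  df
}

#' Read and validate a stands table
#'
#' Reads a UTF-8, comma-separated stands file (see [stands_schema()] for the
#' required header; empty cells are missing values) and validates every row
#' against the record invariants: planted stands carry an age, coordinates
#' are finite and in range, the geomorphic class belongs to the closed
#' five-class vocabulary, at least one compartment stock is present, and a
#' soil stock implies a sampled depth. Unknown geomorphic classes are
#' validation errors, never coerced.
#'
#' @param path Path to the CSV file (or a data frame with the same columns,
#'   useful for in-memory pipelines).
#' @param strict If `TRUE`, any invalid row is an error; if `FALSE`
#'   (default), invalid rows are dropped and logged.
#' @return A `stand_dataset`: a data frame of valid records with attributes
#'   `validation_log` (data frame of dropped rows and reasons) and
#'   `provenance` (source description).
#' @export
read_stands <- function(path, strict = FALSE) {
  if (is.data.frame(path)) {
    df <- as.data.frame(path, stringsAsFactors = FALSE)
    src <- "<data.frame>"
  } else {
    if (!file.exists(path)) stop("stands file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    src <- path
  }
  missing_cols <- setdiff(STANDS_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("stands schema error: missing columns ",
         paste(missing_cols, collapse = ", "))
  df <- df[, STANDS_COLUMNS, drop = FALSE]
  df <- .coerce_stands(df)

  n <- nrow(df)
  reasons <- vector("list", n)
  for (nc in .as_numeric_cols) {
    bad <- attr(df[[nc]], "unparseable")
    for (i in bad) reasons[[i]] <- c(reasons[[i]], paste0("unparseable ", nc))
    attr(df[[nc]], "unparseable") <- NULL
  }
  for (i in seq_len(n)) {
    reasons[[i]] <- c(reasons[[i]], .stand_row_problems(df[i, ]))
  }
  # dataset-level invariants, assessed over the rows that pass row checks
  dup <- duplicated(df$stand_id) & !is.na(df$stand_id)
  for (i in which(dup)) reasons[[i]] <- c(reasons[[i]], "duplicate stand_id")
  row_ok <- vapply(reasons, length, integer(1)) == 0
  cls_by_site <- tapply(df$geomorphic_class[row_ok], df$site_id[row_ok],
                        function(x) length(unique(stats::na.omit(x))))
  multi <- names(cls_by_site)[!is.na(cls_by_site) & cls_by_site > 1]
  for (i in which(df$site_id %in% multi & row_ok))
    reasons[[i]] <- c(reasons[[i]], "site_id maps to multiple geomorphic classes")

  bad_rows <- which(vapply(reasons, length, integer(1)) > 0)
  if (strict && length(bad_rows) > 0) {
    stop("invalid stand rows: ",
         paste(sprintf("%s (%s)", df$stand_id[bad_rows],
                       vapply(reasons[bad_rows], paste, "", collapse = "; ")),
               collapse = " | "))
  }
  log <- data.frame(
    row = bad_rows,
    stand_id = df$stand_id[bad_rows],
    reason = vapply(reasons[bad_rows], paste, "", collapse = "; "),
    stringsAsFactors = FALSE
  )
  out <- df[setdiff(seq_len(n), bad_rows), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            validation_log = log,
            provenance = src,
            class = c("stand_dataset", "data.frame"))
}

#' Write a stands table
#'
#' Inverse of [read_stands()]: writes the dataset as UTF-8 CSV with the
#' documented header, empty cells for missing values and unquoted numerics,
#' so that a read/write round trip is the identity field for field.
#'
#' @param ds A `stand_dataset` or compatible data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stands <- function(ds, path) {
  df <- as.data.frame(ds)[, STANDS_COLUMNS, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Read and validate layered soil-core profiles
#'
#' Each stand's layers must be contiguous and non-overlapping from 0 cm
#' downward, with `bottom_cm > top_cm`, positive bulk density and carbon
#' content in `[0, 100]` percent. Layers violating their invariants are
#' rejected; a stand whose layer stack is broken (gap, overlap, or not
#' starting at the surface) is rejected whole.
#'
#' @param path Path to the CSV file (see [profiles_schema()]) or a data
#'   frame.
#' @param strict If `TRUE`, violations are errors instead of logged drops.
#' @return A data frame of valid layers, ordered by stand and depth, with a
#'   `validation_log` attribute.
#' @export
read_soil_profiles <- function(path, strict = FALSE) {
  if (is.data.frame(path)) {
    df <- as.data.frame(path, stringsAsFactors = FALSE)
  } else {
    if (!file.exists(path)) stop("profiles file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  }
  missing_cols <- setdiff(PROFILES_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("profiles schema error: missing columns ",
         paste(missing_cols, collapse = ", "))
  df <- df[, PROFILES_COLUMNS, drop = FALSE]
  df$stand_id <- trimws(as.character(df$stand_id))
  for (nc in setdiff(PROFILES_COLUMNS, "stand_id"))
    suppressWarnings(df[[nc]] <- as.numeric(as.character(df[[nc]])))

  bad_layer <- with(df, is.na(top_cm) | is.na(bottom_cm) |
                      is.na(bulk_density_gcm3) | is.na(carbon_pct) |
                      top_cm < 0 | bottom_cm <= top_cm |
                      bulk_density_gcm3 <= 0 |
                      carbon_pct < 0 | carbon_pct > 100)
  log <- data.frame(stand_id = df$stand_id[bad_layer],
                    reason = rep("invalid layer bounds or values",
                                 sum(bad_layer)),
                    stringsAsFactors = FALSE)
  if (strict && any(bad_layer))
    stop("invalid soil layers for stands: ",
         paste(unique(df$stand_id[bad_layer]), collapse = ", "))
  df <- df[!bad_layer, , drop = FALSE]
  df <- df[order(df$stand_id, df$top_cm), , drop = FALSE]

  bad_stand <- character(0)
  for (sid in unique(df$stand_id)) {
    lay <- df[df$stand_id == sid, ]
    ok <- isTRUE(all.equal(lay$top_cm[1], 0)) &&
      all(abs(lay$top_cm[-1] - lay$bottom_cm[-nrow(lay)]) < 1e-8)
    if (!ok) bad_stand <- c(bad_stand, sid)
  }
  if (strict && length(bad_stand) > 0)
    stop("non-contiguous soil profiles for stands: ",
         paste(bad_stand, collapse = ", "))
  if (length(bad_stand) > 0) {
    log <- rbind(log, data.frame(stand_id = bad_stand,
                                 reason = rep("non-contiguous profile",
                                              length(bad_stand)),
                                 stringsAsFactors = FALSE))
    df <- df[!df$stand_id %in% bad_stand, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, validation_log = log, class = c("soil_profiles", "data.frame"))
}

#' Apply the meta-analysis exclusion criteria
#'
#' Removes records that cannot enter the ratio analysis: missing geographic
#' location, missing species composition, missing stand age (planted stands
#' only), and unreplicated data (`n_samples == 1`, a single tree or soil core
#' per site). Each removed record is attributed to the first criterion it
#' fails, so the per-criterion counts sum to the number of removals. The
#' operation is idempotent.
#'
#' @param ds A `stand_dataset` from [read_stands()].
#' @return A list with `data` (the filtered `stand_dataset`) and `report`
#'   (data frame of per-criterion removal counts).
#' @export
apply_exclusion_filters <- function(ds) {
  df <- as.data.frame(ds)
  criteria <- list(
    missing_location = is.na(df$latitude) | is.na(df$longitude),
    missing_composition = is.na(df$composition),
    missing_age = df$role == "planted" & is.na(df$age_yr),
    no_replication = !is.na(df$n_samples) & df$n_samples == 1
  )
  assigned <- rep(NA_character_, nrow(df))
  for (nm in names(criteria)) {
    hit <- criteria[[nm]] & is.na(assigned)
    assigned[hit] <- nm
  }
  report <- data.frame(
    criterion = names(criteria),
    removed = vapply(names(criteria), function(nm)
      sum(assigned == nm, na.rm = TRUE), integer(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  keep <- is.na(assigned)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$validation_log <- attr(ds, "validation_log")
  attributes(out)$provenance <- attr(ds, "provenance")
  class(out) <- c("stand_dataset", "data.frame")
  list(data = out, report = report)
}

#' @export
print.stand_dataset <- function(x, ...) {
  cat(sprintf("<stand_dataset> %d records (%d planted, %d intact)\n",
              nrow(x), sum(x$role == "planted"), sum(x$role == "intact")))
  log <- attr(x, "validation_log")
  if (!is.null(log) && nrow(log) > 0)
    cat(sprintf("  %d rows dropped at validation\n", nrow(log)))
  NextMethod()
}
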