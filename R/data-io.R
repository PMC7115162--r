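#' Observation tables of ground measurements and satellite observations
#'
#' The method operates on point observations: per-sample dry and wet
#' above-ground biomass (kg m^-2), volumetric soil moisture (m^3 m^-3), HH and
#' HV backscatter in linear power units, the radar incidence angle (degrees)
#' and NDVI. `read_observations()` reads such a table from CSV, validates it,
#' and records how many leading rows are calibration points;
#' `corn_observations()` returns the packaged 66-point corn dataset on which
#' the method was developed (the first 23 rows are calibration points, the
#' remaining 43 validation points).
#'
#' Backscatter is stored and consumed in linear power units throughout; see
#' [db_to_power()] if your extraction pipeline reports decibels.
#'
#' @param path Path to a CSV file with exactly the columns `point_no`,
#'   `dry_biomass`, `wet_biomass`, `soil_moisture`, `hh_backscatter`,
#'   `hv_backscatter`, `incidence_angle`, `ndvi` (in any order), one header
#'   row, one row per observation point.
#' @param n_calibration Number of leading rows that are calibration points.
#'   The split is positional because the partition is a property of the study
#'   design, not encoded in a column.
#' @return A tibble of class `obs_table` with the eight columns above in
#'   canonical order and an `n_calibration` attribute.
#' @seealso [split_observations()], [summarize_observations()]
#' @examples
#' obs <- corn_observations()
#' nrow(obs)
#' attr(obs, "n_calibration")
#' @export
read_observations <- function(path, n_calibration = 23) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(paste0("input file not found: ", path))
  }
  df <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE),
    error = function(e) abort(paste0("could not parse '", path, "' as CSV: ",
                                     conditionMessage(e)))
  )
  as_obs_table(df, n_calibration = n_calibration)
}

obs_columns <- c("point_no", "dry_biomass", "wet_biomass", "soil_moisture",
                 "hh_backscatter", "hv_backscatter", "incidence_angle", "ndvi")

#' Validate a data frame as an observation table
#'
#' Checks the schema (exactly the eight canonical columns) and the physical
#' invariants of every record: wet biomass at least dry biomass, soil moisture
#' a volumetric fraction in \[0, 1\], strictly positive backscatter power,
#' incidence angle in (0, 90) degrees, NDVI in \[-1, 1\], unique ascending
#' point numbers.
#'
#' @param df A data frame with the canonical columns.
#' @inheritParams read_observations
#' @return A validated `obs_table` tibble.
#' @export
as_obs_table <- function(df, n_calibration = 23) {
  missing <- setdiff(obs_columns, names(df))
  if (length(missing)) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), obs_columns)
  if (length(extra)) {
    abort(paste0("unexpected column(s): ", paste(extra, collapse = ", ")))
  }
  df <- as_tibble(df)[obs_columns]
  if (nrow(df) == 0) abort("observation table has no rows")
  for (col in obs_columns) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]])) {
      abort(paste0("column '", col, "' must be numeric with no missing values"))
    }
  }

  check <- function(ok, field) {
    if (all(ok)) return(invisible())
    bad <- df$point_no[which(!ok)[1]]
    abort(paste0("invalid value in field '", field, "' at point_no ", bad))
  }
  check(df$dry_biomass >= 0, "dry_biomass")
  check(df$wet_biomass >= df$dry_biomass, "wet_biomass")
  check(df$soil_moisture >= 0 & df$soil_moisture <= 1, "soil_moisture")
  check(df$hh_backscatter > 0, "hh_backscatter")
  check(df$hv_backscatter > 0, "hv_backscatter")
  check(df$incidence_angle > 0 & df$incidence_angle < 90, "incidence_angle")
  check(df$ndvi >= -1 & df$ndvi <= 1, "ndvi")
  if (anyDuplicated(df$point_no) || is.unsorted(df$point_no, strictly = TRUE)) {
    abort("point_no values must be unique and ascending")
  }

  n_calibration <- as.integer(n_calibration)
  if (length(n_calibration) != 1 || is.na(n_calibration) ||
      n_calibration < 1 || n_calibration > nrow(df)) {
    abort("n_calibration must be between 1 and the number of records")
  }
  structure(df, n_calibration = n_calibration,
            class = c("obs_table", class(df)))
}

#' @rdname read_observations
#' @export
corn_observations <- function(n_calibration = 23) {
  read_observations(
    system.file("extdata", "corn_biomass_points.csv", package = "wcmbiomass",
                mustWork = TRUE),
    n_calibration = n_calibration
  )
}

#' Write an observation table to CSV
#'
#' Writes the canonical eight-column CSV layout so that reading the file back
#' reproduces the table exactly.
#'
#' @param obs An `obs_table` (or data frame with the canonical columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  obs <- as_obs_table(obs, n_calibration = attr(obs, "n_calibration") %||% 1L)
  readr::write_csv(as_tibble(obs)[obs_columns], path, progress = FALSE)
  invisible(path)
}

#' Split an observation table into calibration and validation points
#'
#' The first `n_calibration` rows (in file order) are the calibration points
#' used to fit the Water Cloud Model and the optical models; the remainder are
#' validation points. The two parts concatenate back to the original table.
#'
#' @param obs An `obs_table`, e.g. from [read_observations()].
#' @return A list with tibbles `calibration` and `validation`.
#' @examples
#' parts <- split_observations(corn_observations())
#' nrow(parts$calibration) # 23
#' nrow(parts$validation)  # 43
#' @export
split_observations <- function(obs) {
  n_cal <- attr(obs, "n_calibration")
  if (is.null(n_cal)) abort("`obs` has no n_calibration attribute; use read_observations() or as_obs_table()")
  df <- strip_obs(obs)
  list(calibration = df[seq_len(n_cal), ],
       validation = df[setdiff(seq_len(nrow(df)), seq_len(n_cal)), ])
}

#' Per-field ranges of a set of observations
#'
#' Exact minimum, maximum and count for every numeric field — the summary used
#' to report the biomass, soil-moisture and incidence-angle ranges spanned by
#' a calibration set.
#'
#' @param records A data frame of observation records (any subset of rows).
#' @return A tibble with columns `field`, `min`, `max`, `n`.
#' @examples
#' summarize_observations(split_observations(corn_observations())$calibration)
#' @export
summarize_observations <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must be a non-empty data frame")
  }
  fields <- setdiff(intersect(obs_columns, names(records)), "point_no")
  purrr::map_dfr(fields, function(f) {
    tibble(field = f, min = min(records[[f]]), max = max(records[[f]]),
           n = nrow(records))
  })
}

#' Convert between decibel and linear-power backscatter
#'
#' The model consumes backscatter in linear power units; extraction pipelines
#' often report decibels. These helpers are never applied implicitly.
#'
#' @param x Backscatter values.
#' @return Converted values: `db_to_power()` returns `10^(x/10)`,
#'   `power_to_db()` returns `10*log10(x)`.
#' @export
db_to_power <- function(x) 10^(x / 10)

#' @rdname db_to_power
#' @export
power_to_db <- function(x) {
  if (any(x <= 0)) abort("power values must be strictly positive")
  10 * log10(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# drop the obs_table class and split attribute, returning a plain tibble
strip_obs <- function(obs) {
  df <- obs
  class(df) <- setdiff(class(df), "obs_table")
  attr(df, "n_calibration") <- NULL
  as_tibble(df)
}
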