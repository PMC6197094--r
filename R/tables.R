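#' Read a stage-duration table
#'
#' Reads per-temperature mean (+/- SD) developmental durations for the five
#' immature stages (and optionally the total immature period) from CSV.
#' The schema is `temperature_C, stage, mean_h, sd_h, n` with stages drawn
#' from `egg, instar1, instar2, instar3, pupa, total`; durations are hours,
#' temperatures degrees Celsius, `n` the number of replicates behind each
#' mean.
#'
#' Validation errors on missing columns, unknown stages and non-positive
#' durations. Two softer consistency checks emit warnings only, because they
#' can fail on legitimately rounded published data: (i) where a `total` row
#' is present its mean should equal the sum of the five stage means to
#' within 2 h; (ii) every stage's mean duration should decrease with
#' temperature.
#'
#' @param file path to a CSV file (or connection).
#' @return a `stage_durations` data frame.
#' @seealso [cm_stage_durations()] for the packaged *C. megacephala* fixture.
#' @export
read_stage_durations <- function(file) {
  df <- tryCatch(read.csv(file, stringsAsFactors = FALSE),
                 error = function(e) cd_stop(
                   paste0("cannot parse stage-duration CSV: ", conditionMessage(e)),
                   "chrysodev_schema_error"))
  need <- c("temperature_C", "stage", "mean_h", "sd_h", "n")
  miss <- setdiff(need, names(df))
  if (length(miss))
    cd_stop(paste0("stage-duration table is missing column(s): ",
                   paste(miss, collapse = ", ")), "chrysodev_schema_error")
  if (nrow(df) == 0L)
    cd_stop("stage-duration table has no rows", "chrysodev_schema_error")
  for (col in c("temperature_C", "mean_h", "sd_h", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(df[[col]]))
      cd_stop(paste0("non-numeric values in column '", col, "'"),
              "chrysodev_schema_error")
  }
  as_stage_durations(df)
}

#' Construct and validate a stage-duration table
#'
#' @param df a data frame with columns `temperature_C, stage, mean_h, sd_h, n`.
#' @return a validated `stage_durations` data frame.
#' @export
as_stage_durations <- function(df) {
  bad <- !df$stage %in% .cd_stages_all
  if (any(bad))
    cd_stop(paste0("unknown stage(s): ", paste(unique(df$stage[bad]), collapse = ", ")),
            "chrysodev_validation_error")
  if (any(df$mean_h <= 0)) {
    row <- which(df$mean_h <= 0)[1L]
    cd_stop(sprintf("non-positive mean duration in row %d (%.1f degC, %s)",
                    row, df$temperature_C[row], df$stage[row]),
            "chrysodev_validation_error")
  }
  if (any(df$sd_h < 0))
    cd_stop("negative SD", "chrysodev_validation_error")
  if (anyDuplicated(df[c("temperature_C", "stage")]))
    cd_stop("duplicate (temperature, stage) rows", "chrysodev_validation_error")

  # soft check: total row vs sum of the five stage means (printed tables are
  # rounded; the reference data itself disagrees by up to 1.6 h at one
  # temperature, so this warns rather than rejects)
  for (tp in unique(df$temperature_C)) {
    sub <- df[df$temperature_C == tp, ]
    if ("total" %in% sub$stage && all(.cd_stages %in% sub$stage)) {
      s <- sum(sub$mean_h[match(.cd_stages, sub$stage)])
      tot <- sub$mean_h[sub$stage == "total"]
      if (abs(s - tot) > 2)
        cd_warn(sprintf("at %.1f degC the stage means sum to %.1f h but total is %.1f h",
                        tp, s, tot), "chrysodev_consistency_warning")
    }
  }
  # soft check: durations should shorten as temperature rises
  for (st in intersect(unique(df$stage), .cd_stages_all)) {
    sub <- df[df$stage == st, ]
    sub <- sub[order(sub$temperature_C), ]
    if (nrow(sub) > 1L && any(diff(sub$mean_h) >= 0))
      cd_warn(paste0("mean duration of stage '", st,
                     "' is not strictly decreasing in temperature"),
              "chrysodev_monotonicity_warning")
  }
  structure(df[c("temperature_C", "stage", "mean_h", "sd_h", "n")],
            class = c("stage_durations", "data.frame"))
}

#' Write a stage-duration table to CSV
#'
#' @param x a `stage_durations` data frame.
#' @param file output path.
#' @export
write_stage_durations <- function(x, file) {
  write.csv(as.data.frame(x), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read an intra-puparial sub-stage timing table
#'
#' Reads min/max hours post-pupariation for the morphological sub-stages
#' A--K from CSV with schema `substage, temperature_C, min_h, max_h`.
#' Rows with `min_h > max_h` are rejected. Zero-width intervals
#' (`min_h == max_h`, e.g. a sub-stage never caught at the sampling
#' resolution) are kept as-is and listed in `attr(x, "flags")`.
#'
#' @param file path to a CSV file.
#' @return a `substage_table` data frame.
#' @seealso [cm_substages()], [substage_age_bracket()]
#' @export
read_substage_table <- function(file) {
  df <- tryCatch(read.csv(file, stringsAsFactors = FALSE),
                 error = function(e) cd_stop(
                   paste0("cannot parse sub-stage CSV: ", conditionMessage(e)),
                   "chrysodev_schema_error"))
  need <- c("substage", "temperature_C", "min_h", "max_h")
  miss <- setdiff(need, names(df))
  if (length(miss))
    cd_stop(paste0("sub-stage table is missing column(s): ",
                   paste(miss, collapse = ", ")), "chrysodev_schema_error")
  if (nrow(df) == 0L) cd_stop("sub-stage table has no rows", "chrysodev_schema_error")
  for (col in c("temperature_C", "min_h", "max_h"))
    df[[col]] <- as.numeric(df[[col]])
  bad <- !df$substage %in% .cd_substages
  if (any(bad))
    cd_stop(paste0("sub-stage letters must be A..K; got: ",
                   paste(unique(df$substage[bad]), collapse = ", ")),
            "chrysodev_validation_error")
  inv <- df$min_h > df$max_h
  if (any(inv)) {
    row <- which(inv)[1L]
    cd_stop(sprintf("inverted interval in row %d (sub-stage %s, %.1f degC): min %.0f > max %.0f",
                    row, df$substage[row], df$temperature_C[row],
                    df$min_h[row], df$max_h[row]),
            "chrysodev_validation_error")
  }
  # sub-stage onsets must not move earlier as the letters advance
  for (tp in unique(df$temperature_C)) {
    sub <- df[df$temperature_C == tp, ]
    sub <- sub[order(match(sub$substage, .cd_substages)), ]
    if (any(diff(sub$min_h) < 0))
      cd_stop(sprintf("sub-stage onsets are not non-decreasing at %.1f degC", tp),
              "chrysodev_validation_error")
  }
  zw <- df$min_h == df$max_h
  out <- structure(df[need], class = c("substage_table", "data.frame"))
  if (any(zw))
    attr(out, "flags") <- sprintf(
      "zero-width interval: sub-stage %s at %.0f degC (min = max = %.0f h)",
      df$substage[zw], df$temperature_C[zw], df$min_h[zw])
  out
}

#' Write a sub-stage timing table to CSV
#' @param x a `substage_table`.
#' @param file output path.
#' @export
write_substage_table <- function(x, file) {
  write.csv(as.data.frame(x), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Construct a temperature series
#'
#' A carrier for timestamped ambient temperatures used for degree-hour
#' accumulation and PMI inversion. `interpolation` declares how temperature
#' between samples is reconstructed: `"step"` (hold the last reading, the
#' natural semantics for hourly logger output; the default) or `"linear"`.
#'
#' @param time_h numeric, strictly increasing times in hours from the series
#'   origin.
#' @param temp_C temperatures in degrees Celsius, same length.
#' @param interpolation `"step"` or `"linear"`.
#' @return a `temperature_series` data frame.
#' @export
temperature_series <- function(time_h, temp_C, interpolation = c("step", "linear")) {
  interpolation <- match.arg(interpolation)
  time_h <- as.numeric(time_h); temp_C <- as.numeric(temp_C)
  if (length(time_h) != length(temp_C))
    cd_stop("time_h and temp_C must have equal length", "chrysodev_validation_error")
  if (length(time_h) < 2L)
    cd_stop("a temperature series needs at least 2 samples", "chrysodev_validation_error")
  if (anyNA(time_h) || anyNA(temp_C))
    cd_stop("missing values in temperature series", "chrysodev_validation_error")
  if (any(diff(time_h) <= 0))
    cd_stop("timestamps must be strictly increasing", "chrysodev_validation_error")
  structure(data.frame(time_h = time_h, temp_C = temp_C),
            interpolation = interpolation,
            class = c("temperature_series", "data.frame"))
}

#' Read a temperature series from CSV
#'
#' The file must contain a `temp_C` column and either a numeric `time_h`
#' column or an ISO 8601 `timestamp` column (converted to hours from the
#' first record).
#'
#' @inheritParams temperature_series
#' @param file path to a CSV file.
#' @return a `temperature_series`.
#' @export
read_temperature_series <- function(file, interpolation = c("step", "linear")) {
  interpolation <- match.arg(interpolation)
  df <- tryCatch(read.csv(file, stringsAsFactors = FALSE),
                 error = function(e) cd_stop(
                   paste0("cannot parse temperature CSV: ", conditionMessage(e)),
                   "chrysodev_schema_error"))
  if (!"temp_C" %in% names(df))
    cd_stop("temperature series is missing column 'temp_C'", "chrysodev_schema_error")
  if ("time_h" %in% names(df)) {
    tm <- as.numeric(df$time_h)
  } else if ("timestamp" %in% names(df)) {
    ts <- as.POSIXct(df$timestamp, tz = "UTC")
    if (anyNA(ts)) cd_stop("unparseable timestamps", "chrysodev_schema_error")
    tm <- as.numeric(difftime(ts, ts[1L], units = "hours"))
  } else {
    cd_stop("temperature series needs a 'time_h' or 'timestamp' column",
            "chrysodev_schema_error")
  }
  temperature_series(tm, df$temp_C, interpolation)
}

#' Write a temperature series to CSV
#' @param x a `temperature_series`.
#' @param file output path.
#' @export
write_temperature_series <- function(x, file) {
  write.csv(as.data.frame(x), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a growth-equation table
#'
#' Reads per-temperature cubic growth equations from CSV with schema
#' `temperature_C, direction, c3, c2, c1, c0, r2` (plus an optional free-text
#' `note` column). `direction` is `length_of_time` for body length L (mm) as
#' a cubic in time after hatching T (h), or `time_of_length` for the reverse
#' regression. Coefficients are stored at full printed precision.
#'
#' @param file path to a CSV file.
#' @return a `growth_equations` data frame.
#' @seealso [growth_curves()] to turn rows into evaluable [growth_curve()]
#'   objects, [cm_growth_equations()] for the packaged fixture.
#' @export
read_growth_equations <- function(file) {
  df <- tryCatch(read.csv(file, stringsAsFactors = FALSE),
                 error = function(e) cd_stop(
                   paste0("cannot parse growth-equation CSV: ", conditionMessage(e)),
                   "chrysodev_schema_error"))
  need <- c("temperature_C", "direction", "c3", "c2", "c1", "c0", "r2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    cd_stop(paste0("growth-equation table is missing column(s): ",
                   paste(miss, collapse = ", ")), "chrysodev_schema_error")
  if (!all(df$direction %in% c("length_of_time", "time_of_length")))
    cd_stop("direction must be 'length_of_time' or 'time_of_length'",
            "chrysodev_validation_error")
  for (col in c("temperature_C", "c3", "c2", "c1", "c0", "r2"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(df$r2 <= 0 | df$r2 > 1))
    cd_stop("r2 must lie in (0, 1]", "chrysodev_validation_error")
  if (anyDuplicated(df[c("temperature_C", "direction")]))
    cd_stop("one equation per (temperature, direction) is required",
            "chrysodev_validation_error")
  if (!"note" %in% names(df)) df$note <- ""
  structure(df[c(need, "note")], class = c("growth_equations", "data.frame"))
}

#' Write a growth-equation table to CSV
#' @param x a `growth_equations` data frame.
#' @param file output path.
#' @export
write_growth_equations <- function(x, file) {
  write.csv(as.data.frame(x), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

.cm_extdata <- function(name) {
  path <- system.file("extdata", name, package = "chrysodev")
  if (!nzchar(path))
    cd_stop(paste0("packaged fixture not found: ", name), "chrysodev_internal_error")
  path
}

#' Packaged *C. megacephala* reference tables (Suzhou population)
#'
#' Accessors for the published developmental reference data of the Yangtze
#' River Delta (Suzhou) *Chrysomya megacephala* population, reared at
#' constant 16, 19, 22, 25, 28, 31 and 34 degrees C:
#'
#' * `cm_stage_durations()` -- mean (+/- SD) duration in hours of egg,
#'   instars 1--3, pupa, and the total immature period at each temperature
#'   (4 replicates per temperature).
#' * `cm_substages()` -- min/max hours post-pupariation of the eleven
#'   intra-puparial morphological sub-stages A--K at 16, 22, 28 and 34
#'   degrees C.
#' * `cm_growth_equations()` -- fitted cubic larval growth equations in both
#'   directions at each rearing temperature.
#' * `cm_thermal_constants()` -- the published per-stage thermal summation
#'   constants K (ADH) and developmental threshold temperatures D0 (degC)
#'   with their SEs and reported R-squared. The total-period row carries a
#'   provenance note: its printed K is inconsistent with its printed D0
#'   under a regression through the mean-duration data, so analyses should
#'   prefer a fresh [fit_thermal_summation()] for the total period.
#'
#' @return the corresponding validated table.
#' @name cm_reference_data
NULL

#' @rdname cm_reference_data
#' @export
cm_stage_durations <- function() {
  read_stage_durations(.cm_extdata("chrysomya_megacephala_suzhou_stage_durations.csv"))
}

#' @rdname cm_reference_data
#' @export
cm_substages <- function() {
  x <- read_substage_table(.cm_extdata("chrysomya_megacephala_suzhou_substages.csv"))
  anchors <- c(16, 22, 28, 34)
  stopifnot(all(.cd_substages %in% x$substage), all(anchors %in% x$temperature_C))
  x
}

#' @rdname cm_reference_data
#' @export
cm_growth_equations <- function() {
  read_growth_equations(.cm_extdata("chrysomya_megacephala_suzhou_growth_equations.csv"))
}

#' @rdname cm_reference_data
#' @export
cm_thermal_constants <- function() {
  df <- read.csv(.cm_extdata("chrysomya_megacephala_suzhou_thermal_constants.csv"),
                 stringsAsFactors = FALSE)
  structure(df, class = c("thermal_constants", "data.frame"))
}

#' Packaged growth curves as evaluable objects
#'
#' Convenience wrapper: [cm_growth_equations()] converted with
#' [growth_curves()], with validity windows derived from
#' [cm_stage_durations()].
#'
#' @param direction optionally restrict to one regression direction.
#' @return a list of [growth_curve()] objects named by temperature.
#' @export
cm_growth_curves <- function(direction = NULL) {
  growth_curves(cm_growth_equations(), durations = cm_stage_durations(),
                direction = direction)
}
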