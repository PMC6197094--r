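#' Age bracket of a pupa from its intra-puparial sub-stage
#'
#' Looks up the min/max hours post-pupariation consistent with a
#' morphological sub-stage (A--K). At a tabulated anchor temperature the
#' bracket is an exact lookup; between anchors both bounds are linearly
#' interpolated against temperature. Temperatures outside the tabulated
#' range are refused (no extrapolation).
#'
#' @param table a `substage_table` (see [cm_substages()]).
#' @param substage a letter A..K.
#' @param temp_C temperature, degC, within the tabulated range.
#' @return named numeric vector `c(min_h, max_h)`, hours post-pupariation.
#' @examples
#' substage_age_bracket(cm_substages(), "H", 28)  # c(72, 80)
#' substage_age_bracket(cm_substages(), "H", 25)  # interpolated
#' @export
substage_age_bracket <- function(table, substage, temp_C) {
  stopifnot(inherits(table, "substage_table"))
  if (!substage %in% .cd_substages)
    cd_stop("substage must be one of A..K", "chrysodev_usage_error")
  rows <- table[table$substage == substage, ]
  rows <- rows[order(rows$temperature_C), ]
  if (nrow(rows) == 0L)
    cd_stop(paste0("no entries for sub-stage ", substage), "chrysodev_usage_error")
  rng <- range(rows$temperature_C)
  if (temp_C < rng[1L] || temp_C > rng[2L])
    cd_stop(sprintf("temperature %.1f degC is outside the tabulated range [%.0f, %.0f]",
                    temp_C, rng[1L], rng[2L]),
            "chrysodev_extrapolation_error")
  c(min_h = approx(rows$temperature_C, rows$min_h, xout = temp_C)$y,
    max_h = approx(rows$temperature_C, rows$max_h, xout = temp_C)$y)
}

# per-stage summaries of a duration table interpolated in temperature
.interp_duration <- function(durations, stage, temp_C, what = "mean_h") {
  sub <- durations[durations$stage == stage, ]
  sub <- sub[order(sub$temperature_C), ]
  if (nrow(sub) == 0L)
    cd_stop(paste0("duration table has no rows for stage ", stage),
            "chrysodev_missing_stage_error")
  rng <- range(sub$temperature_C)
  if (temp_C < rng[1L] || temp_C > rng[2L])
    cd_stop(sprintf("temperature %.1f degC outside the duration table range [%.0f, %.0f]",
                    temp_C, rng[1L], rng[2L]),
            "chrysodev_extrapolation_error")
  approx(sub$temperature_C, sub[[what]], xout = temp_C)$y
}

#' Age a larva from its body length
#'
#' Inverse prediction of larval age (hours after hatching) from body length
#' using the fitted T(L) cubics. The cubic is evaluated at the two fitted
#' temperatures bracketing `temp_C` and the two ages are linearly
#' interpolated in temperature. If a stage-duration table is supplied and an
#' instar is given, the predicted age is cross-checked against that
#' instar's time window (interpolated in temperature): a prediction outside
#' the window draws a warning, and one further away than a full window
#' width is rejected as inconsistent evidence.
#'
#' @param curves list of `time_of_length` [growth_curve()] objects covering
#'   the temperature range (e.g. `cm_growth_curves("time_of_length")`).
#' @param instar optional instar 1..3 of the specimen.
#' @param length_mm measured body length, mm.
#' @param temp_C temperature, degC, within the curves' fitted range.
#' @param durations optional `stage_durations` table for the instar
#'   cross-check.
#' @return a list with `age_h`, `window` (the instar's `c(onset, offset)`
#'   hours after hatching, or `NULL`), and `temperatures` used.
#' @export
larval_age_from_length <- function(curves, instar = NULL, length_mm, temp_C,
                                   durations = NULL) {
  dirs <- vapply(curves, function(cu) cu$direction, character(1L))
  curves <- curves[dirs == "time_of_length"]
  if (!length(curves))
    cd_stop("no time_of_length curves supplied", "chrysodev_usage_error")
  temps <- vapply(curves, function(cu) cu$temperature_C, numeric(1L))
  ord <- order(temps); curves <- curves[ord]; temps <- temps[ord]
  if (temp_C < min(temps) || temp_C > max(temps))
    cd_stop(sprintf("temperature %.1f degC outside the fitted range [%.0f, %.0f]",
                    temp_C, min(temps), max(temps)),
            "chrysodev_extrapolation_error")
  i_hi <- which(temps >= temp_C)[1L]
  i_lo <- if (temps[i_hi] == temp_C) i_hi else i_hi - 1L
  use <- unique(c(i_lo, i_hi))
  ages <- vapply(curves[use], function(cu) predict_age(cu, length_mm), numeric(1L))
  age <- if (length(use) == 1L) ages[[1L]] else
    approx(temps[use], ages, xout = temp_C)$y
  window <- NULL
  if (!is.null(instar)) {
    if (!instar %in% 1:3)
      cd_stop("instar must be 1, 2 or 3", "chrysodev_usage_error")
    if (!is.null(durations)) {
      means <- vapply(c("instar1", "instar2", "instar3"), function(st)
        .interp_duration(durations, st, temp_C), numeric(1L))
      onset <- if (instar == 1L) 0 else sum(means[seq_len(instar - 1L)])
      offset <- sum(means[seq_len(instar)])
      window <- c(onset = onset, offset = offset)
      w <- offset - onset
      if (age < onset - w || age > offset + w)
        cd_stop(sprintf(
          "length %.1f mm implies an age of %.1f h after hatching, far outside instar %d's window [%.1f, %.1f] h",
          length_mm, age, instar, onset, offset),
          "chrysodev_inconsistent_evidence_error")
      if (age < onset || age > offset)
        cd_warn(sprintf(
          "predicted age %.1f h falls outside instar %d's window [%.1f, %.1f] h",
          age, instar, onset, offset),
          "chrysodev_evidence_warning")
    }
  }
  list(age_h = age, window = window, temperatures = temps[use])
}

#' Invert a temperature record for the oviposition time
#'
#' Walks backward from `end_time_h` through the temperature series,
#' consuming each stage's thermal requirement `K` (degree hours above that
#' stage's own threshold `D0`) in reverse traversal order; the last stage of
#' the plan may be only partially completed (`partial_fraction` of its `K`).
#' The returned time is when accumulation of the first stage (egg) began,
#' i.e. the oviposition time. On a constant-temperature series this reduces
#' exactly to `end_time - sum(K_i / (T - D0_i))`.
#'
#' Each stage boundary is located with [stats::uniroot()] on the exact
#' closed-form degree-hour accumulator, so the inversion is accurate to
#' ~1e-6 h.
#'
#' @param series a [temperature_series()] extending back past oviposition.
#' @param plan a [stage_plan()] (ordered data frame `stage, D0, K`).
#' @param end_time_h series time at which the last stage of the plan reached
#'   `partial_fraction` of its requirement.
#' @param partial_fraction fraction in `[0, 1]` of the final stage's `K`
#'   already accumulated (1 = stage complete, 0 = stage just entered).
#' @return the start (oviposition) time on the series clock, with a
#'   `"trace"` attribute: data frame `stage, adh, hours` in backward order.
#' @examples
#' s <- temperature_series(c(0, 400), c(28, 28))
#' plan <- stage_plan(cm_thermal_constants(), "hatch")
#' 400 - invert_oviposition_time(s, plan, 400)  # 207.2 / (28 - 10.91)
#' @export
invert_oviposition_time <- function(series, plan, end_time_h, partial_fraction = 1) {
  stopifnot(inherits(series, "temperature_series"))
  if (!is.data.frame(plan) || !all(c("stage", "D0", "K") %in% names(plan)))
    cd_stop("plan must be a data frame with columns stage, D0, K",
            "chrysodev_usage_error")
  if (partial_fraction < 0 || partial_fraction > 1)
    cd_stop("partial_fraction must lie in [0, 1]", "chrysodev_range_error")
  t0 <- series$time_h[1L]
  tn <- series$time_h[nrow(series)]
  if (end_time_h < t0 || end_time_h > tn)
    cd_stop("end_time_h outside the series span", "chrysodev_range_error")
  req <- plan$K
  req[length(req)] <- req[length(req)] * partial_fraction
  cur <- end_time_h
  trace <- list()
  for (i in rev(seq_len(nrow(plan)))) {
    rem <- req[i]
    if (rem <= 0) {
      trace[[length(trace) + 1L]] <- data.frame(stage = plan$stage[i], adh = 0, hours = 0)
      next
    }
    if (cur <= t0)
      cd_stop(sprintf(
        "temperature record too short: stage '%s' still needs %.1f degree hours before its start",
        plan$stage[i], rem), "chrysodev_insufficient_record_error")
    avail <- accumulate_degree_hours(series, plan$D0[i], t0, cur)
    if (avail < rem - 1e-9)
      cd_stop(sprintf(
        "temperature record too short: stage '%s' needs %.1f degree hours but only %.1f are available (shortfall %.1f)",
        plan$stage[i], rem, avail, rem - avail),
        "chrysodev_insufficient_record_error")
    start <- uniroot(function(x) accumulate_degree_hours(series, plan$D0[i], x, cur) - rem,
                     lower = t0, upper = cur, tol = 1e-10,
                     f.lower = avail - rem, f.upper = -rem)$root
    trace[[length(trace) + 1L]] <- data.frame(stage = plan$stage[i], adh = rem,
                                              hours = cur - start)
    cur <- start
  }
  structure(cur, trace = do.call(rbind, trace))
}

#' Describe case evidence
#'
#' Bundles the insect evidence collected from remains into a validated
#' record for [estimate_pmi()]. Supported kinds: a larva with a measured
#' body length (`larva_with_length`; instar optional but recommended), a
#' larva staged only to instar (`larva_stage_only`), a pupa staged to an
#' intra-puparial sub-stage letter (`pupa_substage`), or an empty puparium
#' (`empty_puparium`, eclosion already occurred: lower bound only).
#'
#' @param kind evidence kind, see above.
#' @param instar instar 1..3 (required for `larva_stage_only`).
#' @param length_mm body length, mm (required for `larva_with_length`).
#' @param substage sub-stage letter A..K (required for `pupa_substage`).
#' @param collection_time_h time of collection on the temperature-series
#'   clock, hours.
#' @return a `case_evidence` object.
#' @export
case_evidence <- function(kind = c("larva_with_length", "larva_stage_only",
                                   "pupa_substage", "empty_puparium"),
                          instar = NULL, length_mm = NULL, substage = NULL,
                          collection_time_h) {
  kind <- match.arg(kind)
  if (kind == "larva_with_length") {
    if (is.null(length_mm) || length_mm <= 0)
      cd_stop("larva_with_length evidence needs a positive length_mm",
              "chrysodev_validation_error")
  }
  if (kind == "larva_stage_only" && is.null(instar))
    cd_stop("larva_stage_only evidence needs an instar", "chrysodev_validation_error")
  if (!is.null(instar) && !instar %in% 1:3)
    cd_stop("instar must be 1, 2 or 3", "chrysodev_validation_error")
  if (kind == "pupa_substage") {
    if (is.null(substage) || !substage %in% .cd_substages)
      cd_stop("pupa_substage evidence needs a sub-stage letter A..K",
              "chrysodev_validation_error")
  }
  structure(list(kind = kind, instar = instar, length_mm = length_mm,
                 substage = substage, collection_time_h = collection_time_h),
            class = "case_evidence")
}

# pre-pupal (oviposition -> pupariation) plan, optionally without the egg
.prepupal_plan <- function(fits, include_egg = TRUE) {
  p <- stage_plan(fits, "pupariation")
  if (!include_egg) p <- p[p$stage != "egg", ]
  p
}

# elapsed hours from a backward inversion ending at end_h
.elapsed_since_start <- function(series, plan, end_h, fraction = 1) {
  st <- invert_oviposition_time(series, plan, end_h, fraction)
  list(elapsed = end_h - as.numeric(st), start = as.numeric(st),
       trace = attr(st, "trace"))
}

#' Estimate the minimum postmortem interval from insect evidence
#'
#' Combines case evidence with an ambient temperature record and the
#' developmental reference models into a PMI_min interval. Dispatch by
#' evidence kind:
#'
#' * `larva_with_length`: the larva is aged from its length via the T(L)
#'   cubics at an effective temperature (time-weighted series mean over the
#'   candidate larval window, iterated once), then the egg stage is
#'   inverted through the series. The interval reflects the length
#'   measurement inverted at `length_mm +/- 2 * length_sd_mm` plus (when a
#'   duration table is supplied) +/- 2 SD of the egg duration.
#' * `larva_stage_only`: interval spanning the instar's onset to offset,
#'   both found by backward degree-hour inversion.
#' * `pupa_substage`: sub-stage bracket (hours post-pupariation, effective
#'   temperature = ADH-weighted series mean over the candidate pupal
#'   window, iterated once) plus the inverted pre-pupal span.
#' * `empty_puparium`: eclosion has occurred; lower bound only.
#'
#' The pre-pupal span uses per-stage thermal fits by default
#' (`prepupal = "stage_fits"`), so arbitrary temperature records work; with
#' `prepupal = "duration_table"` it is read off the rearing-duration table
#' instead (interpolated in temperature), which reproduces the published
#' durations exactly at the rearing temperatures but assumes a near-constant
#' record. How these reference models are composed into a case estimate is
#' this package's own procedure, reported in the estimate's `policies`.
#'
#' @param evidence a [case_evidence()].
#' @param series a [temperature_series()] covering collection back past the
#'   candidate oviposition time.
#' @param fits per-stage thermal constants: a named list of `thermal_fit`
#'   objects or a data frame like [cm_thermal_constants()].
#' @param curves list of T(L) growth curves (length evidence only).
#' @param substages a `substage_table` (pupal evidence only).
#' @param durations optional `stage_durations` table (used by the
#'   `duration_table` policy, the instar cross-check, and egg-SD interval
#'   widening).
#' @param anchor report the interval since `"oviposition"` (the PMI_min
#'   convention; default) or since `"hatching"`.
#' @param prepupal pre-pupal span policy, see above.
#' @param length_sd_mm assumed SD of a larval length measurement, mm.
#' @return a `pmi_estimate`: list with `pmi_min_h`, `pmi_max_h` (NA when
#'   unbounded), `point_h` (point estimate when one exists), `anchor`,
#'   `trace`, `warnings`, `policies`.
#' @examples
#' s <- temperature_series(c(0, 500), c(22, 22))
#' ev <- case_evidence("larva_with_length", instar = 3, length_mm = 10,
#'                     collection_time_h = 500)
#' est <- estimate_pmi(ev, s, cm_thermal_constants(),
#'                     curves = cm_growth_curves("time_of_length"),
#'                     durations = cm_stage_durations())
#' est$point_h  # ~92.7 h
#' @export
estimate_pmi <- function(evidence, series, fits, curves = NULL, substages = NULL,
                         durations = NULL,
                         anchor = c("oviposition", "hatching"),
                         prepupal = c("stage_fits", "duration_table"),
                         length_sd_mm = 0.3) {
  stopifnot(inherits(evidence, "case_evidence"), inherits(series, "temperature_series"))
  anchor <- match.arg(anchor)
  prepupal <- match.arg(prepupal)
  notes <- character(0)
  note <- function(msg) notes <<- c(notes, msg)
  t_coll <- evidence$collection_time_h
  if (t_coll < series$time_h[1L] || t_coll > series$time_h[nrow(series)])
    cd_stop("collection time outside the temperature record", "chrysodev_range_error")
  include_egg <- anchor == "oviposition"
  trace <- NULL
  point <- NA_real_

  collect <- function(expr) withCallingHandlers(expr,
    chrysodev_warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    })

  if (evidence$kind == "larva_with_length") {
    if (is.null(curves)) cd_stop("length evidence needs growth curves", "chrysodev_usage_error")
    temp0 <- .mean_temp(series, max(series$time_h[1L], t_coll - 1e-6), t_coll)
    a0 <- collect(larval_age_from_length(curves, evidence$instar,
                                         evidence$length_mm, temp0, durations))
    temp_eff <- .mean_temp(series, max(series$time_h[1L], t_coll - a0$age_h), t_coll)
    aC <- collect(larval_age_from_length(curves, evidence$instar,
                                         evidence$length_mm, temp_eff, durations))
    age_at <- function(len) {
      r <- tryCatch(collect(larval_age_from_length(curves, NULL, len, temp_eff)),
                    chrysodev_domain_error = function(e) NULL)
      if (is.null(r)) NA_real_ else r$age_h
    }
    aL <- age_at(evidence$length_mm - 2 * length_sd_mm)
    aH <- age_at(evidence$length_mm + 2 * length_sd_mm)
    lim <- .curve_length_limits(curves, temp_eff)
    if (is.na(aL)) { aL <- age_at(max(lim[1L], evidence$length_mm - 2 * length_sd_mm)); if (is.na(aL)) aL <- 0 }
    if (is.na(aH)) {
      aH <- age_at(min(lim[2L], evidence$length_mm + 2 * length_sd_mm))
      if (is.na(aH)) aH <- aC$age_h
      note("length near peak feeding: upper age bound clamped to the curve window")
    }
    sd_egg <- if (!is.null(durations))
      .interp_duration(durations, "egg", temp_eff, "sd_h") else 0
    if (include_egg) {
      plan_egg <- stage_plan(fits, "hatch")
      pmi_of <- function(age) {
        r <- .elapsed_since_start(series, plan_egg, t_coll - age, 1)
        age + r$elapsed
      }
      point <- pmi_of(aC$age_h)
      lo <- max(pmi_of(min(aL, aH)) - 2 * sd_egg, 0)
      hi <- pmi_of(max(aL, aH)) + 2 * sd_egg
      trace <- .elapsed_since_start(series, plan_egg, t_coll - aC$age_h, 1)$trace
      trace <- rbind(data.frame(stage = "larva(length)", adh = NA_real_,
                                hours = aC$age_h), trace)
    } else {
      point <- aC$age_h
      lo <- min(aL, aH); hi <- max(aL, aH)
      trace <- data.frame(stage = "larva(length)", adh = NA_real_, hours = aC$age_h)
    }
    est <- list(pmi_min_h = lo, pmi_max_h = hi)
  } else if (evidence$kind == "larva_stage_only") {
    upto <- c("hatch", "ecdysis1", "ecdysis2")[evidence$instar]
    off_ms <- c("ecdysis1", "ecdysis2", "pupariation")[evidence$instar]
    onset_plan <- stage_plan(fits, upto)
    offset_plan <- stage_plan(fits, off_ms)
    if (!include_egg) {
      onset_plan <- onset_plan[onset_plan$stage != "egg", ]
      offset_plan <- offset_plan[offset_plan$stage != "egg", ]
    }
    lo <- if (nrow(onset_plan)) .elapsed_since_start(series, onset_plan, t_coll, 1)$elapsed else 0
    hi_r <- .elapsed_since_start(series, offset_plan, t_coll, 1)
    est <- list(pmi_min_h = lo, pmi_max_h = hi_r$elapsed)
    trace <- hi_r$trace
  } else if (evidence$kind == "pupa_substage") {
    if (is.null(substages)) cd_stop("pupal evidence needs a sub-stage table", "chrysodev_usage_error")
    pupa_D0 <- stage_plan(fits, "eclosion")
    pupa_D0 <- pupa_D0$D0[pupa_D0$stage == "pupa"]
    temp0 <- .mean_temp(series, max(series$time_h[1L], t_coll - 1e-6), t_coll)
    br0 <- substage_age_bracket(substages, evidence$substage, temp0)
    mid <- mean(br0)
    win_lo <- max(series$time_h[1L], t_coll - max(mid, 1e-6))
    temp_eff <- if (win_lo < t_coll)
      .adh_weighted_mean_temp(series, pupa_D0, win_lo, t_coll) else temp0
    br <- substage_age_bracket(substages, evidence$substage, temp_eff)
    if (prepupal == "duration_table") {
      if (is.null(durations))
        cd_stop("duration_table policy needs a stage_durations table", "chrysodev_usage_error")
      stages <- if (include_egg) c("egg", "instar1", "instar2", "instar3") else
        c("instar1", "instar2", "instar3")
      span <- sum(vapply(stages, function(st)
        .interp_duration(durations, st, temp_eff), numeric(1L)))
      est <- list(pmi_min_h = br[["min_h"]] + span, pmi_max_h = br[["max_h"]] + span)
      trace <- data.frame(stage = c("pupa(substage)", "pre-pupal(table)"),
                          adh = NA_real_, hours = c(mean(br), span))
    } else {
      plan <- .prepupal_plan(fits, include_egg)
      span_for <- function(b) .elapsed_since_start(series, plan, t_coll - b, 1)
      lo_r <- span_for(br[["min_h"]])
      hi_r <- span_for(br[["max_h"]])
      est <- list(pmi_min_h = br[["min_h"]] + lo_r$elapsed,
                  pmi_max_h = br[["max_h"]] + hi_r$elapsed)
      trace <- rbind(data.frame(stage = "pupa(substage)", adh = NA_real_,
                                hours = mean(br)), hi_r$trace)
    }
    note(sprintf("sub-stage bracket at effective temperature %.1f degC (policy: linear interpolation in hours)",
                 temp_eff))
  } else { # empty_puparium
    if (prepupal == "duration_table") {
      if (is.null(durations))
        cd_stop("duration_table policy needs a stage_durations table", "chrysodev_usage_error")
      temp_eff <- .mean_temp(series, series$time_h[1L], t_coll)
      tot <- if ("total" %in% durations$stage && include_egg)
        .interp_duration(durations, "total", temp_eff)
      else {
        stages <- if (include_egg) .cd_stages else setdiff(.cd_stages, "egg")
        sum(vapply(stages, function(st) .interp_duration(durations, st, temp_eff),
                   numeric(1L)))
      }
      est <- list(pmi_min_h = tot, pmi_max_h = NA_real_)
      trace <- data.frame(stage = "immature(table)", adh = NA_real_, hours = tot)
    } else {
      plan <- stage_plan(fits, "eclosion")
      if (!include_egg) plan <- plan[plan$stage != "egg", ]
      r <- .elapsed_since_start(series, plan, t_coll, 1)
      est <- list(pmi_min_h = r$elapsed, pmi_max_h = NA_real_)
      trace <- r$trace
    }
    note("empty puparium: eclosion already occurred, no upper bound")
  }

  notes <- unique(notes)
  structure(list(pmi_min_h = max(est$pmi_min_h, 0),
                 pmi_max_h = est$pmi_max_h,
                 point_h = point,
                 anchor = anchor,
                 trace = trace,
                 warnings = notes,
                 policies = list(prepupal = prepupal, anchor = anchor,
                                 length_sd_mm = length_sd_mm,
                                 substage_interpolation = "linear_hours",
                                 composition = "chrysodev case-composition procedure")),
            class = "pmi_estimate")
}

# length window of the bracketing T(L) curves at a temperature
.curve_length_limits <- function(curves, temp_C) {
  dirs <- vapply(curves, function(cu) cu$direction, character(1L))
  curves <- curves[dirs == "time_of_length"]
  temps <- vapply(curves, function(cu) cu$temperature_C, numeric(1L))
  ord <- order(abs(temps - temp_C))
  use <- curves[ord[seq_len(min(2L, length(curves)))]]
  c(max(vapply(use, function(cu) cu$valid_min, numeric(1L))),
    min(vapply(use, function(cu) cu$valid_max, numeric(1L))))
}

#' @export
print.pmi_estimate <- function(x, ...) {
  cat(sprintf("PMI_min estimate (anchor: %s)\n", x$anchor))
  if (is.na(x$pmi_max_h))
    cat(sprintf("  at least %.1f h (%.1f d); no upper bound from this evidence\n",
                x$pmi_min_h, x$pmi_min_h / 24))
  else
    cat(sprintf("  interval: %.1f - %.1f h (%.1f - %.1f d)\n",
                x$pmi_min_h, x$pmi_max_h, x$pmi_min_h / 24, x$pmi_max_h / 24))
  if (!is.na(x$point_h))
    cat(sprintf("  point estimate: %.1f h\n", x$point_h))
  if (length(x$warnings))
    cat("  notes:", paste0("\n   - ", x$warnings), "\n", sep = "")
  invisible(x)
}
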