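#' Fit the Ikemoto--Takai thermal summation model for one stage
#'
#' Development under the thermal summation law satisfies
#' `D * (T - D0) = K`, where `D` is the stage duration (h) at constant
#' temperature `T` (degC), `D0` the developmental threshold temperature and
#' `K` the thermal summation constant (degree hours). The Ikemoto--Takai
#' linearization regresses `y = D * T` (the accumulated degree hours
#' including the sub-threshold part) on `x = D`, so that the slope estimates
#' `D0` and the intercept estimates `K`. Fitting is ordinary least squares
#' via [stats::lm()].
#'
#' When the table holds one row per temperature (the usual published form)
#' the fit is on means; if several rows share a (temperature, stage) pair --
#' replicate-level data -- every row enters as its own point.
#'
#' Both the plain and the adjusted coefficient of determination are
#' reported. Published tables in this field typically print the adjusted
#' value.
#'
#' @param durations a `stage_durations` table (see [read_stage_durations()]).
#' @param stage one of `"egg", "instar1", "instar2", "instar3", "pupa",
#'   "total"`.
#' @return a `thermal_fit` object: list with `stage`, `D0`, `K`, `se_D0`,
#'   `se_K`, `r2`, `adj_r2`, `n_points`, `estimator`.
#' @examples
#' fit <- fit_thermal_summation(cm_stage_durations(), "egg")
#' fit$D0  # ~10.9 degC
#' predict_duration(fit, 25)  # ~14.7 h
#' @export
fit_thermal_summation <- function(durations, stage) {
  if (!inherits(durations, "stage_durations"))
    durations <- as_stage_durations(durations)
  stage <- match.arg(stage, .cd_stages_all)
  rows <- durations[durations$stage == stage, ]
  if (length(unique(rows$temperature_C)) < 3L)
    cd_stop(sprintf("need >= 3 distinct temperatures to fit stage '%s' (got %d)",
                    stage, length(unique(rows$temperature_C))),
            "chrysodev_insufficient_data_error")
  D <- rows$mean_h
  Tc <- rows$temperature_C
  if (isTRUE(all.equal(stats::var(D), 0)) || stats::var(D) == 0)
    cd_stop("zero variance in durations: thermal summation fit is singular",
            "chrysodev_singular_fit_error")
  y <- D * Tc
  fit <- lm(y ~ D)
  # noiseless thermal-law data are a legitimate input (simulator truth runs);
  # silence summary.lm's perfect-fit nuisance warning
  sm <- suppressWarnings(summary(fit))
  out <- structure(list(
    stage = stage,
    D0 = unname(coef(fit)[2L]),
    K = unname(coef(fit)[1L]),
    se_D0 = sm$coefficients[2L, 2L],
    se_K = sm$coefficients[1L, 2L],
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    n_points = length(D),
    estimator = if (anyDuplicated(Tc)) "ols_replicates" else "ols_means"
  ), class = "thermal_fit")
  if (out$K <= 0)
    cd_warn("fitted thermal summation constant K is not positive",
            "chrysodev_fit_warning")
  if (out$D0 >= min(Tc))
    cd_warn("fitted threshold D0 is not below the smallest fitted temperature",
            "chrysodev_fit_warning")
  out
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf("Thermal summation fit (Ikemoto-Takai OLS, %s), stage '%s'\n",
              x$estimator, x$stage))
  cat(sprintf("  D0 = %.2f degC (SE %.2f)   K = %.1f ADH (SE %.1f)\n",
              x$D0, x$se_D0, x$K, x$se_K))
  cat(sprintf("  R2 = %.4f (adjusted %.4f), n = %d\n", x$r2, x$adj_r2, x$n_points))
  invisible(x)
}

#' Predict a stage duration at constant temperature
#'
#' Inverts the fitted thermal summation line: `D = K / (T - D0)`.
#'
#' @param fit a `thermal_fit`.
#' @param temp_C constant temperature(s), degC; must exceed the threshold
#'   `D0` (below it no development occurs and an error is raised).
#' @return predicted duration(s) in hours.
#' @export
predict_duration <- function(fit, temp_C) {
  stopifnot(inherits(fit, "thermal_fit"))
  if (any(temp_C <= fit$D0))
    cd_stop(sprintf("no development at or below the threshold D0 = %.2f degC", fit$D0),
            "chrysodev_no_development_error")
  fit$K / (temp_C - fit$D0)
}

#' @export
predict.thermal_fit <- function(object, temp_C, ...) predict_duration(object, temp_C)

# piecewise segment overlap bookkeeping shared by the ADH integrators:
# returns, for [start_h, end_h], each series segment's clipped bounds and
# the temperatures at those bounds under the series' interpolation mode
.segment_clip <- function(series, start_h, end_h) {
  t <- series$time_h; v <- series$temp_C
  n <- length(t)
  a <- pmax(t[-n], start_h)
  b <- pmin(t[-1L], end_h)
  w <- pmax(b - a, 0)
  keep <- w > 0
  interp <- attr(series, "interpolation")
  if (identical(interp, "linear")) {
    slope <- diff(v) / diff(t)
    va <- v[-n] + slope * (a - t[-n])
    vb <- v[-n] + slope * (b - t[-n])
  } else {
    va <- v[-n]; vb <- v[-n]
  }
  list(a = a[keep], b = b[keep], w = w[keep], va = va[keep], vb = vb[keep])
}

#' Accumulate degree hours over a temperature record
#'
#' Computes the thermal-time integral `ADH = integral of max(T(t) - D0, 0) dt`
#' over `[start_h, end_h]`, with `T(t)` reconstructed from the series
#' according to its interpolation mode (`"step"`: hold last reading;
#' `"linear"`: trapezoid between samples, with exact handling of segments
#' that cross the threshold). Accumulation is clipped at zero below `D0`
#' and has no upper temperature cutoff. The result is non-negative and
#' additive over adjacent intervals.
#'
#' @param series a [temperature_series()].
#' @param D0 developmental threshold temperature, degC.
#' @param start_h,end_h interval bounds in series time (hours); must lie
#'   within the series span.
#' @return accumulated degree hours (numeric scalar).
#' @examples
#' s <- temperature_series(c(0, 10), c(28, 28))
#' accumulate_degree_hours(s, 11.41, 0, 10)  # (28 - 11.41) * 10
#' @export
accumulate_degree_hours <- function(series, D0, start_h, end_h) {
  stopifnot(inherits(series, "temperature_series"))
  if (start_h >= end_h)
    cd_stop("start_h must be strictly before end_h", "chrysodev_range_error")
  t <- series$time_h
  if (start_h < t[1L] - 1e-9 || end_h > t[length(t)] + 1e-9)
    cd_stop(sprintf("interval [%.2f, %.2f] h lies outside the series span [%.2f, %.2f] h",
                    start_h, end_h, t[1L], t[length(t)]),
            "chrysodev_range_error")
  sc <- .segment_clip(series, start_h, end_h)
  ea <- sc$va - D0
  eb <- sc$vb - D0
  both_pos <- ea >= 0 & eb >= 0
  cross <- xor(ea > 0, eb > 0)
  contrib <- numeric(length(sc$w))
  contrib[both_pos] <- (ea[both_pos] + eb[both_pos]) / 2 * sc$w[both_pos]
  if (any(cross)) {
    hi <- pmax(ea, eb)[cross]
    lo <- pmin(ea, eb)[cross]
    # positive part of a linear segment crossing zero is a triangle
    contrib[cross] <- hi^2 / (hi - lo) / 2 * sc$w[cross]
  }
  sum(contrib)
}

# time-weighted mean temperature over [a, b]
.mean_temp <- function(series, a, b) {
  sc <- .segment_clip(series, a, b)
  sum((sc$va + sc$vb) / 2 * sc$w) / (b - a)
}

# ADH-weighted mean temperature over [a, b] with threshold D0: the mean
# temperature experienced while development was actually proceeding.
# Simpson's rule per segment is exact for the quadratic integrand T*(T-D0)
# on linear segments and trivially exact on step segments.
.adh_weighted_mean_temp <- function(series, D0, a, b) {
  denom <- accumulate_degree_hours(series, D0, a, b)
  if (denom <= 0) return(.mean_temp(series, a, b))
  sc <- .segment_clip(series, a, b)
  num <- 0
  for (i in seq_along(sc$w)) {
    va <- sc$va[i]; vb <- sc$vb[i]; w <- sc$w[i]
    if (va <= D0 && vb <= D0) next
    # clip the sub-threshold part of a crossing segment
    if ((va - D0) * (vb - D0) < 0) {
      frac <- (D0 - va) / (vb - va)
      if (va < D0) { va <- D0; w <- w * (1 - frac) } else { vb <- D0; w <- w * frac }
    }
    vm <- (va + vb) / 2
    num <- num + w / 6 * (va * (va - D0) + 4 * vm * (vm - D0) + vb * (vb - D0))
  }
  num / denom
}

#' Development progress as a fraction of the thermal requirement
#'
#' @param adh accumulated degree hours (non-negative).
#' @param fit a `thermal_fit` supplying the stage's `K`.
#' @return `adh / K`, uncapped: values above 1 mean the stage's thermal
#'   requirement has been exceeded.
#' @export
development_fraction <- function(adh, fit) {
  stopifnot(inherits(fit, "thermal_fit"))
  if (any(adh < 0)) cd_stop("adh must be non-negative", "chrysodev_range_error")
  adh / fit$K
}

#' Stage traversal plan up to a developmental milestone
#'
#' Assembles the ordered list of (stage, D0, K) that development traverses
#' from oviposition up to a milestone event. Each stage carries its own
#' fitted threshold and thermal constant, so multi-stage degree-hour
#' bookkeeping (see [invert_oviposition_time()]) uses stage-specific
#' thresholds rather than a single total-period pair.
#'
#' @param fits either a named list of `thermal_fit` objects (names = stages),
#'   or a data frame with columns `stage`, `D0`, `K` such as
#'   [cm_thermal_constants()].
#' @param milestone one of `"hatch"`, `"ecdysis1"`, `"ecdysis2"`,
#'   `"pupariation"`, `"eclosion"`.
#' @return a `stage_plan` data frame with columns `stage`, `D0`, `K`, in
#'   traversal order.
#' @examples
#' stage_plan(cm_thermal_constants(), "pupariation")
#' @export
stage_plan <- function(fits, milestone = c("hatch", "ecdysis1", "ecdysis2",
                                           "pupariation", "eclosion")) {
  milestone <- match.arg(milestone)
  upto <- switch(milestone,
    hatch = "egg", ecdysis1 = "instar1", ecdysis2 = "instar2",
    pupariation = "instar3", eclosion = "pupa")
  stages <- .cd_stages[seq_len(match(upto, .cd_stages))]
  if (is.data.frame(fits)) {
    miss <- setdiff(stages, fits$stage)
    if (length(miss))
      cd_stop(paste0("missing stage fit(s): ", paste(miss, collapse = ", ")),
              "chrysodev_missing_stage_error")
    idx <- match(stages, fits$stage)
    out <- data.frame(stage = stages, D0 = fits$D0[idx], K = fits$K[idx])
  } else {
    got <- vapply(fits, function(f) f$stage, character(1L))
    miss <- setdiff(stages, got)
    if (length(miss))
      cd_stop(paste0("missing stage fit(s): ", paste(miss, collapse = ", ")),
              "chrysodev_missing_stage_error")
    idx <- match(stages, got)
    out <- data.frame(stage = stages,
                      D0 = vapply(fits[idx], function(f) f$D0, numeric(1L)),
                      K = vapply(fits[idx], function(f) f$K, numeric(1L)))
  }
  structure(out, class = c("stage_plan", "data.frame"))
}
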