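# cubic evaluation with coefficients ordered (c3, c2, c1, c0)
.eval_cubic <- function(co, x) ((co[1L] * x + co[2L]) * x + co[3L]) * x + co[4L]

# real roots of the derivative 3*c3*x^2 + 2*c2*x + c1
.deriv_roots <- function(co) {
  a <- 3 * co[1L]; b <- 2 * co[2L]; cc <- co[3L]
  if (abs(a) < 1e-300) {
    if (abs(b) < 1e-300) return(numeric(0))
    return(-cc / b)
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(numeric(0))
  sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
}

#' Construct a cubic growth curve
#'
#' A `growth_curve` holds one per-temperature cubic relating larval body
#' length (mm) and time after hatching (h), in one regression direction:
#' `length_of_time` gives L(T) and `time_of_length` gives T(L) (the
#' inverse-prediction form used to age a larva from its length; it is only
#' meaningful up to peak feeding, after which post-feeding larvae shrink and
#' the relation is no longer invertible). `valid_min`/`valid_max` bound the
#' input domain: time in hours for L(T), length in mm for T(L).
#'
#' For `time_of_length` curves the cubic is checked for monotone
#' non-decrease over the validity window; violations attach a monotonicity
#' warning to the curve (inspect `attr(curve, "flags")`).
#'
#' @param temperature_C rearing temperature, degC.
#' @param direction `"length_of_time"` or `"time_of_length"`.
#' @param coefficients numeric length-4 vector `(c3, c2, c1, c0)`.
#' @param valid_min,valid_max input-domain bounds.
#' @param r2 coefficient of determination of the underlying fit (optional).
#' @return a `growth_curve` object.
#' @export
growth_curve <- function(temperature_C, direction = c("length_of_time", "time_of_length"),
                         coefficients, valid_min, valid_max, r2 = NA_real_) {
  direction <- match.arg(direction)
  if (length(coefficients) != 4L || anyNA(coefficients))
    cd_stop("coefficients must be numeric (c3, c2, c1, c0)", "chrysodev_validation_error")
  if (!is.finite(valid_min) || !is.finite(valid_max) || valid_min >= valid_max)
    cd_stop("valid_min must be below valid_max", "chrysodev_validation_error")
  out <- structure(list(temperature_C = temperature_C, direction = direction,
                        coefficients = as.numeric(coefficients),
                        valid_min = valid_min, valid_max = valid_max, r2 = r2),
                   class = "growth_curve")
  if (direction == "time_of_length") {
    grid <- seq(valid_min, valid_max, length.out = 201L)
    d <- 3 * coefficients[1L] * grid^2 + 2 * coefficients[2L] * grid + coefficients[3L]
    if (any(d < -1e-9)) {
      attr(out, "flags") <- "non-monotone T(L) over the validity window"
      cd_warn(sprintf("fitted T(L) cubic at %.1f degC is not monotone over [%.2f, %.2f] mm",
                      temperature_C, valid_min, valid_max),
              "chrysodev_monotonicity_warning")
    }
  }
  out
}

#' @export
print.growth_curve <- function(x, ...) {
  co <- x$coefficients
  var <- if (x$direction == "length_of_time") c("L", "T") else c("T", "L")
  cat(sprintf("Growth curve at %.1f degC: %s = %.3g %s^3 + %.3g %s^2 + %.3g %s + %.3g\n",
              x$temperature_C, var[1L], co[1L], var[2L], co[2L], var[2L], co[3L], var[2L], co[4L]))
  cat(sprintf("  valid for %s in [%.2f, %.2f]%s\n",
              var[2L], x$valid_min, x$valid_max,
              if (is.na(x$r2)) "" else sprintf(", R2 = %.3f", x$r2)))
  invisible(x)
}

#' Fit a cubic growth curve by least squares
#'
#' Fits a degree-3 polynomial to larval length measurements by ordinary
#' least squares ([stats::lm()]). For `direction = "time_of_length"` the
#' data are first truncated at peak feeding (the sampling time of maximum
#' mean length), because beyond it the length--age relation is not
#' invertible; time is then regressed on length. For
#' `direction = "length_of_time"` length is regressed on time over the full
#' record.
#'
#' @param measurements a data frame with columns `time_h` (hours after
#'   hatching) and `length_mm`.
#' @param direction regression direction, see [growth_curve()].
#' @return a [growth_curve()] with the validity window set from the data
#'   actually fitted.
#' @export
fit_growth_curve <- function(measurements, direction = c("length_of_time", "time_of_length")) {
  direction <- match.arg(direction)
  need <- c("time_h", "length_mm")
  if (!all(need %in% names(measurements)))
    cd_stop("measurements need columns time_h and length_mm", "chrysodev_schema_error")
  df <- measurements[stats::complete.cases(measurements[need]), need]
  if (direction == "time_of_length") {
    # truncate at peak feeding: keep records up to the sampling time whose
    # mean length is maximal
    ml <- aggregate(length_mm ~ time_h, df, mean)
    t_peak <- ml$time_h[which.max(ml$length_mm)]
    df <- df[df$time_h <= t_peak, ]
    x <- df$length_mm; y <- df$time_h
  } else {
    x <- df$time_h; y <- df$length_mm
  }
  if (nrow(df) < 8L)
    cd_stop(sprintf("need >= 8 measurements to fit a cubic (got %d)", nrow(df)),
            "chrysodev_insufficient_data_error")
  fit <- lm(y ~ x + I(x^2) + I(x^3))
  co <- rev(unname(coef(fit)))  # (c3, c2, c1, c0)
  growth_curve(temperature_C = if (!is.null(attr(measurements, "temperature_C")))
                 attr(measurements, "temperature_C") else NA_real_,
               direction = direction, coefficients = co,
               valid_min = min(x), valid_max = max(x),
               r2 = suppressWarnings(summary(fit))$r.squared)
}

#' Convert a growth-equation table to growth-curve objects
#'
#' Turns the rows of a [read_growth_equations()] table into evaluable
#' [growth_curve()] objects. Validity windows are not part of the published
#' equations, so they are reconstructed: when a stage-duration table is
#' supplied, an L(T) curve is valid from hatching (t = 0) to the end of the
#' larval feeding period at that temperature (sum of the three instar
#' means); otherwise up to the curve's interior maximum. A T(L) curve is
#' valid from the hatching length to the peak length, both evaluated on the
#' paired L(T) cubic at the same temperature when present (defaults 2--17 mm
#' otherwise).
#'
#' @param equations a `growth_equations` table.
#' @param durations optional `stage_durations` table used to bound the time
#'   windows.
#' @param direction optionally keep only one direction.
#' @return a list of `growth_curve` objects, named `"<temp>"` for a single
#'   direction or `"<temp>:<direction>"` when both are kept.
#' @export
growth_curves <- function(equations, durations = NULL, direction = NULL) {
  stopifnot(inherits(equations, "growth_equations") || is.data.frame(equations))
  eq <- as.data.frame(equations)
  keep <- eq
  if (!is.null(direction)) {
    direction <- match.arg(direction, c("length_of_time", "time_of_length"))
    keep <- eq[eq$direction == direction, ]
  }
  larval_span <- function(tp) {
    if (is.null(durations)) return(NA_real_)
    sub <- durations[durations$temperature_C == tp & durations$stage %in%
                       c("instar1", "instar2", "instar3"), ]
    if (nrow(sub) < 3L) return(NA_real_)
    sum(sub$mean_h)
  }
  out <- list()
  for (i in seq_len(nrow(keep))) {
    tp <- keep$temperature_C[i]
    co <- as.numeric(keep[i, c("c3", "c2", "c1", "c0")])
    if (keep$direction[i] == "length_of_time") {
      vmax <- larval_span(tp)
      if (is.na(vmax)) {
        dr <- .deriv_roots(co)
        dr <- dr[dr > 0 & 6 * co[1L] * dr + 2 * co[2L] < 0]
        vmax <- if (length(dr)) max(dr) else 400
      }
      crv <- growth_curve(tp, "length_of_time", co, 0, vmax, keep$r2[i])
    } else {
      pair <- eq[eq$temperature_C == tp & eq$direction == "length_of_time", ]
      if (nrow(pair) == 1L) {
        pco <- as.numeric(pair[1L, c("c3", "c2", "c1", "c0")])
        span <- larval_span(tp)
        pcrv <- growth_curve(tp, "length_of_time", pco, 0,
                             if (is.na(span)) 400 else span, pair$r2[1L])
        pk <- suppressWarnings(peak_feeding_time(pcrv))
        lmin <- .eval_cubic(pco, 0)
        lmax <- pk[["length_mm"]]
      } else {
        lmin <- 2; lmax <- 17
      }
      crv <- growth_curve(tp, "time_of_length", co, lmin, lmax, keep$r2[i])
    }
    nm <- if (is.null(direction)) paste0(tp, ":", keep$direction[i]) else as.character(tp)
    out[[nm]] <- crv
  }
  out
}

.check_direction <- function(curve, direction) {
  if (!inherits(curve, "growth_curve"))
    cd_stop("not a growth_curve object", "chrysodev_usage_error")
  if (curve$direction != direction)
    cd_stop(sprintf("curve has direction '%s'; this operation needs '%s'",
                    curve$direction, direction), "chrysodev_usage_error")
}

#' Predict larval body length from time after hatching
#'
#' Evaluates an L(T) cubic. Times outside the validity window are evaluated
#' anyway but raise an extrapolation warning.
#'
#' @param curve a `growth_curve` with direction `length_of_time`.
#' @param time_h hours after hatching (vectorized).
#' @return body length(s), mm.
#' @export
predict_length <- function(curve, time_h) {
  .check_direction(curve, "length_of_time")
  if (any(time_h < curve$valid_min | time_h > curve$valid_max))
    cd_warn(sprintf("time outside the fitted window [%.1f, %.1f] h: extrapolating",
                    curve$valid_min, curve$valid_max),
            "chrysodev_extrapolation_warning")
  .eval_cubic(curve$coefficients, time_h)
}

#' Predict larval age from body length (inverse prediction)
#'
#' Evaluates a T(L) cubic, the regression direction fitted for ageing
#' larvae. Lengths outside the fitted length window are a domain error
#' (below hatching length or above peak length the inverse relation is
#' undefined). Negative predicted ages are clamped to 0 with a warning.
#'
#' @param curve a `growth_curve` with direction `time_of_length`.
#' @param length_mm body length(s), mm.
#' @param tol_mm tolerance on the window check (default 1e-6).
#' @return age(s) in hours after hatching.
#' @export
predict_age <- function(curve, length_mm, tol_mm = 1e-6) {
  .check_direction(curve, "time_of_length")
  if (any(length_mm < curve$valid_min - tol_mm | length_mm > curve$valid_max + tol_mm))
    cd_stop(sprintf("length outside the fitted window [%.2f, %.2f] mm",
                    curve$valid_min, curve$valid_max),
            "chrysodev_domain_error")
  age <- .eval_cubic(curve$coefficients, length_mm)
  if (any(age < 0)) {
    cd_warn("negative predicted age clamped to 0 h", "chrysodev_clamp_warning")
    age <- pmax(age, 0)
  }
  age
}

#' Time and length at peak feeding
#'
#' Locates the maximum of an L(T) cubic over its validity window via the
#' closed-form roots of the derivative. Peak feeding -- the point of maximum
#' larval length, after which post-feeding larvae shrink -- bounds the
#' region where age can be inferred from length. If the cubic has no
#' interior maximum the better boundary is returned with a warning
#' (ties break to the earlier time).
#'
#' @param curve a `growth_curve` with direction `length_of_time`.
#' @return named numeric vector `c(time_h, length_mm)`.
#' @export
peak_feeding_time <- function(curve) {
  .check_direction(curve, "length_of_time")
  co <- curve$coefficients
  dr <- .deriv_roots(co)
  interior <- dr[dr > curve$valid_min & dr < curve$valid_max &
                   6 * co[1L] * dr + 2 * co[2L] < 0]
  if (length(interior)) {
    vals <- .eval_cubic(co, interior)
    best <- interior[order(-vals, interior)][1L]  # max value, earlier time on ties
  } else {
    ends <- c(curve$valid_min, curve$valid_max)
    vals <- .eval_cubic(co, ends)
    best <- ends[order(-vals, ends)][1L]
    cd_warn("no interior maximum in the validity window: returning the boundary maximum",
            "chrysodev_boundary_warning")
  }
  c(time_h = best, length_mm = .eval_cubic(co, best))
}

# solve L(t) = len on the rising pre-peak branch of a length_of_time curve;
# NA if the length is not reached on that branch
.solve_time_for_length <- function(curve, len) {
  co <- curve$coefficients
  pk <- suppressWarnings(peak_feeding_time(curve))
  lo <- curve$valid_min
  # start the bracket after any early local minimum (some fitted cubics dip
  # slightly just after hatching before rising)
  dr <- .deriv_roots(co)
  mins <- dr[dr > lo & dr < pk[["time_h"]] & 6 * co[1L] * dr + 2 * co[2L] > 0]
  if (length(mins)) lo <- max(mins)
  f_lo <- .eval_cubic(co, lo) - len
  f_hi <- pk[["length_mm"]] - len
  if (f_lo > 0 || f_hi < 0) return(NA_real_)
  if (f_lo == 0) return(lo)
  uniroot(function(x) .eval_cubic(co, x) - len, c(lo, pk[["time_h"]]),
          tol = 1e-9)$root
}

#' Build an isomegalen surface
#'
#' An isomegalen diagram charts, for each larval body length, the time after
#' hatching at which larvae reach that length across rearing temperatures
#' (valid from hatching to peak feeding). Given per-temperature growth
#' curves, each contour is solved at every fitted temperature --
#' by direct evaluation for `time_of_length` curves, or by root-finding on
#' the rising pre-peak branch for `length_of_time` curves -- and connected
#' by linear interpolation in temperature.
#'
#' @param curves a list of `growth_curve` objects (one per temperature; a
#'   single direction).
#' @param lengths body lengths (mm) to contour.
#' @return an `isomegalen_surface`: list with `lengths`, `points` (a data
#'   frame `length_mm, temperature_C, time_h`) and `notes` recording any
#'   contour truncations. `as.data.frame()` returns the points, the
#'   canonical CSV artifact.
#' @examples
#' surf <- build_isomegalen(cm_growth_curves("time_of_length"), lengths = c(3, 10))
#' head(as.data.frame(surf))
#' @export
build_isomegalen <- function(curves, lengths) {
  if (!length(curves)) cd_stop("no growth curves supplied", "chrysodev_usage_error")
  temps <- vapply(curves, function(cu) cu$temperature_C, numeric(1L))
  ord <- order(temps)
  curves <- curves[ord]; temps <- temps[ord]
  pts <- list(); notes <- character(0)
  for (len in lengths) {
    for (i in seq_along(curves)) {
      cu <- curves[[i]]
      tm <- if (cu$direction == "time_of_length") {
        if (len < cu$valid_min - 1e-6 || len > cu$valid_max + 1e-6) NA_real_
        else suppressWarnings(predict_age(cu, len))
      } else {
        .solve_time_for_length(cu, len)
      }
      if (is.na(tm)) {
        notes <- c(notes, sprintf("length %.1f mm is not reached at %.1f degC: contour truncated",
                                  len, temps[i]))
      } else {
        pts[[length(pts) + 1L]] <- data.frame(length_mm = len,
                                              temperature_C = temps[i],
                                              time_h = tm)
      }
    }
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    data.frame(length_mm = numeric(0), temperature_C = numeric(0), time_h = numeric(0))
  structure(list(lengths = lengths, temperatures = temps, points = points,
                 notes = notes),
            class = "isomegalen_surface")
}

#' @export
as.data.frame.isomegalen_surface <- function(x, ...) x$points

#' Interpolate an isomegalen contour at an arbitrary temperature
#'
#' Piecewise-linear interpolation in (temperature, time) along one contour.
#'
#' @param surface an `isomegalen_surface`.
#' @param length_mm one of the surface's contour lengths.
#' @param temp_C temperature(s) within the contour's temperature range.
#' @return interpolated time(s) after hatching, hours.
#' @export
interpolate_contour <- function(surface, length_mm, temp_C) {
  stopifnot(inherits(surface, "isomegalen_surface"))
  pts <- surface$points[surface$points$length_mm == length_mm, ]
  if (nrow(pts) == 0L)
    cd_stop("no contour at that length", "chrysodev_usage_error")
  if (nrow(pts) == 1L) {
    if (any(temp_C != pts$temperature_C))
      cd_stop("one-point contour: cannot interpolate away from its temperature",
              "chrysodev_range_error")
    return(rep(pts$time_h, length(temp_C)))
  }
  if (any(temp_C < min(pts$temperature_C) | temp_C > max(pts$temperature_C)))
    cd_stop("temperature outside the contour's range", "chrysodev_range_error")
  approx(pts$temperature_C, pts$time_h, xout = temp_C)$y
}

#' @export
plot.isomegalen_surface <- function(x, xlab = "Time after hatching (h)",
                                    ylab = "Temperature (°C)", ...) {
  pts <- x$points
  if (nrow(pts) == 0L) cd_stop("empty surface", "chrysodev_usage_error")
  plot(NA, xlim = range(pts$time_h), ylim = range(pts$temperature_C),
       xlab = xlab, ylab = ylab, ...)
  for (len in unique(pts$length_mm)) {
    sub <- pts[pts$length_mm == len, ]
    sub <- sub[order(sub$temperature_C), ]
    lines(sub$time_h, sub$temperature_C)
    text(sub$time_h[1L], sub$temperature_C[1L], labels = len, pos = 1, cex = 0.7)
  }
  invisible(x)
}

#' Build an isomorphen chart
#'
#' An isomorphen diagram charts the cumulative time from oviposition to each
#' developmental event (hatching, first and second ecdysis, pupariation,
#' eclosion) against rearing temperature. Event times are cumulative sums of
#' the stage mean durations; SDs are propagated by quadrature (stage
#' durations treated as independent). For eclosion the observed `total`
#' duration row (with its own SD) is preferred when the table carries one,
#' since it is a direct measurement rather than a sum of rounded means.
#'
#' @param durations a `stage_durations` table with all five stages at each
#'   temperature.
#' @return an `isomorphen_chart`: data frame `event, temperature_C, time_h,
#'   sd_h` with an ordered `event` factor.
#' @examples
#' chart <- build_isomorphen(cm_stage_durations())
#' subset(chart, event == "eclosion")
#' @export
build_isomorphen <- function(durations) {
  if (!inherits(durations, "stage_durations"))
    durations <- as_stage_durations(durations)
  temps <- sort(unique(durations$temperature_C))
  rows <- list()
  for (tp in temps) {
    sub <- durations[durations$temperature_C == tp, ]
    if (!all(.cd_stages %in% sub$stage))
      cd_stop(sprintf("missing stage(s) at %.1f degC: %s", tp,
                      paste(setdiff(.cd_stages, sub$stage), collapse = ", ")),
              "chrysodev_missing_stage_error")
    m <- sub$mean_h[match(.cd_stages, sub$stage)]
    s <- sub$sd_h[match(.cd_stages, sub$stage)]
    time_h <- cumsum(m)
    sd_h <- sqrt(cumsum(s^2))
    if ("total" %in% sub$stage) {
      time_h[length(time_h)] <- sub$mean_h[sub$stage == "total"]
      sd_h[length(sd_h)] <- sub$sd_h[sub$stage == "total"]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      event = .cd_events, temperature_C = tp, time_h = time_h, sd_h = sd_h)
  }
  out <- do.call(rbind, rows)
  out$event <- factor(out$event, levels = .cd_events, ordered = TRUE)
  structure(out, class = c("isomorphen_chart", "data.frame"))
}

#' @export
plot.isomorphen_chart <- function(x, xlab = "Time from oviposition (h)",
                                  ylab = "Temperature (°C)", ...) {
  plot(NA, xlim = range(x$time_h + x$sd_h, 0), ylim = range(x$temperature_C),
       xlab = xlab, ylab = ylab, ...)
  for (ev in levels(x$event)) {
    sub <- x[x$event == ev, ]
    sub <- sub[order(sub$temperature_C), ]
    lines(sub$time_h, sub$temperature_C, type = "o", pch = 16, cex = 0.6)
    text(max(sub$time_h), min(sub$temperature_C), labels = ev, pos = 4, cex = 0.7)
  }
  invisible(x)
}
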