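test_that("cubic fits agree with a normal-equations oracle", {
  set.seed(303)
  for (rep in 1:8) {
    tt <- sort(runif(20, 0, 100))
    LL <- 2 + 0.2 * tt - 1e-3 * tt^2 + rnorm(20, 0, 0.3)
    crv <- fit_growth_curve(data.frame(time_h = tt, length_mm = LL),
                            "length_of_time")
    oracle <- poly_oracle(tt, LL, 3L)  # (c0, c1, c2, c3)
    expect_equal(unname(rev(crv$coefficients)), unname(oracle), tolerance = 1e-8)
  }
})

test_that("noiseless samples of the published cubics recover the coefficients", {
  # 34 degC length-of-time cubic
  truth <- c(-7.4e-5, 0.006, 0.120, 2.093)
  tt <- seq(0, 96, by = 4)
  meas <- data.frame(time_h = tt,
                     length_mm = eval_cubic_oracle(truth[1], truth[2], truth[3], truth[4], tt))
  crv <- fit_growth_curve(meas, "length_of_time")
  expect_equal(crv$coefficients, truth, tolerance = 1e-6)
  expect_equal(crv$r2, 1, tolerance = 1e-9)

  # 16 degC time-of-length cubic (fit is time on length)
  truth2 <- c(0.125, -3.832, 52.398, -99.977)
  LL <- seq(3, 16, by = 0.5)
  meas2 <- data.frame(time_h = eval_cubic_oracle(truth2[1], truth2[2], truth2[3], truth2[4], LL),
                      length_mm = LL)
  crv2 <- fit_growth_curve(meas2, "time_of_length")
  expect_equal(crv2$coefficients, truth2, tolerance = 1e-6)
})

test_that("noisy simulated growth data are fitted well", {
  # 8 larvae every 4 h from the 28 degC cubic, sigma = 0.3 mm
  truth <- cm_growth_curves("length_of_time")[["28"]]
  set.seed(404)
  tt <- rep(seq(0, truth$valid_max, by = 4), each = 8)
  LL <- eval_cubic_oracle(truth$coefficients[1], truth$coefficients[2],
                          truth$coefficients[3], truth$coefficients[4], tt) +
    rnorm(length(tt), 0, 0.3)
  crv <- fit_growth_curve(data.frame(time_h = tt, length_mm = LL), "length_of_time")
  expect_gt(crv$r2, 0.95)
  # coefficient recovery within 3 SEs of the refit
  sm <- summary(lm(LL ~ tt + I(tt^2) + I(tt^3)))
  se <- rev(sm$coefficients[, 2])
  expect_true(all(abs(crv$coefficients - truth$coefficients) < 3 * se))
})

test_that("fit refuses sparse data and flags non-monotone inversions", {
  expect_error(fit_growth_curve(data.frame(time_h = 1:5, length_mm = 1:5),
                                "length_of_time"),
               class = "chrysodev_insufficient_data_error")
  expect_warning(
    growth_curve(20, "time_of_length", c(1, -3, 1, 5), 0, 3),
    class = "chrysodev_monotonicity_warning")
})

test_that("printed-curve evaluation matches hand computation", {
  cl <- cm_growth_curves("length_of_time")
  ct <- cm_growth_curves("time_of_length")
  expect_equal(predict_length(cl[["34"]], 10), 3.819, tolerance = 1e-9)
  expect_equal(predict_length(cl[["34"]], 0), 2.093)  # intercept
  expect_equal(suppressWarnings(predict_length(cl[["16"]], 100)),
               -1.1e-6 * 1e6 + 5.1e-4 * 1e4 - 0.010 * 100 + 2.836)
  expect_equal(predict_age(ct[["16"]], 3), 26.104, tolerance = 1e-9)
  expect_error(predict_length(ct[["16"]], 10), class = "chrysodev_usage_error")
  expect_error(predict_age(cl[["16"]], 3), class = "chrysodev_usage_error")
  expect_error(predict_age(ct[["16"]], 30), class = "chrysodev_domain_error")
})

test_that("peak feeding is located by the derivative root", {
  cl <- cm_growth_curves("length_of_time")
  pk22 <- peak_feeding_time(cl[["22"]])
  # fitted peak is a smoothed estimate near, but below, the observed 17.0 mm
  expect_gt(pk22[["length_mm"]], 15)
  expect_lt(pk22[["length_mm"]], 17)
  pk34 <- peak_feeding_time(cl[["34"]])
  expect_gt(pk34[["time_h"]], 48)
  expect_lt(pk34[["time_h"]], 96)
  # monotone-decreasing cubic: boundary maximum with a warning
  dec <- growth_curve(25, "length_of_time", c(-1, 0, 0, 0), 0, 5)
  expect_warning(pk <- peak_feeding_time(dec), class = "chrysodev_boundary_warning")
  expect_equal(pk[["time_h"]], 0)
})

test_that("self-consistent noiseless curve pairs round-trip within 2 h", {
  # the inverse of a cubic is not a cubic, so this holds where the inverse
  # is well conditioned: warm temperatures, lengths more than one noise SD
  # (0.3 mm) below peak
  for (tp in c("28", "34")) {
    truth <- cm_growth_curves("length_of_time")[[tp]]
    meas <- noiseless_growth_data(truth)
    fwd <- fit_growth_curve(meas, "length_of_time")
    inv <- fit_growth_curve(meas, "time_of_length")
    pk <- peak_feeding_time(fwd)
    tg <- seq(0, floor(pk[["time_h"]]), by = 1)
    L <- predict_length(fwd, tg)
    keep <- L >= inv$valid_min & L <= pk[["length_mm"]] - 0.3
    rt <- suppressWarnings(predict_age(inv, L[keep]))
    expect_lt(max(abs(rt - tg[keep])), 2)
  }
})

test_that("isomegalen contours solve each curve and drop unreachable lengths", {
  ct <- cm_growth_curves("time_of_length")
  surf <- build_isomegalen(ct, lengths = c(3, 10, 16))
  pts <- as.data.frame(surf)
  p316 <- pts[pts$length_mm == 3 & pts$temperature_C == 16, ]
  expect_equal(p316$time_h, 26.104, tolerance = 1e-6)
  # contour times fall as temperature rises
  c10 <- pts[pts$length_mm == 10, ]
  c10 <- c10[order(c10$temperature_C), ]
  expect_true(all(diff(c10$time_h) < 0))
  # 16 mm exceeds the fitted peak length at some temperatures
  expect_true(any(grepl("16.0 mm", surf$notes)))

  # root-solving route on length-of-time curves agrees with direct
  # evaluation of the paired inverse within the pairs' mutual misfit
  cl <- cm_growth_curves("length_of_time")
  surf2 <- build_isomegalen(cl["28"], lengths = 10)
  t_root <- as.data.frame(surf2)$time_h
  expect_equal(predict_length(cl[["28"]], t_root), 10, tolerance = 1e-6)

  one <- build_isomegalen(ct["22"], lengths = 10)
  expect_equal(nrow(as.data.frame(one)), 1L)
  expect_equal(interpolate_contour(surf, 10, 23.5),
               mean(c10$time_h[c10$temperature_C %in% c(22, 25)]))
})

test_that("isomorphen event times are cumulative stage sums with quadrature SDs", {
  chart <- build_isomorphen(cm_stage_durations())
  g <- function(ev, tp) chart[chart$event == ev & chart$temperature_C == tp, ]
  # eclosion reports the observed total duration (not the sum of rounded means)
  expect_equal(g("eclosion", 25)$time_h, 280.8)
  expect_equal(g("eclosion", 25)$sd_h, 15.1)
  expect_equal(g("hatching", 16)$time_h, 38.9)
  expect_equal(g("pupariation", 28)$time_h, 12.2 + 18.0 + 22.5 + 61.2)
  expect_equal(g("pupariation", 28)$sd_h, sqrt(0.9^2 + 2.3^2 + 4.2^2 + 4.0^2))
  # each event strictly later than the previous within a temperature,
  # and strictly earlier as temperature rises
  for (tp in unique(chart$temperature_C))
    expect_true(all(diff(chart$time_h[chart$temperature_C == tp]) > 0))
  for (ev in levels(chart$event)) {
    sub <- chart[chart$event == ev, ]
    expect_true(all(diff(sub$time_h[order(sub$temperature_C)]) < 0))
  }
  broken <- cm_stage_durations()
  broken <- broken[!(broken$temperature_C == 22 & broken$stage == "instar2"), ]
  expect_error(build_isomorphen(broken), class = "chrysodev_missing_stage_error")
})
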