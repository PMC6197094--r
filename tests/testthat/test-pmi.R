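test_that("sub-stage brackets look up anchors exactly and interpolate between", {
  ss <- cm_substages()
  expect_equal(substage_age_bracket(ss, "K", 16), c(min_h = 272, max_h = 344))
  expect_equal(substage_age_bracket(ss, "H", 28), c(min_h = 72, max_h = 80))
  # 25 degC is halfway between the 22 and 28 degC anchors
  expect_equal(substage_age_bracket(ss, "H", 25),
               c(min_h = (104 + 72) / 2, max_h = (128 + 80) / 2))
  expect_error(substage_age_bracket(ss, "H", 35.5),
               class = "chrysodev_extrapolation_error")
  expect_error(substage_age_bracket(ss, "Z", 28), class = "chrysodev_usage_error")
})

test_that("larval age from length interpolates curves and cross-checks the instar", {
  ct <- cm_growth_curves("time_of_length")
  durs <- cm_stage_durations()
  r <- larval_age_from_length(ct, instar = NULL, length_mm = 3, temp_C = 16)
  expect_equal(r$age_h, 26.104, tolerance = 1e-6)
  # between fitted temperatures: linear interpolation of the two ages
  r2 <- larval_age_from_length(ct, NULL, 10, 23.5)
  a22 <- predict_age(ct[["22"]], 10)
  a25 <- predict_age(ct[["25"]], 10)
  expect_equal(r2$age_h, (a22 + a25) / 2)
  # a 15 mm "first instar" is impossible
  expect_error(
    larval_age_from_length(ct, instar = 1, length_mm = 15, temp_C = 22,
                           durations = durs),
    class = "chrysodev_inconsistent_evidence_error")
  expect_error(larval_age_from_length(ct, NULL, 10, 10),
               class = "chrysodev_extrapolation_error")

  # on self-consistent refit curves a hatchling-sized larva ages to ~0 h
  truth <- cm_growth_curves("length_of_time")[["28"]]
  meas <- noiseless_growth_data(truth)
  inv <- fit_growth_curve(meas, "time_of_length")
  inv$temperature_C <- 28
  a0 <- suppressWarnings(predict_age(inv, inv$valid_min))
  expect_lt(a0, 2)
})

test_that("backward inversion equals the closed form on constant records", {
  tc <- cm_thermal_constants()
  s <- temperature_series(c(0, 400), c(28, 28))
  ovi <- invert_oviposition_time(s, stage_plan(tc, "hatch"), 400)
  expect_equal(400 - as.numeric(ovi), 207.2 / (28 - 10.91), tolerance = 1e-6)

  # full plan, several constant temperatures, against sum(K_i / (T - D0_i))
  plan <- stage_plan(tc, "eclosion")
  for (tp in c(18, 23.7, 30)) {
    span <- sum(plan$K / (tp - plan$D0))
    s2 <- temperature_series(c(0, span + 50), c(tp, tp))
    ovi2 <- invert_oviposition_time(s2, plan, span + 10)
    expect_equal((span + 10) - as.numeric(ovi2), span, tolerance = 1e-6)
  }

  # partial_fraction = 0 spans the complete stages only
  s3 <- temperature_series(c(0, 400), c(28, 28))
  p2 <- stage_plan(tc, "ecdysis1")
  ovi3 <- invert_oviposition_time(s3, p2, 300, partial_fraction = 0)
  expect_equal(300 - as.numeric(ovi3), 207.2 / (28 - 10.91), tolerance = 1e-6)
  tr <- attr(ovi3, "trace")
  expect_equal(tr$hours[tr$stage == "instar1"], 0)

  err <- tryCatch(invert_oviposition_time(temperature_series(c(0, 30), c(28, 28)),
                                          plan, 30),
                  error = identity)
  expect_s3_class(err, "chrysodev_insufficient_record_error")
  expect_match(conditionMessage(err), "shortfall")
})

test_that("forward-simulated milestones invert back to the oviposition time", {
  set.seed(505)
  tc <- cm_thermal_constants()
  plan <- stage_plan(tc, "eclosion")
  for (rep in 1:3) {
    s <- temperature_series(seq(0, 2500, by = 1),
                            25 + sample(-5:5, 2501, replace = TRUE))
    t_ovi <- runif(1, 5, 20)
    cur <- t_ovi
    for (i in seq_len(nrow(plan))) {
      f <- function(x) accumulate_degree_hours(s, plan$D0[i], cur, x) - plan$K[i]
      cur <- uniroot(f, c(cur + 1e-6, 2500), tol = 1e-10)$root
      rec <- invert_oviposition_time(s, plan[seq_len(i), ], cur)
      expect_lt(abs(as.numeric(rec) - t_ovi), 1)  # within one series step
    }
  }
})

test_that("warming the record never lengthens the estimated PMI", {
  tc <- cm_thermal_constants()
  ss <- cm_substages()
  set.seed(606)
  base <- 24 + sample(-4:4, 1201, replace = TRUE)
  for (delta in c(0, 1, 2)) {
    s <- temperature_series(0:1200, base + delta)
    ev <- case_evidence("pupa_substage", substage = "G", collection_time_h = 1100)
    est <- estimate_pmi(ev, s, tc, substages = ss)
    if (delta == 0) prev <- est$pmi_min_h
    expect_lte(est$pmi_min_h, prev + 1e-9)
    prev <- est$pmi_min_h
  }
})

test_that("worked case estimates reproduce the reference compositions", {
  tc <- cm_thermal_constants()
  durs <- cm_stage_durations()
  ss <- cm_substages()

  # larva, 10 mm at constant 22 degC: age 73.98 h (22 degC inverse cubic at
  # 10 mm) plus the inverted egg stage 207.2 / (22 - 10.91) = 18.68 h
  s22 <- temperature_series(c(0, 500), c(22, 22))
  ev <- case_evidence("larva_with_length", instar = 3, length_mm = 10,
                      collection_time_h = 500)
  est <- estimate_pmi(ev, s22, tc, curves = cm_growth_curves("time_of_length"),
                      durations = durs)
  age22 <- 0.046 * 1000 - 1.192 * 100 + 17.993 * 10 - 32.748
  expect_equal(est$point_h, age22 + 207.2 / (22 - 10.91), tolerance = 1e-3)
  expect_lte(est$pmi_min_h, est$point_h)
  expect_gte(est$pmi_max_h, est$point_h)
  # hatching anchor drops the egg stage
  esth <- estimate_pmi(ev, s22, tc, curves = cm_growth_curves("time_of_length"),
                       durations = durs, anchor = "hatching")
  expect_equal(esth$point_h, age22, tolerance = 1e-3)

  # pupa in sub-stage H at constant 28 degC, duration-table policy:
  # bracket [72, 80] h plus the 113.9 h pre-pupal span
  s28 <- temperature_series(c(0, 500), c(28, 28))
  evp <- case_evidence("pupa_substage", substage = "H", collection_time_h = 500)
  estp <- estimate_pmi(evp, s28, tc, substages = ss, durations = durs,
                       prepupal = "duration_table")
  expect_equal(estp$pmi_min_h, 72 + 113.9, tolerance = 1e-6)
  expect_equal(estp$pmi_max_h, 80 + 113.9, tolerance = 1e-6)
  # stage-fit policy agrees within the thermal model's prediction error (~6%)
  estp2 <- estimate_pmi(evp, s28, tc, substages = ss)
  expect_lt(abs(estp2$pmi_min_h - estp$pmi_min_h) / estp$pmi_min_h, 0.06)

  # empty puparium: eclosion passed, lower bound only
  eve <- case_evidence("empty_puparium", collection_time_h = 500)
  este <- estimate_pmi(eve, s28, tc, durations = durs, prepupal = "duration_table")
  expect_equal(este$pmi_min_h, 218.9)
  expect_true(is.na(este$pmi_max_h))

  # stage-only larva: instar onset/offset interval
  evs <- case_evidence("larva_stage_only", instar = 2, collection_time_h = 500)
  ests <- estimate_pmi(evs, s28, tc)
  on_h <- 207.2 / (28 - 10.91) + 272.0 / (28 - 13.35)
  off_h <- on_h + 332.8 / (28 - 12.68)
  expect_equal(ests$pmi_min_h, on_h, tolerance = 1e-6)
  expect_equal(ests$pmi_max_h, off_h, tolerance = 1e-6)
})

test_that("case evidence is validated by kind", {
  expect_error(case_evidence("larva_with_length", collection_time_h = 10),
               class = "chrysodev_validation_error")
  expect_error(case_evidence("larva_stage_only", collection_time_h = 10),
               class = "chrysodev_validation_error")
  expect_error(case_evidence("pupa_substage", substage = "X", collection_time_h = 10),
               class = "chrysodev_validation_error")
  ev <- case_evidence("larva_stage_only", instar = 2, collection_time_h = 10)
  expect_s3_class(ev, "case_evidence")
})

test_that("simulated cases fall inside their estimated PMI intervals", {
  # end-to-end: simulate a rearing study, refit growth + thermal models from
  # the simulated data, then estimate PMI for fresh simulated larvae
  cfg <- simulation_config(temperatures = c(22, 25, 28, 31),
                          n_individuals = 80, seed = 97)
  sim <- simulate_rearing_experiment(cfg)
  fits <- lapply(setNames(nm = c("egg", "instar1", "instar2", "instar3", "pupa")),
                 function(st) fit_thermal_summation(sim$durations, st))
  curves <- lapply(c(22, 25, 28, 31), function(tp) {
    sub <- sim$lengths[sim$lengths$temperature_C == tp, ]
    crv <- suppressWarnings(fit_growth_curve(sub, "time_of_length"))
    crv$temperature_C <- tp
    crv
  })

  # the record must extend back beyond the candidate oviposition time:
  # oviposition is placed at hour 500 of the record
  covered <- 0L; n_cases <- 0L
  for (tp in c(22, 25, 28, 31)) {
    co <- simulate_cohort(cfg, tp, replicate = 90L)
    s <- temperature_series(c(0, 3000), c(tp, tp))
    ln <- co$lengths
    idx <- which(ln$length_mm > 4 & ln$length_mm < 15)
    set.seed(1000 + tp)
    idx <- sample(idx, 25)
    for (i in idx) {
      truth_elapsed <- ln$sample_time_h[i]
      ev <- case_evidence("larva_with_length", length_mm = ln$length_mm[i],
                          collection_time_h = 500 + truth_elapsed)
      est <- tryCatch(
        estimate_pmi(ev, s, fits, curves = curves, durations = sim$durations),
        chrysodev_error = function(e) NULL)
      if (is.null(est)) next
      n_cases <- n_cases + 1L
      if (truth_elapsed >= est$pmi_min_h - 1e-9 &&
          truth_elapsed <= est$pmi_max_h + 1e-9)
        covered <- covered + 1L
    }
  }
  expect_gte(n_cases, 80L)
  expect_gte(covered / n_cases, 0.9)

  # stage-only intervals always cover when transitions are deterministic
  cfg0 <- simulation_config(temperatures = c(25, 28), n_individuals = 20,
                           sd_scale = 0, seed = 5)
  tc <- cm_thermal_constants()
  for (tp in c(25, 28)) {
    co <- simulate_cohort(cfg0, tp)
    s <- temperature_series(c(0, 3000), c(tp, tp))
    ind <- co$individuals[1L, ]
    for (instar in 1:3) {
      onset <- c(ind$hatching, ind$ecdysis1, ind$ecdysis2)[instar]
      offset <- c(ind$ecdysis1, ind$ecdysis2, ind$pupariation)[instar]
      mid <- (onset + offset) / 2
      ev <- case_evidence("larva_stage_only", instar = instar,
                          collection_time_h = 500 + mid)
      fits0 <- lapply(setNames(nm = c("egg", "instar1", "instar2", "instar3")),
                      function(st) suppressWarnings(
                        fit_thermal_summation(cfg0$stage_truth, st)))
      est <- estimate_pmi(ev, s, fits0)
      expect_lte(est$pmi_min_h, mid)
      expect_gte(est$pmi_max_h, mid)
    }
  }
})
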