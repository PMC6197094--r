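#' Configuration for synthetic rearing simulations
#'
#' Bundles the design and the generative truth of a simulated rearing
#' experiment. The defaults mirror the reference rearing study: seven
#' constant temperatures, four replicates, eight larvae sampled every 4 h,
#' stage durations with the published means and SDs, and lengths following
#' the published per-temperature cubics with 0.3 mm Gaussian measurement
#' noise.
#'
#' `stage_truth` takes either a `stage_durations` table (per-temperature
#' means and SDs; the default is the packaged table) or a data frame
#' `stage, D0, K` of thermal constants, in which case the mean duration at
#' temperature T is `K / (T - D0)` and the SD is `duration_cv` times the
#' mean.
#'
#' Published SDs of this kind are ambiguous: they may describe variation of
#' replicate means or of individuals. `sd_interpretation` exposes both
#' readings: `"replicate_means"` (default) draws a replicate-level shift
#' with the tabulated SD and reuses the same SD for individuals within a
#' replicate; `"individuals"` applies the SD to individuals only.
#'
#' @param temperatures rearing temperatures, degC.
#' @param n_replicates replicate cohorts per temperature.
#' @param n_individuals individuals per cohort.
#' @param larvae_per_sample larvae measured per sampling occasion.
#' @param sampling_interval_h hours between larval samplings.
#' @param stage_truth generative truth for stage durations, see Details.
#' @param length_truth list of `length_of_time` [growth_curve()] objects
#'   (default: the packaged cubics).
#' @param length_noise_sd_mm SD of length measurement noise, mm.
#' @param duration_cv coefficient of variation of stage durations when
#'   `stage_truth` is a (D0, K) table.
#' @param sd_scale multiplier on all duration SDs (0 = deterministic
#'   durations).
#' @param sd_interpretation `"replicate_means"` or `"individuals"`.
#' @param stage_correlation correlation of successive stage durations within
#'   an individual (default 0, durations independent).
#' @param seed mandatory integer seed; all simulator output is a pure
#'   function of (config, arguments).
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(temperatures = c(16, 19, 22, 25, 28, 31, 34),
                              n_replicates = 4L,
                              n_individuals = 200L,
                              larvae_per_sample = 8L,
                              sampling_interval_h = 4,
                              stage_truth = NULL,
                              length_truth = NULL,
                              length_noise_sd_mm = 0.3,
                              duration_cv = 0.04,
                              sd_scale = 1,
                              sd_interpretation = c("replicate_means", "individuals"),
                              stage_correlation = 0,
                              seed) {
  if (missing(seed))
    cd_stop("a seed is mandatory: simulators must not be silently nondeterministic",
            "chrysodev_config_error")
  sd_interpretation <- match.arg(sd_interpretation)
  if (n_replicates < 1L || n_individuals < 1L || larvae_per_sample < 1L ||
      sampling_interval_h <= 0)
    cd_stop("counts and intervals must be positive", "chrysodev_config_error")
  if (stage_correlation < 0 || stage_correlation > 1)
    cd_stop("stage_correlation must lie in [0, 1]", "chrysodev_config_error")
  if (is.null(stage_truth)) stage_truth <- cm_stage_durations()
  if (is.null(length_truth)) length_truth <- cm_growth_curves("length_of_time")
  structure(list(temperatures = temperatures, n_replicates = as.integer(n_replicates),
                 n_individuals = as.integer(n_individuals),
                 larvae_per_sample = as.integer(larvae_per_sample),
                 sampling_interval_h = sampling_interval_h,
                 stage_truth = stage_truth, length_truth = length_truth,
                 length_noise_sd_mm = length_noise_sd_mm,
                 duration_cv = duration_cv, sd_scale = sd_scale,
                 sd_interpretation = sd_interpretation,
                 stage_correlation = stage_correlation,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# per-stage (mean, sd) of durations at one temperature under the config's truth
.stage_moments <- function(config, temperature_C) {
  truth <- config$stage_truth
  if (inherits(truth, "stage_durations") ||
      (is.data.frame(truth) && "mean_h" %in% names(truth))) {
    m <- vapply(.cd_stages, function(st)
      .interp_duration(truth, st, temperature_C), numeric(1L))
    s <- vapply(.cd_stages, function(st)
      .interp_duration(truth, st, temperature_C, "sd_h"), numeric(1L))
  } else if (is.data.frame(truth) && all(c("stage", "D0", "K") %in% names(truth))) {
    idx <- match(.cd_stages, truth$stage)
    if (anyNA(idx))
      cd_stop("stage_truth must cover all five stages", "chrysodev_config_error")
    if (any(temperature_C <= truth$D0[idx]))
      cd_stop(sprintf("no development: %.1f degC is at or below a stage threshold",
                      temperature_C), "chrysodev_no_development_error")
    m <- truth$K[idx] / (temperature_C - truth$D0[idx])
    s <- config$duration_cv * m
  } else {
    cd_stop("unrecognized stage_truth", "chrysodev_config_error")
  }
  list(mean = setNames(m, .cd_stages), sd = setNames(s * config$sd_scale, .cd_stages))
}

# growth cubic at a temperature: exact match or coefficientwise linear
# interpolation between the two bracketing truth curves
.length_cubic_at <- function(curves, temperature_C) {
  temps <- vapply(curves, function(cu) cu$temperature_C, numeric(1L))
  ord <- order(temps); curves <- curves[ord]; temps <- temps[ord]
  if (temperature_C <= temps[1L]) return(curves[[1L]])
  if (temperature_C >= temps[length(temps)]) return(curves[[length(curves)]])
  i <- findInterval(temperature_C, temps)
  if (temps[i] == temperature_C) return(curves[[i]])
  w <- (temperature_C - temps[i]) / (temps[i + 1L] - temps[i])
  growth_curve(temperature_C, "length_of_time",
               (1 - w) * curves[[i]]$coefficients + w * curves[[i + 1L]]$coefficients,
               valid_min = 0,
               valid_max = (1 - w) * curves[[i]]$valid_max + w * curves[[i + 1L]]$valid_max)
}

#' Simulate one rearing cohort
#'
#' Draws per-individual stage durations from truncated normal distributions
#' (mean and SD per [simulation_config()]; a hard floor at 0.2 x mean
#' prevents nonphysical durations) and generates larval length samples:
#' every `sampling_interval_h` hours, up to `larvae_per_sample` larvae still
#' in the feeding phase are measured, each length being the temperature's
#' growth cubic evaluated at the individual's age plus Gaussian noise.
#'
#' Output is bit-reproducible: the RNG substream is derived from
#' `(config$seed, temperature, replicate)`.
#'
#' @param config a [simulation_config()].
#' @param temperature_C rearing temperature, degC.
#' @param replicate replicate index (changes the RNG substream).
#' @return a `synthetic_cohort`: list with `individuals` (stage durations
#'   and cumulative event times per individual, hours from oviposition),
#'   `lengths` (sampling records: `sample_time_h`, `id`, `age_h`,
#'   `length_mm`), `events` (cohort mean event times), `temperature_C`.
#' @export
simulate_cohort <- function(config, temperature_C, replicate = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  mom <- .stage_moments(config, temperature_C)
  n <- config$n_individuals
  sub_seed <- (config$seed + 7919L * as.integer(replicate) +
                 13L * as.integer(round(temperature_C * 10))) %% .Machine$integer.max
  with_seed(sub_seed, {
    rep_shift <- if (config$sd_interpretation == "replicate_means")
      rnorm(length(.cd_stages), 0, mom$sd) else rep(0, length(.cd_stages))
    names(rep_shift) <- .cd_stages
    z_shared <- rnorm(n)
    rho <- config$stage_correlation
    dur <- sapply(.cd_stages, function(st) {
      z <- rho * z_shared + sqrt(1 - rho^2) * rnorm(n)
      pmax(mom$mean[[st]] + rep_shift[[st]] + mom$sd[[st]] * z,
           0.2 * mom$mean[[st]])
    })
    dur <- matrix(dur, nrow = n, dimnames = list(NULL, .cd_stages))
    cum <- t(apply(dur, 1L, cumsum))
    colnames(cum) <- .cd_events
    individuals <- data.frame(id = seq_len(n), dur, total = rowSums(dur), cum,
                              check.names = FALSE)

    # length sampling: cubic at individual age + measurement noise
    curve <- .length_cubic_at(config$length_truth, temperature_C)
    dt <- config$sampling_interval_h
    first <- ceiling(min(cum[, "hatching"]) / dt) * dt
    last <- max(cum[, "pupariation"])
    samples <- list()
    if (first < last) {
      for (tm in seq(first, last, by = dt)) {
        feeding <- which(cum[, "hatching"] <= tm & cum[, "pupariation"] > tm)
        if (!length(feeding)) next
        take <- if (length(feeding) > config$larvae_per_sample)
          sort(sample(feeding, config$larvae_per_sample)) else feeding
        age <- tm - cum[take, "hatching"]
        mu <- .eval_cubic(curve$coefficients, pmin(age, curve$valid_max))
        samples[[length(samples) + 1L]] <- data.frame(
          sample_time_h = tm, id = take, age_h = age,
          length_mm = pmax(mu + rnorm(length(take), 0, config$length_noise_sd_mm), 0.1))
      }
    }
    lengths <- if (length(samples)) do.call(rbind, samples) else
      data.frame(sample_time_h = numeric(0), id = integer(0),
                 age_h = numeric(0), length_mm = numeric(0))
    rownames(lengths) <- NULL
    structure(list(individuals = individuals, lengths = lengths,
                   events = colMeans(cum), temperature_C = temperature_C,
                   replicate = replicate),
              class = "synthetic_cohort")
  })
}

#' Simulate a full rearing experiment
#'
#' Runs [simulate_cohort()] for every (temperature, replicate) cell of the
#' design and aggregates the result into the same tabular shapes the
#' reference data use, so the whole pipeline (thermal summation fit, growth
#' curves, PMI inversion) can be exercised end to end on data with known
#' truth.
#'
#' The stage-duration table reports, per (temperature, stage), the mean of
#' replicate means; its SD column follows `config$sd_interpretation`:
#' the SD of replicate means (default) or the pooled individual SD.
#'
#' @param config a [simulation_config()].
#' @return list with `durations` (a `stage_durations` table including
#'   `total` rows, `n` = number of replicates), `lengths` (all length
#'   records with a `temperature_C` column and `time_h` = hours after
#'   hatching), and `cohorts` (the underlying `synthetic_cohort` objects).
#' @examples
#' cfg <- simulation_config(temperatures = c(19, 25, 31), n_individuals = 40,
#'                          seed = 1)
#' sim <- simulate_rearing_experiment(cfg)
#' fit_thermal_summation(sim$durations, "egg")
#' @export
simulate_rearing_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rows <- list(); lens <- list(); cohorts <- list()
  for (tp in config$temperatures) {
    rep_means <- matrix(NA_real_, config$n_replicates, length(.cd_stages_all),
                        dimnames = list(NULL, .cd_stages_all))
    ind_sds <- matrix(NA_real_, config$n_replicates, length(.cd_stages_all),
                      dimnames = list(NULL, .cd_stages_all))
    for (r in seq_len(config$n_replicates)) {
      co <- simulate_cohort(config, tp, r)
      cohorts[[length(cohorts) + 1L]] <- co
      for (st in .cd_stages) {
        rep_means[r, st] <- mean(co$individuals[[st]])
        ind_sds[r, st] <- sd(co$individuals[[st]])
      }
      rep_means[r, "total"] <- mean(co$individuals$total)
      ind_sds[r, "total"] <- sd(co$individuals$total)
      ln <- co$lengths
      if (nrow(ln)) {
        ln$temperature_C <- tp
        ln$replicate <- r
        lens[[length(lens) + 1L]] <- ln
      }
    }
    for (st in .cd_stages_all) {
      sd_out <- if (config$sd_interpretation == "replicate_means")
        sd(rep_means[, st]) else sqrt(mean(ind_sds[, st]^2))
      if (config$n_replicates == 1L || config$sd_scale == 0 || is.na(sd_out))
        sd_out <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        temperature_C = tp, stage = st, mean_h = mean(rep_means[, st]),
        sd_h = sd_out, n = config$n_replicates)
    }
  }
  durations <- suppressWarnings(as_stage_durations(do.call(rbind, rows)))
  lengths <- if (length(lens)) do.call(rbind, lens) else
    data.frame(sample_time_h = numeric(0), id = integer(0), age_h = numeric(0),
               length_mm = numeric(0), temperature_C = numeric(0),
               replicate = integer(0))
  lengths$time_h <- lengths$age_h
  list(durations = durations, lengths = lengths, cohorts = cohorts)
}

#' Simulate an ambient temperature series
#'
#' Generates an hourly temperature record: `"constant"`, a diel sinusoid
#' `mean + amplitude * sin(2 * pi * t / 24 + phase)`, or a `"step"` profile
#' holding given levels for given spans. Optional Gaussian jitter emulates
#' sensor noise (seeded).
#'
#' @param pattern `"constant"`, `"sinusoidal_diel"` or `"step"`.
#' @param duration_h record length, hours (samples at 0, 1, ..., duration).
#' @param mean_C mean temperature (constant / sinusoid).
#' @param amplitude_C sinusoid amplitude, degC.
#' @param phase sinusoid phase, radians.
#' @param levels,durations_h step profile: level i is held for
#'   `durations_h[i]` hours.
#' @param jitter_sd_C SD of additive Gaussian noise (0 = none).
#' @param seed required when `jitter_sd_C > 0`.
#' @param interpolation passed to [temperature_series()].
#' @return a [temperature_series()].
#' @export
simulate_temperature_series <- function(pattern = c("constant", "sinusoidal_diel", "step"),
                                        duration_h = NULL, mean_C = NULL,
                                        amplitude_C = 0, phase = 0,
                                        levels = NULL, durations_h = NULL,
                                        jitter_sd_C = 0, seed = NULL,
                                        interpolation = "step") {
  pattern <- match.arg(pattern)
  if (pattern == "step") {
    if (is.null(levels) || is.null(durations_h) || length(levels) != length(durations_h))
      cd_stop("step pattern needs matching 'levels' and 'durations_h'",
              "chrysodev_config_error")
    duration_h <- sum(durations_h)
    tm <- 0:floor(duration_h)
    bounds <- cumsum(durations_h)
    temp <- levels[findInterval(tm, c(0, bounds), rightmost.closed = TRUE)]
  } else {
    if (is.null(duration_h) || is.null(mean_C))
      cd_stop(paste0(pattern, " pattern needs 'duration_h' and 'mean_C'"),
              "chrysodev_config_error")
    tm <- 0:floor(duration_h)
    temp <- if (pattern == "constant") rep(mean_C, length(tm))
    else mean_C + amplitude_C * sin(2 * pi * tm / 24 + phase)
  }
  if (pattern == "sinusoidal_diel" && amplitude_C >= mean_C)
    cd_warn("sinusoid amplitude reaches or crosses 0 degC", "chrysodev_config_warning")
  if (jitter_sd_C > 0) {
    if (is.null(seed))
      cd_stop("jittered series need a seed", "chrysodev_config_error")
    temp <- with_seed(seed, temp + rnorm(length(temp), 0, jitter_sd_C))
  }
  temperature_series(tm, temp, interpolation)
}
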