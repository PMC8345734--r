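# Synthetic fixtures: log-normal radon series with optional diurnal and
# seasonal modulation, parametric occupancy presets, and named end-to-end
# scenarios with their expected outcomes attached. Indoor radon
# concentrations are empirically log-normal, so the generator draws
# log-concentration as gaussian noise around ln(GM) with sd ln(GSD);
# sinusoidal terms on the log scale emulate the night-time and winter
# build-up seen in closed buildings. All defaults keep the amplitudes at 0
# so distributional tests see pure log-normality.

#' Specification of a synthetic radon series
#'
#' @param gm Geometric mean concentration, Bq m^-3, > 0.
#' @param gsd Geometric standard deviation, dimensionless, >= 1 (1 = no
#'   noise).
#' @param diurnal_amplitude,seasonal_amplitude Modulation amplitudes as a
#'   fraction of the log-mean `ln(gm)`, in `[0, 1)`; 0 disables the term.
#' @param sampling_interval_min Minutes between readings.
#' @param span_days Series length in days, > 0.
#' @param seed Integer seed; identical seeds give bit-identical series.
#' @return A `series_spec` list.
#' @export
series_spec <- function(gm = 100, gsd = 2, diurnal_amplitude = 0,
                        seasonal_amplitude = 0, sampling_interval_min = 60,
                        span_days = 90, seed = 1L) {
  if (!is.numeric(gm) || gm <= 0) stop("`gm` must be > 0", call. = FALSE)
  if (!is.numeric(gsd) || gsd < 1) stop("`gsd` must be >= 1", call. = FALSE)
  for (a in c(diurnal_amplitude, seasonal_amplitude))
    if (!is.numeric(a) || a < 0 || a >= 1)
      stop("amplitudes must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(span_days) || span_days <= 0)
    stop("`span_days` must be > 0", call. = FALSE)
  if (!is.numeric(sampling_interval_min) || sampling_interval_min <= 0)
    stop("`sampling_interval_min` must be > 0", call. = FALSE)
  structure(list(gm = gm, gsd = gsd,
                 diurnal_amplitude = diurnal_amplitude,
                 seasonal_amplitude = seasonal_amplitude,
                 sampling_interval_min = sampling_interval_min,
                 span_days = span_days, seed = as.integer(seed)),
            class = "series_spec")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic radon series
#'
#' Draws `ln(c_t) = ln(gm) + A sin(2 pi hour/24 + phi_d)
#' + B sin(2 pi day/365 + phi_s) + eps`, with `eps ~ Normal(0, ln(gsd))`,
#' `A = diurnal_amplitude * ln(gm)` and `B = seasonal_amplitude * ln(gm)`.
#' The default phases put the diurnal peak at about 03:00 and the seasonal
#' peak in mid-January (concentrations build up at night and in winter when
#' buildings are closed). All generated concentrations are strictly
#' positive; the generator is fully deterministic given the spec's seed.
#'
#' @param spec A [series_spec()].
#' @param start First reading instant.
#' @param compartment_id Label for the generated series.
#' @return A [radon_series()] of `span_days * 1440 / sampling_interval_min`
#'   readings.
#' @examples
#' s <- generate_series(series_spec(gm = 100, gsd = 2, seed = 7))
#' @export
generate_series <- function(spec, start = "2021-01-04T00:00:00",
                            compartment_id = "synthetic") {
  stopifnot(inherits(spec, "series_spec"))
  start <- as_instant(start)
  n <- round(spec$span_days * 1440 / spec$sampling_interval_min)
  ts <- start + (seq_len(n) - 1) * spec$sampling_interval_min * 60
  epoch <- as.numeric(ts)
  hour <- (epoch %% 86400) / 3600
  doy <- as.numeric(format(ts, "%j", tz = "UTC")) +
    hour / 24  # fractional day of year
  phi_d <- pi / 2 - 2 * pi * 3 / 24      # peak near 03:00
  phi_s <- pi / 2 - 2 * pi * 15 / 365    # peak near mid-January
  mu <- log(spec$gm)
  lc <- mu +
    spec$diurnal_amplitude * mu * sin(2 * pi * hour / 24 + phi_d) +
    spec$seasonal_amplitude * mu * sin(2 * pi * doy / 365 + phi_s)
  eps <- if (spec$gsd > 1)
    with_seed(spec$seed, stats::rnorm(n, 0, log(spec$gsd)))
  else rep(0, n)
  radon_series(ts, exp(lc + eps), compartment_id = compartment_id)
}

#' Occupancy schedule presets
#'
#' Parametric schedules matching the standard annual-occupancy conventions:
#' `"office"` is weekdays 09:00-17:00 (about 2000 h per year: 2080 h over
#' 260 weekdays); `"dwelling"` is every day 00:00-08:00 plus 13:00-24:00
#' (19 h per day, 6935 h per 365-day year, the ~7000 h living-area
#' convention); `"continuous"` is 24/7; `"custom"` passes `weekly` and
#' `exceptions` through to [occupancy_schedule()].
#'
#' @param kind Preset name.
#' @param weekly,exceptions For `kind = "custom"`.
#' @return An [occupancy_schedule()].
#' @export
generate_schedule <- function(kind = c("office", "dwelling", "continuous",
                                       "custom"),
                              weekly = NULL, exceptions = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    office = occupancy_schedule(
      data.frame(day = 1:5, start = 9, end = 17)),
    dwelling = occupancy_schedule(
      data.frame(day = rep(1:7, 2),
                 start = rep(c(0, 13), each = 7),
                 end = rep(c(8, 24), each = 7))),
    continuous = occupancy_schedule(
      data.frame(day = 1:7, start = 0, end = 24)),
    custom = occupancy_schedule(weekly = weekly, exceptions = exceptions))
}

#' Named end-to-end scenarios with expected outcomes
#'
#' Deterministic fixture bundles for testing the full pipeline. Each bundle
#' carries the series, the schedule, the config, the `asof` instant and an
#' `expected` skeleton (per-window risk levels or coverage conditions) that
#' [assess()] must reproduce:
#'
#' * `worked_example_yellow`: constant 300 Bq m^-3 with 8 h/day occupancy --
#'   annualizes to 3.154 mSv/y, level 2 (yellow) in every conditioned
#'   window.
#' * `baseline_green`: log-normal series around GM 20 Bq m^-3 under an
#'   office schedule -- well below the 1 mSv/y public limit, level 1.
#' * `mitigation_drop`: 600 Bq m^-3 for 60 days, then 30 Bq m^-3 after a
#'   mitigation action, continuous occupancy -- recent windows are green
#'   (level 1) while the long-term window still carries the pre-mitigation
#'   burden (level 3).
#' * `data_gap`: the worked example with a detector outage inside the last
#'   week -- short-term coverage drops below 1 and is reported as such.
#'
#' @param name Scenario name.
#' @return List with elements `series`, `schedule`, `config`, `asof`,
#'   `expected`.
#' @export
scenario <- function(name = c("worked_example_yellow", "baseline_green",
                              "mitigation_drop", "data_gap")) {
  name <- match.arg(name)
  start <- "2021-01-04T00:00:00"  # a Monday
  config <- dose_model_config()
  eight_h_daily <- occupancy_schedule(
    data.frame(day = 1:7, start = 9, end = 17))
  if (name == "worked_example_yellow") {
    spec <- series_spec(gm = 300, gsd = 1, sampling_interval_min = 30,
                        span_days = 91, seed = 1L)
    series <- generate_series(spec, start, compartment_id = name)
    list(series = series, schedule = eight_h_daily, config = config,
         asof = NULL,
         expected = list(iaed_mSv = iaed_from_dao(300, 8, config),
                         levels = c(VST = 2L, ST = 2L, LT = 2L)))
  } else if (name == "baseline_green") {
    spec <- series_spec(gm = 20, gsd = 2, sampling_interval_min = 30,
                        span_days = 94, seed = 20L)
    series <- generate_series(spec, start, compartment_id = name)
    list(series = series, schedule = generate_schedule("office"),
         config = config, asof = NULL,
         expected = list(levels = c(VST = 1L, ST = 1L, LT = 1L)))
  } else if (name == "mitigation_drop") {
    ts <- as_instant(start) + (0:(90 * 24 - 1)) * 3600
    conc <- c(rep(600, 60 * 24), rep(30, 30 * 24))
    series <- radon_series(ts, conc, compartment_id = name)
    list(series = series, schedule = generate_schedule("continuous"),
         config = config, asof = NULL,
         expected = list(levels = c(VST = 1L, ST = 1L, LT = 3L)))
  } else {
    spec <- series_spec(gm = 300, gsd = 1, sampling_interval_min = 30,
                        span_days = 91, seed = 1L)
    series <- generate_series(spec, start, compartment_id = name)
    # detector outage: 24 h of missing readings two days before the end
    end <- series$timestamp[nrow(series)] + 30 * 60
    gap <- series$timestamp >= end - 3 * 86400 & series$timestamp < end - 2 * 86400
    series$quality_flag[gap] <- "missing"
    list(series = series, schedule = eight_h_daily, config = config,
         asof = NULL,
         expected = list(levels = c(VST = 2L, ST = 2L, LT = 2L),
                         st_coverage_below_1 = TRUE))
  }
}
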