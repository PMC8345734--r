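# Windowed aggregation: the monitoring pipeline that turns a radon series
# plus an occupancy schedule into per-window mean concentrations (AMRC),
# effective doses (IED), annualized dose estimates (IAED) and risk levels.
#
# Four standard assessment windows look back from an `asof` instant:
#   RT  - real time, the last hour, NOT occupancy-conditioned (it drives
#         mitigation such as ventilation, which is useful whether or not
#         anyone is present); reported as a mean concentration only.
#   VST - very short term, the occupied part of the last 24 h.
#   ST  - short term, the occupied part of the last week.
#   LT  - long term, the occupied part of at least the last 90 days.

#' Assessment window specification
#'
#' @param name One of `"RT"`, `"VST"`, `"ST"`, `"LT"`.
#' @param lt_days Span of the long-term window in days; at least 90.
#' @return A `window_spec`: name, `span_hours`, and whether the mean is
#'   occupancy-conditioned (all but RT).
#' @export
window_spec <- function(name = c("RT", "VST", "ST", "LT"), lt_days = 90) {
  name <- match.arg(name)
  if (name == "LT" && lt_days < 90)
    stop("the long-term window must span at least 90 days", call. = FALSE)
  span_hours <- switch(name, RT = 1, VST = 24, ST = 7 * 24, LT = lt_days * 24)
  structure(list(name = name, span_hours = span_hours,
                 occupancy_conditioned = name != "RT"),
            class = "window_spec")
}

default_windows <- function(lt_days = 90) {
  lapply(c("RT", "VST", "ST", "LT"), window_spec, lt_days = lt_days)
}

# total overlap integral of piecewise-constant segments with mask intervals;
# returns c(observed_seconds, integral_conc_seconds)
mask_overlap <- function(segments, mask_start, mask_end) {
  observed <- 0; integral <- 0
  for (k in seq_along(mask_start)) {
    dur <- pmax(0, pmin(segments$end, mask_end[k]) -
                   pmax(segments$start, mask_start[k]))
    observed <- observed + sum(dur)
    integral <- integral + sum(dur * segments$concentration)
  }
  c(observed, integral)
}

#' Time-weighted mean radon concentration over a window
#'
#' Restricts the piecewise-constant series to the window `[asof - span,
#' asof)` -- intersected with the occupied time if the window is
#' occupancy-conditioned -- and returns the time-weighted arithmetic mean
#' concentration (AMRC) together with the fraction of that masked time the
#' detector actually covered.
#'
#' "No occupancy in the window" (the schedule contributes zero time) and
#' "no data" (the detector contributes zero time to a non-empty mask) are
#' distinct conditions, reported in `status`; both leave `amrc` as `NA`.
#'
#' @param series A [radon_series()].
#' @param window A [window_spec()].
#' @param schedule An [occupancy_schedule()]; ignored for unconditioned
#'   windows. `NULL` disables conditioning (all time counts).
#' @param asof Instant the window looks back from.
#' @return List: `amrc` (Bq m^-3), `coverage_fraction` in `[0, 1]`,
#'   `occupied_hours` (masked time in the window), `observed_hours`, and
#'   `status` (`"ok"`, `"no_occupancy"`, or `"no_data"`).
#' @export
window_amrc <- function(series, window, schedule = NULL, asof) {
  stopifnot(inherits(series, "radon_series"), inherits(window, "window_spec"))
  asof <- as_instant(asof)
  w0 <- asof - window$span_hours * 3600
  if (window$occupancy_conditioned && !is.null(schedule)) {
    stopifnot(inherits(schedule, "occupancy_schedule"))
    mask <- occupancy_mask(schedule, w0, asof)
    mask_start <- as.numeric(mask$start); mask_end <- as.numeric(mask$end)
  } else {
    mask_start <- as.numeric(w0); mask_end <- as.numeric(asof)
  }
  masked_h <- sum(mask_end - mask_start) / 3600
  if (masked_h <= 0)
    return(list(amrc = NA_real_, coverage_fraction = NA_real_,
                occupied_hours = 0, observed_hours = 0,
                status = "no_occupancy"))
  ov <- mask_overlap(series_segments(series), mask_start, mask_end)
  observed_h <- ov[1] / 3600
  if (observed_h <= 0)
    return(list(amrc = NA_real_, coverage_fraction = 0,
                occupied_hours = masked_h, observed_hours = 0,
                status = "no_data"))
  list(amrc = ov[2] / ov[1],
       coverage_fraction = min(1, observed_h / masked_h),
       occupied_hours = masked_h, observed_hours = observed_h,
       status = "ok")
}

#' Sample summary statistics over a window
#'
#' Complements the time-weighted mean with the sample-based summaries in
#' both conventional reporting scales: arithmetic mean and standard
#' deviation on the raw scale, and geometric mean / geometric standard
#' deviation (`exp` of mean and sd of log concentration), the natural
#' summaries for log-normally distributed radon data. Computed over the
#' non-missing readings whose timestamps fall in the (masked) window.
#'
#' @inheritParams window_amrc
#' @return List with `n`, `am`, `sd`, `gm`, `gsd`. `sd`/`gsd` are `NA` for
#'   fewer than 2 readings; `gm`/`gsd` are `NA` when any concentration is 0.
#' @export
summary_stats <- function(series, window, schedule = NULL, asof) {
  stopifnot(inherits(series, "radon_series"), inherits(window, "window_spec"))
  asof <- as_instant(asof)
  w0 <- asof - window$span_hours * 3600
  ts <- as.numeric(series$timestamp)
  live <- series$quality_flag != "missing"
  if (window$occupancy_conditioned && !is.null(schedule)) {
    stopifnot(inherits(schedule, "occupancy_schedule"))
    mask <- occupancy_mask(schedule, w0, asof)
    inside <- rep(FALSE, length(ts))
    for (k in seq_len(nrow(mask)))
      inside <- inside | (ts >= as.numeric(mask$start[k]) &
                          ts < as.numeric(mask$end[k]))
  } else {
    inside <- ts >= as.numeric(w0) & ts < as.numeric(asof)
  }
  x <- series$concentration[inside & live]
  n <- length(x)
  if (n == 0L)
    return(list(n = 0L, am = NA_real_, sd = NA_real_,
                gm = NA_real_, gsd = NA_real_))
  am <- mean(x)
  s <- if (n >= 2L) stats::sd(x) else NA_real_
  if (any(x == 0)) {
    gm <- NA_real_; gsd <- NA_real_
  } else {
    gm <- exp(mean(log(x)))
    gsd <- if (n >= 2L) exp(stats::sd(log(x))) else NA_real_
  }
  list(n = n, am = am, sd = s, gm = gm, gsd = gsd)
}

#' Effective dose received over a window
#'
#' Dose accumulated during the occupied hours of a window at the window's
#' mean concentration, in mSv.
#'
#' @param amrc Mean radon concentration over the window, Bq m^-3.
#' @param occupied_hours Occupied time in the window, hours, >= 0.
#' @param config A [dose_model_config()].
#' @return Dose in mSv.
#' @export
window_ied <- function(amrc, occupied_hours, config = dose_model_config()) {
  if (any(!is.finite(occupied_hours)) || any(occupied_hours < 0))
    stop("`occupied_hours` must be finite and >= 0", call. = FALSE)
  1e3 * effective_dose(amrc * occupied_hours, config)
}

#' Annualize a window's conditions into an annual dose estimate
#'
#' Extrapolates the window's mean concentration and daily average occupation
#' to a full year: if both were maintained for a year, this is the annual
#' effective dose that would result. Delegates to [iaed_from_dao()].
#'
#' @param amrc Mean radon concentration, Bq m^-3.
#' @param dao Daily average occupation, hours per day in `[0, 24]` (for a
#'   window: occupied hours divided by days spanned).
#' @param config A [dose_model_config()].
#' @return Annual dose estimate in mSv per year.
#' @export
annualize <- function(amrc, dao, config = dose_model_config()) {
  iaed_from_dao(amrc, dao, config)
}

#' Full multi-window radon risk assessment
#'
#' Runs the monitoring pipeline for each assessment window ending at `asof`:
#' occupancy-conditioned mean concentration, occupied hours and daily
#' average occupation, window dose, annualized dose estimate, and risk
#' level. The real-time window reports the unconditioned last-hour mean only
#' (no risk level): it exists to drive mitigation, not classification.
#'
#' Windows whose data coverage of occupied time falls below
#' `config$min_coverage` are flagged `low_confidence` but still reported;
#' windows with no data or no occupancy carry an explanatory `status` and
#' `NA` results rather than failing.
#'
#' @param series A [radon_series()].
#' @param schedule An [occupancy_schedule()].
#' @param config A [dose_model_config()].
#' @param asof Instant the windows look back from; defaults to the end of
#'   the observed series.
#' @param lt_days Long-term window span in days (>= 90).
#' @return An `irrei_assessment`: a data frame with one row per window and
#'   columns `window`, `span_hours`, `amrc`, `coverage_fraction`,
#'   `occupied_hours`, `dao`, `ied_mSv`, `iaed_mSv`, `level`, `color`,
#'   `status`, `low_confidence`. The configuration and `asof` are attached
#'   as attributes.
#' @examples
#' sc <- scenario("worked_example_yellow")
#' assess(sc$series, sc$schedule)
#' @export
assess <- function(series, schedule, config = dose_model_config(),
                   asof = NULL, lt_days = 90) {
  stopifnot(inherits(series, "radon_series"),
            inherits(schedule, "occupancy_schedule"),
            inherits(config, "dose_model_config"))
  if (is.null(asof)) {
    seg <- series_segments(series)
    asof <- as.POSIXct(max(seg$end), tz = "UTC", origin = "1970-01-01")
  } else {
    asof <- as_instant(asof)
  }
  rows <- lapply(default_windows(lt_days), function(w) {
    res <- window_amrc(series, w, schedule, asof)
    row <- data.frame(
      window = w$name, span_hours = w$span_hours,
      amrc = res$amrc, coverage_fraction = res$coverage_fraction,
      occupied_hours = NA_real_, dao = NA_real_,
      ied_mSv = NA_real_, iaed_mSv = NA_real_,
      level = NA_integer_, color = NA_character_,
      status = res$status, low_confidence = FALSE)
    if (w$occupancy_conditioned) {
      row$occupied_hours <- res$occupied_hours
      if (res$status == "ok") {
        row$dao <- res$occupied_hours / (w$span_hours / 24)
        row$ied_mSv <- window_ied(res$amrc, res$occupied_hours, config)
        row$iaed_mSv <- annualize(res$amrc, row$dao, config)
        lev <- classify_irrei(row$iaed_mSv, config)
        row$level <- level(lev)
        row$color <- risk_color(lev)
        row$low_confidence <- res$coverage_fraction < config$min_coverage
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$window
  structure(out, class = c("irrei_assessment", "data.frame"),
            config = config, asof = asof)
}

#' @export
print.irrei_assessment <- function(x, ...) {
  cat(sprintf("<irrei_assessment> as of %s\n",
              format_instant(attr(x, "asof"))))
  for (i in seq_len(nrow(x))) {
    if (x$window[i] == "RT") {
      cat(sprintf("  RT  : mean %s Bq/m^3 (last hour, all time)%s\n",
                  if (is.na(x$amrc[i])) "NA" else signif2(x$amrc[i]),
                  if (x$status[i] != "ok") paste0(" [", x$status[i], "]") else ""))
    } else if (x$status[i] != "ok") {
      cat(sprintf("  %-3s : [%s]\n", x$window[i], x$status[i]))
    } else {
      cat(sprintf(
        "  %-3s : AMRC %s Bq/m^3, DAO %.1f h, IED %s mSv, annual %s mSv/y -> IRREI %d (%s)%s\n",
        x$window[i], signif2(x$amrc[i]), x$dao[i], signif2(x$ied_mSv[i]),
        signif2(x$iaed_mSv[i]), x$level[i], x$color[i],
        if (x$low_confidence[i]) " [low confidence]" else ""))
    }
  }
  invisible(x)
}

# doses are echoed at 2 significant figures in human-facing output;
# internal computation stays full precision
signif2 <- function(x) format(signif(x, 2), trim = TRUE, scientific = FALSE)
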