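# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's interval arithmetic: they discretize time on a 1-minute
# grid and evaluate schedule membership and the left-hold series value
# pointwise.

constant_series <- function(value, span_days, interval_min = 60,
                            start = "2021-01-04T00:00:00") {
  n <- span_days * 1440 / interval_min
  radon_series(as_instant(start) + (seq_len(n) - 1) * interval_min * 60,
               rep(value, n))
}

daily_schedule <- function(start_h, end_h) {
  occupancy_schedule(data.frame(day = 1:7, start = start_h, end = end_h))
}

# pointwise schedule membership from the weekly definition (no exceptions)
oracle_occupied <- function(epoch, weekly) {
  date <- as.Date(as.POSIXct(epoch, tz = "UTC", origin = "1970-01-01"),
                  tz = "UTC")
  wd <- as.integer(format(date, "%u"))
  hod <- (epoch %% 86400) / 3600
  occ <- rep(FALSE, length(epoch))
  for (i in seq_len(nrow(weekly)))
    occ <- occ | (wd == weekly$day[i] & hod >= weekly$start[i] &
                  hod < weekly$end[i])
  occ
}

# left-hold value of the series at given epochs; NA outside observed time
oracle_value <- function(epoch, series) {
  ts <- as.numeric(series$timestamp)
  n <- length(ts)
  tail_gap <- if (n >= 2) ts[n] - ts[n - 1] else 0
  idx <- findInterval(epoch, ts)
  val <- rep(NA_real_, length(epoch))
  inside <- idx >= 1 & epoch < ts[n] + tail_gap
  ok <- inside & series$quality_flag[pmax(idx, 1)] != "missing"
  val[ok] <- series$concentration[idx[ok]]
  val
}

# brute-force masked time-weighted mean on 1-minute midpoints
oracle_amrc <- function(series, schedule, w0, w1, conditioned = TRUE) {
  w0 <- as.numeric(as_instant(w0)); w1 <- as.numeric(as_instant(w1))
  mid <- seq(w0 + 30, w1 - 30, by = 60)
  occ <- if (conditioned) oracle_occupied(mid, schedule$weekly)
         else rep(TRUE, length(mid))
  val <- oracle_value(mid, series)
  use <- occ & !is.na(val)
  if (!any(use)) return(NA_real_)
  mean(val[use])
}
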