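# Windowed aggregation: masked time-weighted means, summary statistics,
# window doses and the full multi-window assessment.

test_that("window specs encode the standard spans", {
  expect_equal(window_spec("RT")$span_hours, 1)
  expect_false(window_spec("RT")$occupancy_conditioned)
  expect_equal(window_spec("VST")$span_hours, 24)
  expect_equal(window_spec("ST")$span_hours, 168)
  expect_equal(window_spec("LT")$span_hours, 90 * 24)
  expect_equal(window_spec("LT", lt_days = 120)$span_hours, 120 * 24)
  expect_error(window_spec("LT", lt_days = 30), "90")
})

test_that("mean of a constant series is that constant under any mask", {
  s <- constant_series(300, span_days = 10)
  for (sched in list(daily_schedule(9, 17), generate_schedule("office"),
                     generate_schedule("dwelling"))) {
    r <- window_amrc(s, window_spec("ST"), sched, asof = "2021-01-14")
    expect_equal(r$amrc, 300)
    expect_equal(r$coverage_fraction, 1)
  }
})

test_that("two half-windows at 500 and 1000 average to 750 unmasked", {
  t0 <- as_instant("2021-01-04T00:00:00")
  s <- radon_series(t0 + 3600 * (0:23), rep(c(500, 1000), each = 12))
  r <- window_amrc(s, window_spec("VST"), asof = t0 + 24 * 3600)
  expect_equal(r$amrc, 750)
})

test_that("hourly readings 100..400 with two occupied hours average to 250", {
  t0 <- as_instant("2021-01-04T00:00:00")  # a Monday
  s <- radon_series(t0 + 3600 * (0:3), c(100, 200, 300, 400))
  sched <- occupancy_schedule(data.frame(day = "Mon", start = 1, end = 3))
  r <- window_amrc(s, window_spec("VST"), sched, asof = t0 + 4 * 3600)
  expect_equal(r$amrc, 250)
  expect_equal(r$occupied_hours, 2)
})

test_that("masked means match the 1-minute brute-force oracle within 0.5%", {
  scheds <- list(office = generate_schedule("office"),
                 dwelling = generate_schedule("dwelling"),
                 narrow = daily_schedule(22, 23.5))
  specs <- list(series_spec(gm = 150, gsd = 2, sampling_interval_min = 45,
                            span_days = 10, seed = 101,
                            diurnal_amplitude = 0.3),
                series_spec(gm = 60, gsd = 3, sampling_interval_min = 137,
                            span_days = 10, seed = 102,
                            seasonal_amplitude = 0.2))
  asof <- "2021-01-13T06:30:00"
  for (spec in specs) {
    s <- generate_series(spec)
    for (nm in names(scheds)) {
      for (w in c("VST", "ST")) {
        win <- window_spec(w)
        got <- window_amrc(s, win, scheds[[nm]], asof = asof)
        want <- oracle_amrc(s, scheds[[nm]],
                            as_instant(asof) - win$span_hours * 3600, asof)
        expect_equal(got$amrc, want, tolerance = 5e-3,
                     label = sprintf("amrc(%s, %s)", nm, w))
      }
    }
  }
})

test_that("no-occupancy and no-data windows are distinguished", {
  s <- constant_series(300, span_days = 5)
  none <- occupancy_schedule()
  r <- window_amrc(s, window_spec("VST"), none, asof = "2021-01-08")
  expect_identical(r$status, "no_occupancy")
  expect_true(is.na(r$amrc))
  # occupied window entirely outside the observed series
  r2 <- window_amrc(s, window_spec("VST"), daily_schedule(9, 17),
                    asof = "2021-03-01")
  expect_identical(r2$status, "no_data")
  expect_equal(r2$coverage_fraction, 0)
})

test_that("summary statistics: AM/SD/GM/GSD over masked readings", {
  t0 <- as_instant("2021-01-04T00:00:00")
  s <- radon_series(t0 + 3600 * (0:23), rep(c(100, 400), 12))
  st <- summary_stats(s, window_spec("VST"), asof = t0 + 24 * 3600)
  expect_equal(st$am, 250)
  expect_equal(st$gm, 200)  # exp(mean(log(c(100, 400)))) = 200
  expect_true(st$gm <= st$am)
  # constant series: AM = GM, SD = 0, GSD = 1
  sc <- constant_series(50, 2)
  stc <- summary_stats(sc, window_spec("VST"), asof = "2021-01-06")
  expect_equal(stc$am, 50); expect_equal(stc$gm, 50)
  expect_equal(stc$sd, 0); expect_equal(stc$gsd, 1)
  # a zero concentration leaves AM/SD defined, GM/GSD undefined
  sz <- radon_series(t0 + 3600 * (0:2), c(0, 100, 200))
  stz <- summary_stats(sz, window_spec("VST"), asof = t0 + 3 * 3600)
  expect_equal(stz$am, 100)
  expect_true(is.na(stz$gm) && is.na(stz$gsd))
})

test_that("GM <= AM across random positive samples", {
  set.seed(9)
  for (i in 1:10) {
    s <- generate_series(series_spec(gm = runif(1, 20, 300),
                                     gsd = runif(1, 1.2, 3),
                                     span_days = 3, seed = i))
    st <- summary_stats(s, window_spec("VST"), asof = "2021-01-06")
    expect_true(st$gm <= st$am)
  }
})

test_that("window dose is linear in occupied hours and matches hand arithmetic", {
  cfg <- dose_model_config()
  expect_equal(window_ied(300, 40, cfg), 300 * 40 * 0.4 * 9e-9 * 1e3)
  expect_equal(window_ied(300, 0, cfg), 0)
  expect_equal(window_ied(300, 80, cfg), 2 * window_ied(300, 40, cfg))
  expect_error(window_ied(300, -1, cfg), ">= 0")
})

test_that("annualize delegates to the daily-occupation dose form", {
  cfg <- dose_model_config()
  expect_equal(annualize(300, 8, cfg), iaed_from_dao(300, 8, cfg))
  expect_equal(annualize(40, 7000 / 365, cfg), iaed_from_aao(40, 7000, cfg))
  expect_equal(annualize(55, 24, cfg), iaed_from_aao(55, 8760, cfg))
})

test_that("assess reports all four windows with consistent fields", {
  sc <- scenario("worked_example_yellow")
  a <- assess(sc$series, sc$schedule, sc$config)
  expect_identical(a$window, c("RT", "VST", "ST", "LT"))
  expect_true(is.na(a$level[a$window == "RT"]))
  cond <- a$window != "RT"
  expect_equal(a$amrc[cond], rep(300, 3))
  expect_equal(a$dao[cond], rep(8, 3))
  expect_equal(a$level[cond], rep(2L, 3))
  expect_equal(a$color[cond], rep("yellow", 3))
  # report values equal the library-level operations exactly
  expect_equal(a$iaed_mSv[cond], rep(iaed_from_dao(300, 8, sc$config), 3))
  expect_equal(a$ied_mSv[a$window == "ST"],
               window_ied(300, 7 * 8, sc$config))
})

test_that("assess is causal: readings after asof have no effect", {
  sc <- scenario("worked_example_yellow")
  asof <- "2021-03-01T00:00:00"
  a1 <- assess(sc$series, sc$schedule, sc$config, asof = asof)
  future <- sc$series$timestamp >= as_instant(asof)
  spiked <- radon_series(sc$series$timestamp,
                         ifelse(future, 1e5, sc$series$concentration))
  a2 <- assess(spiked, sc$schedule, sc$config, asof = asof)
  expect_equal(as.data.frame(a1), as.data.frame(a2), ignore_attr = TRUE)
})

test_that("assessments are translation invariant under a whole-week shift", {
  s <- generate_series(series_spec(gm = 120, gsd = 1.8, span_days = 95,
                                   seed = 33))
  sched <- generate_schedule("office")
  asof <- "2021-04-05T00:00:00"
  a1 <- assess(s, sched, asof = asof)
  shift <- 14 * 86400  # two weeks keeps weekday alignment
  s2 <- radon_series(s$timestamp + shift, s$concentration)
  a2 <- assess(s2, sched, asof = as_instant(asof) + shift)
  expect_equal(as.data.frame(a1), as.data.frame(a2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("empty schedule: conditioned windows flag no occupancy, RT still works", {
  s <- constant_series(120, span_days = 5)
  a <- assess(s, occupancy_schedule(), asof = "2021-01-08")
  expect_equal(a$amrc[a$window == "RT"], 120)
  expect_true(all(a$status[a$window != "RT"] == "no_occupancy"))
})

test_that("series entirely before the long-term window is reported, not an error", {
  s <- constant_series(120, span_days = 5, start = "2020-01-06T00:00:00")
  a <- assess(s, daily_schedule(9, 17), asof = "2021-06-01")
  expect_true(all(a$status[a$window != "RT"] == "no_data"))
})

test_that("coverage is 1 for a fully observed masked window, < 1 with a gap", {
  sc <- scenario("data_gap")
  a <- assess(sc$series, sc$schedule, sc$config)
  expect_lt(a$coverage_fraction[a$window == "ST"], 1)
  expect_equal(a$coverage_fraction[a$window == "VST"], 1)
  # a big enough gap trips the low-confidence flag
  s <- constant_series(300, span_days = 10, interval_min = 30)
  gap <- s$timestamp >= as_instant("2021-01-08") &
    s$timestamp < as_instant("2021-01-13")
  s$quality_flag[gap] <- "missing"
  a2 <- assess(s, daily_schedule(9, 17), asof = "2021-01-14")
  st <- a2[a2$window == "ST", ]
  expect_lt(st$coverage_fraction, 0.5)
  expect_true(st$low_confidence)
})
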