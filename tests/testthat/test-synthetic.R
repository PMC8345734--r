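# The synthetic generator: determinism, distributional fidelity, occupancy
# presets, and the end-to-end scenarios.

test_that("degenerate spec (gsd = 1, no modulation) gives a constant series", {
  s <- generate_series(series_spec(gm = 150, gsd = 1, span_days = 2, seed = 1))
  expect_equal(s$concentration, rep(150, 2 * 24))
  expect_equal(nrow(s), 2 * 24)
})

test_that("identical seeds give bit-identical series; the RNG stream is untouched", {
  spec <- series_spec(gm = 100, gsd = 2, span_days = 3, seed = 42)
  set.seed(777)
  before <- runif(1)
  set.seed(777)
  s1 <- generate_series(spec)
  after <- runif(1)
  s2 <- generate_series(spec)
  expect_identical(s1$concentration, s2$concentration)
  expect_identical(before, after)  # caller's stream undisturbed
  # a different seed gives a different series
  s3 <- generate_series(series_spec(gm = 100, gsd = 2, span_days = 3,
                                    seed = 43))
  expect_false(identical(s1$concentration, s3$concentration))
})

test_that("generated series recover their GM and GSD within 5% at n = 10000", {
  spec <- series_spec(gm = 100, gsd = 2, sampling_interval_min = 13,
                      span_days = 91, seed = 5)  # 10080 readings
  x <- generate_series(spec)$concentration
  expect_gte(length(x), 10000)
  expect_lt(abs(exp(mean(log(x))) / 100 - 1), 0.05)
  expect_lt(abs(exp(stats::sd(log(x))) / 2 - 1), 0.05)
  expect_true(all(x > 0))
})

test_that("log concentrations of unmodulated series pass a normality check", {
  # Shapiro-Wilk at alpha = 0.01 over 20 seeds; with a true null about
  # 0.2 rejections are expected, so allow at most 1
  rejections <- 0L
  for (seed in 1:20) {
    x <- generate_series(series_spec(gm = 100, gsd = 2,
                                     sampling_interval_min = 130,
                                     span_days = 91, seed = seed))$concentration
    p <- stats::shapiro.test(log(x)[seq_len(1000)])$p.value
    rejections <- rejections + (p < 0.01)
  }
  expect_lte(rejections, 1L)
})

test_that("modulation amplitudes shape the series as specified", {
  spec <- series_spec(gm = 100, gsd = 1, diurnal_amplitude = 0.2,
                      span_days = 2, sampling_interval_min = 60, seed = 1)
  s <- generate_series(spec)
  # noiseless diurnal series: log ranges +- 0.2 * log(gm) around log(gm)
  lc <- log(s$concentration)
  expect_equal(max(abs(lc - log(100))), 0.2 * log(100), tolerance = 0.01)
  # day-1 and day-2 patterns repeat
  expect_equal(s$concentration[1:24], s$concentration[25:48], tolerance = 1e-9)
})

test_that("zero-amplitude series are exchangeable across disjoint windows", {
  s <- generate_series(series_spec(gm = 100, gsd = 2,
                                   sampling_interval_min = 30,
                                   span_days = 20, seed = 8))
  sched <- generate_schedule("continuous")
  m1 <- window_amrc(s, window_spec("ST"), sched, asof = "2021-01-11")$amrc
  m2 <- window_amrc(s, window_spec("ST"), sched, asof = "2021-01-18")$amrc
  # Monte-Carlo error of a weekly mean at these settings is a few percent
  expect_lt(abs(m1 / m2 - 1), 0.15)
})

test_that("occupancy presets hit their annual-hour conventions", {
  # 2021 is a non-leap year with 261 weekdays
  y0 <- "2021-01-01"; y1 <- "2022-01-01"
  expect_equal(occupied_hours(generate_schedule("office"), y0, y1), 261 * 8)
  expect_equal(occupied_hours(generate_schedule("dwelling"), y0, y1), 19 * 365)
  expect_equal(daily_average_occupation(generate_schedule("continuous"),
                                        y0, y1), 24)
  # both presets sit at their ~2000 h and ~7000 h conventions
  expect_lt(abs(occupied_hours(generate_schedule("office"), y0, y1) - 2000),
            100)
  expect_lt(abs(occupied_hours(generate_schedule("dwelling"), y0, y1) - 7000),
            100)
  expect_error(generate_schedule("hotel"))
})

test_that("scenarios reproduce their attached expected outcomes end to end", {
  for (nm in c("worked_example_yellow", "baseline_green", "mitigation_drop",
               "data_gap")) {
    sc <- scenario(nm)
    a <- assess(sc$series, sc$schedule, sc$config, asof = sc$asof)
    got <- setNames(a$level[match(names(sc$expected$levels), a$window)],
                    names(sc$expected$levels))
    expect_identical(got, sc$expected$levels, label = nm)
    if (isTRUE(sc$expected$st_coverage_below_1))
      expect_lt(a$coverage_fraction[a$window == "ST"], 1)
  }
})

test_that("scenario bundles are deterministic", {
  a1 <- assess2 <- NULL
  sc1 <- scenario("baseline_green"); sc2 <- scenario("baseline_green")
  expect_identical(sc1$series$concentration, sc2$series$concentration)
})

test_that("invalid specs are rejected", {
  expect_error(series_spec(gm = -1), "> 0")
  expect_error(series_spec(gsd = 0.5), ">= 1")
  expect_error(series_spec(diurnal_amplitude = 1), "amplitudes")
  expect_error(series_spec(span_days = 0), "> 0")
})
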