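cfg <- ekman_config()

test_that("Coriolis frequency follows 2*Omega*sin(lat)", {
  expect_equal(coriolis_frequency(90), 1.45842e-4, tolerance = 1e-6)
  expect_warning(f0 <- coriolis_frequency(0), "equator")
  expect_identical(f0, 0)
  expect_equal(coriolis_frequency(53.375), 1.1705e-4, tolerance = 1e-4)
  expect_error(coriolis_frequency(91), "within")
})

test_that("wind stress is quadratic in the along-axis speed", {
  expect_identical(wind_stress(0, cfg), 0)
  expect_equal(wind_stress(10, cfg), 0.156)
  expect_equal(wind_stress(20, cfg), 4 * wind_stress(10, cfg))
  expect_error(wind_stress(-1, cfg), "non-negative")
})

test_that("transport rate is stress over f*rho", {
  expect_identical(transport_rate(0, cfg), 0)
  expect_equal(transport_rate(0.156, cfg), 1.333, tolerance = 1e-3)
  half_rho <- ekman_config(rho_water = cfg$rho_water / 2)
  expect_equal(transport_rate(0.156, half_rho), 2 * transport_rate(0.156, cfg))
})

test_that("axis projection uses the 40-degree compass bearing, floored at 0", {
  expect_equal(axis_component(10, 40, cfg), 10)
  expect_equal(axis_component(10, 130, cfg), 0, tolerance = 1e-12)
  expect_equal(axis_component(10, 100, cfg), 5, tolerance = 1e-12)
  # winds opposing the axis floor at zero
  expect_equal(axis_component(10, 220, cfg), 0)
  # adding 360 degrees changes nothing
  expect_equal(axis_component(10, 400, cfg), axis_component(10, 40, cfg))
})

test_that("short interruptions merge events, day-long ones split them", {
  # 3 d NE, 12 h SW, 1.5 d NE at 6-h steps -> one event spanning 5 d
  dirs <- c(rep(45, 12), rep(225, 2), rep(45, 6))
  ev <- detect_ne_events(wind_series(dirs), cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_s, 5 * 86400)
  # 36-h interruption (>= 24 h) splits
  dirs2 <- c(rep(45, 12), rep(225, 6), rep(45, 6))
  ev2 <- detect_ne_events(wind_series(dirs2), cfg)
  expect_equal(nrow(ev2), 2L)
  # exactly 24 h of interruption also splits (strictly-less-than rule)
  dirs3 <- c(rep(45, 4), rep(225, 4), rep(45, 4))
  expect_equal(nrow(detect_ne_events(wind_series(dirs3), cfg)), 2L)
  dirs4 <- c(rep(45, 4), rep(225, 3), rep(45, 4))
  expect_equal(nrow(detect_ne_events(wind_series(dirs4), cfg)), 1L)
  expect_equal(nrow(detect_ne_events(wind_series(numeric(0)), cfg)), 0L)
})

test_that("event detector matches the brute-force oracle on random series", {
  set.seed(101)
  for (i in 1:200) {
    dirs <- runif(sample(30:120, 1), 0, 360)
    w <- wind_series(dirs)
    got <- detect_ne_events(w, cfg)
    want <- oracle_ne_events(w)
    expect_equal(got$start_idx, want$start_idx)
    expect_equal(got$end_idx, want$end_idx)
  }
})

test_that("cumulative transport sums rate times step over NE samples only", {
  w <- wind_series(c(40, 225), speeds = 10)
  ev <- detect_ne_events(w, cfg)
  mc <- cumulative_event_transport(ev[1, ], w, cfg)
  expect_equal(mc, transport_rate(wind_stress(10, cfg), cfg) * 21600,
               tolerance = 1e-9)
  # all-calm event contributes nothing
  w0 <- wind_series(rep(45, 4), speeds = 0)
  ev0 <- detect_ne_events(w0, cfg)
  expect_equal(cumulative_event_transport(ev0[1, ], w0, cfg), 0)
  # additive over disjoint sub-events; gap samples contribute zero
  dirs <- c(rep(45, 4), rep(225, 2), rep(45, 4))
  wm <- wind_series(dirs, speeds = 8)
  evm <- detect_ne_events(wm, cfg)
  expect_equal(nrow(evm), 1L)
  part1 <- list(start_idx = 1L, end_idx = 4L)
  part2 <- list(start_idx = 7L, end_idx = 10L)
  expect_equal(cumulative_event_transport(evm[1, ], wm, cfg),
               cumulative_event_transport(part1, wm, cfg) +
                 cumulative_event_transport(part2, wm, cfg))
})

test_that("transport obeys the k^2 scale law in wind speed", {
  set.seed(7)
  w <- wind_series(runif(200, 0, 360), speeds = runif(200, 0, 12))
  ev <- detect_ne_events(w, cfg)
  w2 <- w; w2$speed_ms <- 3 * w$speed_ms
  for (i in seq_len(nrow(ev))) {
    expect_equal(cumulative_event_transport(ev[i, ], w2, cfg),
                 9 * cumulative_event_transport(ev[i, ], w, cfg),
                 tolerance = 1e-9)
  }
})

test_that("seasonal anomalies self-normalize over the baseline", {
  gen <- make_wind(wind_config(span = c(1988, 2004)), seed = 3)
  seas <- ekman_seasonal(gen$wind, cfg)
  for (s in c("MJ", "DJ")) {
    base <- seas$season == s & seas$year >= 1990 & seas$year <= 2000
    expect_equal(mean(seas$anomaly[base], na.rm = TRUE), 1, tolerance = 1e-12)
  }
  expect_true(all(seas$anomaly > 0, na.rm = TRUE))
})

test_that("a doubled-wind year shows ~4x the anomaly of its twin", {
  # identical NE blocks every year; one year with doubled speeds
  years <- 1988:2002
  blocks <- lapply(years, function(y) {
    w <- wind_series(rep(45, 20), speeds = 9,
                     start = sprintf("%d-05-10 00:00:00", y))
    if (y == 1995) w$speed_ms <- w$speed_ms * 2
    w
  })
  # stitch onto one regular grid: fill between blocks with SW wind
  t0 <- as.POSIXct("1988-01-01", tz = "UTC")
  t1 <- as.POSIXct("2003-01-01", tz = "UTC")
  grid <- seq(t0, t1, by = 21600)
  wind <- data.frame(timestamp = grid, speed_ms = 5,
                     direction_from_deg = 225)
  for (b in blocks) {
    idx <- match(as.numeric(b$timestamp), as.numeric(grid))
    wind$speed_ms[idx] <- b$speed_ms
    wind$direction_from_deg[idx] <- b$direction_from_deg
  }
  seas <- ekman_seasonal(wind, cfg)
  mj <- seas[seas$season == "MJ", ]
  a95 <- mj$anomaly[mj$year == 1995]
  a94 <- mj$anomaly[mj$year == 1994]
  expect_equal(a95 / a94, 4, tolerance = 1e-9)
})

test_that("every in-season event lands in exactly one (year, season) bin", {
  gen <- make_wind(wind_config(span = c(1990, 2000)), seed = 9)
  ev <- detect_ne_events(gen$wind, cfg)
  months <- as.POSIXlt(ev$start, tz = "UTC")$mon + 1
  in_season <- months %in% c(5, 6, 12, 1)
  seas <- ekman_seasonal(gen$wind, cfg, events = ev)
  expect_equal(sum(seas$n_events), sum(in_season))
})

test_that("an empty baseline is rejected with a clear message", {
  gen <- make_wind(wind_config(span = c(1950, 1960)), seed = 4)
  expect_error(ekman_seasonal(gen$wind, cfg), "baseline")
})
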