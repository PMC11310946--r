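test_that("predominant behavior follows occupied time with the energy tie-break", {
  dyn <- dyn_df(rnorm(600, sd = 10), dt = 0.1)     # one minute at 10 Hz
  weather <- constant_weather(15)

  # unanimity
  iv <- aggregate_intervals(label_row("W"), dyn, weather)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$predominant, "W")
  expect_equal(iv$ta, 15)

  # majority: 35 s of W vs 25 s of S
  lab <- rbind(label_row("W", dur_s = 35),
               data.frame(window_start = t_origin() + 35,
                          window_end = t_origin() + 60, behavior = "S"))
  expect_equal(aggregate_intervals(lab, dyn, weather)$predominant, "W")

  # 30/30 tie: higher-energy behavior wins (W over S)
  tie <- rbind(label_row("S", dur_s = 30),
               data.frame(window_start = t_origin() + 30,
                          window_end = t_origin() + 60, behavior = "W"))
  expect_equal(aggregate_intervals(tie, dyn, weather)$predominant, "W")
  # and L loses a tie against anything
  tie2 <- rbind(label_row("L", dur_s = 30),
                data.frame(window_start = t_origin() + 30,
                           window_end = t_origin() + 60, behavior = "R"))
  expect_equal(aggregate_intervals(tie2, dyn, weather)$predominant, "R")
})

test_that("interval mean VeDBA and temperature lookup are correct", {
  dyn <- dyn_df(c(rep(3, 600), rep(0, 600)), c(rep(4, 600), rep(0, 600)),
                rep(0, 1200), dt = 0.1)
  # temperature changes between the two minutes' midpoints
  weather <- data.frame(timestamp = t_origin() + c(30, 90), ta = c(10, 20))
  iv <- aggregate_intervals(label_row("S", dur_s = 120), dyn, weather)
  expect_equal(iv$mean_vedba, c(5, 0), tolerance = 1e-9)
  expect_equal(iv$ta, c(10, 20))

  # no weather record within 24 h is an error
  far <- data.frame(timestamp = t_origin() + 200000, ta = 15)
  expect_error(aggregate_intervals(label_row("S"), dyn_df(rnorm(600), dt = 0.1),
                                   far), "no weather record within")
})

test_that("sparse intervals are excluded and counted", {
  dyn <- dyn_df(rnorm(660), dt = 0.1)
  dyn <- dyn[c(1:600, seq(601, 660, by = 4)), ]   # minute 2 at ~25% coverage
  iv <- aggregate_intervals(label_row("S", dur_s = 120), dyn,
                            constant_weather(), rate_hz = 10)
  expect_equal(nrow(iv), 1)
  expect_equal(attr(iv, "excluded"), 1L)
})

test_that("interval_energy delegates to the behavior equations", {
  iv <- data.frame(start = t_origin(), duration_s = 60, mean_vedba = 0,
                   predominant = "S", ta = 0, coverage = 1)
  out <- interval_energy(iv, animal_profile(weight_kg = 1e-9))
  expect_equal(out$energy, 66.98, tolerance = 1e-6)

  # lying vs standing at identical summaries -> exactly 0.29
  iv2 <- iv; iv2$mean_vedba <- 120; iv2$ta <- 15
  ivL <- iv2; ivL$predominant <- "L"
  p60 <- animal_profile(weight_kg = 60)
  expect_equal(interval_energy(ivL, p60)$energy /
                 interval_energy(iv2, p60)$energy, 0.29)

  # dba_unit = "g" converts the pipeline's mG before the equations
  pg <- energy_params(dba_unit = "g")
  eg <- suppressWarnings(interval_energy(iv2, p60, pg))
  expect_equal(eg$energy,
               66.98 + 0.15 * 225 - 7.97 * 15 + 60 + 0.12)
})

test_that("hourly budget conserves monitored time", {
  set.seed(53)
  # 3 hours of one-minute intervals with random behaviors
  n <- 180
  iv <- data.frame(
    start = t_origin() + (seq_len(n) - 1) * 60,
    duration_s = 60,
    mean_vedba = runif(n, 0, 100),
    predominant = sample(behavior_codes(), n, replace = TRUE),
    ta = 15, coverage = 1
  )
  hb <- hourly_time_budget(iv)
  expect_equal(nrow(hb), 24)
  totals <- rowSums(hb[, behavior_codes()])
  expect_equal(totals[1:3], rep(60, 3), ignore_attr = TRUE)
  expect_equal(totals[4:24], rep(0, 21), ignore_attr = TRUE)

  # an all-lying hour produces the expected row
  ivL <- iv[1:60, ]; ivL$predominant <- "L"
  hbL <- hourly_time_budget(ivL)
  expect_equal(hbL$L[1], 60)
  expect_equal(sum(hbL[1, c("E", "R", "S", "W")]), 0)
})

test_that("daily report shares one accumulator between parts and total", {
  set.seed(59)
  n <- 500
  iv <- data.frame(
    start = t_origin() + (seq_len(n) - 1) * 60, duration_s = 60,
    mean_vedba = runif(n, 0, 3000),
    predominant = sample(behavior_codes(), n, replace = TRUE),
    ta = runif(n, 5, 25), coverage = 1
  )
  iv <- interval_energy(iv, animal_profile())
  rep <- daily_energy_report(iv, animal_profile())
  parts <- rep$energy[rep$behavior != "Total"]
  expect_identical(rep$energy[rep$behavior == "Total"], sum(parts))
  expect_equal(sum(parts), sum(iv$energy))
  expect_equal(rep$minutes[rep$behavior == "Total"], n)

  # single-behavior example: 5 intervals of energy 10
  iv5 <- iv[1:5, ]; iv5$predominant <- "R"; iv5$energy <- 10
  r5 <- daily_energy_report(iv5, animal_profile())
  expect_equal(r5$energy[r5$behavior == "R"], 50)
  expect_equal(r5$energy[r5$behavior == "Total"], 50)

  # empty input -> all-zero report
  r0 <- daily_energy_report(iv[0, ], animal_profile())
  expect_true(all(r0$energy == 0) && all(r0$minutes == 0))
})

test_that("pipeline equals an independent brute-force per-minute oracle", {
  day <- simulate_day("active", seed = 101, span_s = 3600 * 2)
  cl <- clean_records(day$samples)
  res <- run_pipeline(cl$samples, day$weather, animal_profile(),
                      labels = day$labels, rate_hz = 10)
  dyn <- remove_gravity(cl$samples, rate_hz = 10)
  oracle <- brute_force_minutes(day$labels, dyn, day$weather)
  expect_equal(nrow(res$intervals), nrow(oracle))
  expect_equal(as.numeric(res$intervals$start), oracle$start)
  expect_equal(res$intervals$mean_vedba, oracle$mean_vedba, tolerance = 1e-9)
  expect_identical(res$intervals$predominant, oracle$predominant)
  expect_equal(res$intervals$ta, oracle$ta)
  expect_equal(res$intervals$energy, oracle$energy, tolerance = 1e-9)
  expect_equal(res$daily$energy[res$daily$behavior == "Total"],
               sum(oracle$energy), tolerance = 1e-9)
})

test_that("relabeling standing intervals as walking never decreases the total", {
  day <- simulate_day("active", seed = 103, span_s = 3600)
  res <- run_pipeline(day$samples, day$weather, animal_profile(),
                      labels = day$labels, rate_hz = 10)
  iv <- res$intervals
  iv$predominant[iv$predominant == "S"] <- "W"
  iv2 <- suppressWarnings(interval_energy(iv, animal_profile()))
  total1 <- res$daily$energy[res$daily$behavior == "Total"]
  total2 <- sum(iv2$energy)
  expect_gte(total2, total1)
})

test_that("zero-length input yields structured empty outputs", {
  empty <- accel_df(numeric(0))
  res <- run_pipeline(empty, constant_weather(), animal_profile(),
                      labels = label_row("L"))
  expect_equal(nrow(res$intervals), 0)
  expect_equal(nrow(res$hourly), 24)
  expect_true(all(res$daily$energy == 0))
})
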