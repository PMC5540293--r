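test_that("zero-noise residency pins every pre-switch fix at the centre", {
  cfg <- sim_config(n_whales = 1, residency_sd = 0, tide_coupling = 0,
                    dup_fraction = 0, migration_speed = 0,
                    argos_class_probs = c(`3` = 1), argos_error_sd = c(`3` = 0),
                    fixes_per_day = 6)
  fx <- simulate_tracks(cfg)
  d <- geodesic_km(cbind(fx$lon, fx$lat), cfg$residency_center)
  expect_lt(max(d), 1e-6)
})

test_that("zero-noise migration drifts at the configured speed and bearing", {
  cfg <- sim_config(n_whales = 1, residency_sd = 0, tide_coupling = 0,
                    dup_fraction = 0, migration_speed = 30,
                    argos_class_probs = c(`3` = 1), argos_error_sd = c(`3` = 0),
                    fixes_per_day = 6)
  fx <- simulate_tracks(cfg)
  t_days <- as.numeric(difftime(fx$timestamp, as.POSIXct("2003-07-05", tz = "UTC"),
                                units = "days"))
  switch_off <- as.numeric(as.Date("2003-08-09") - cfg$start_date)
  d_since <- pmax(0, t_days - switch_off)
  post <- d_since > 0.1
  d <- geodesic_km(cbind(fx$lon, fx$lat), cfg$residency_center)
  expect_true(all(abs(d[post] - 30 * d_since[post]) / (30 * d_since[post]) < 0.01))
})

test_that("residency walk has the configured stationary spread", {
  cfg <- sim_config(n_whales = 1, residency_sd = 5, tide_coupling = 0,
                    dup_fraction = 0, migration_speed = 0, switch_doy = 365,
                    start_date = "2003-01-01", end_date = "2003-12-01",
                    argos_class_probs = c(`3` = 1), argos_error_sd = c(`3` = 0),
                    fixes_per_day = 30, tau_days = 0.25, seed = 42)
  fx <- simulate_tracks(cfg)
  expect_gt(nrow(fx), 9000)
  xy <- project_local(cbind(fx$lon, fx$lat), centre = cfg$residency_center)
  expect_lt(abs(sd(xy$x) - 5) / 5, 0.05)
  expect_lt(abs(sd(xy$y) - 5) / 5, 0.05)
})

test_that("track generation is reproducible and chronological", {
  cfg <- sim_config(n_whales = 3)
  a <- simulate_tracks(cfg)
  b <- simulate_tracks(cfg)
  expect_identical(a, b)
  for (w in unique(a$whale_id)) {
    expect_false(is.unsorted(a$timestamp[a$whale_id == w]))
  }
  # per-whale streams do not depend on n_whales
  solo <- simulate_whale_track(sim_config(n_whales = 13), 2)
  expect_identical(solo, simulate_whale_track(sim_config(n_whales = 3), 2))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(start_date = "2003-09-01", end_date = "2003-07-01"),
               "start_date")
  expect_error(sim_config(argos_class_probs = c(`3` = 0.5)), "sum to 1")
  expect_error(sim_config(residency_sd = -1), "residency_sd")
  expect_error(simulate_whale_track(sim_config(fixes_per_day = 0), 0),
               "fixes_per_day")
})

test_that("noiseless discharge is exactly constant and runs are reproducible", {
  d <- simulate_discharge(c(`2003` = 3331), noise_sd = 0)
  expect_true(all(d$discharge == 3331))
  a <- simulate_discharge(c(`2002` = 2831, `2005` = 5163), noise_sd = 150, seed = 9)
  b <- simulate_discharge(c(`2002` = 2831, `2005` = 5163), noise_sd = 150, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_discharge(numeric(0)), "non-empty")
})

test_that("simulated dry/wet year means round-trip through classification", {
  d <- simulate_discharge(c(`2004` = 2831, `2005` = 5163), noise_sd = 150, seed = 3)
  cls <- classify_wet_dry(seasonal_means(d), baseline_mean = 3331)
  expect_equal(cls$label[cls$year == 2004], "dry")
  expect_equal(cls$label[cls$year == 2005], "wet")
  expect_lt(abs(cls$seasonal_mean[cls$year == 2005] - 5163), 150)
})

test_that("tide series is semidiurnal with fortnightly spring clusters", {
  td <- simulate_tides(amplitude = 2, days = 92)
  h <- high_tides(td)
  per_day <- table(as.Date(h$time))
  expect_true(all(per_day >= 1 & per_day <= 3))
  expect_gt(mean(per_day), 1.5)
  # spring maxima (fortnightly envelope peaks) separated by ~14.77 d
  spring <- h[h$phase == "spring", ]
  gaps <- which(diff(as.numeric(spring$time)) / 86400 > 4)
  cluster <- cumsum(c(1, seq_along(diff(spring$time)) %in% gaps))
  peak_t <- vapply(split(spring, cluster),
                   function(s) as.numeric(s$time[which.max(s$height)]), numeric(1))
  seps <- diff(sort(peak_t)) / 86400
  expect_true(all(abs(seps - 14.77) < 0.6))
})

test_that("flat tide series flags no high tides", {
  td <- simulate_tides(amplitude = 0)
  expect_true(all(td$height == 0))
  expect_equal(nrow(high_tides(td)), 0)
})

test_that("shoreline fixture is a seaward funnel with the mouth at its apex", {
  sh <- make_shoreline()
  expect_lt(dist_to_shoreline(port_nelson(), sh), 1e-6)
  xy <- project_local(sh$vertices)
  expect_equal(max(xy$y), 60, tolerance = 1e-6)
  # V-shape: no self intersection means x strictly increasing along vertices
  expect_false(is.unsorted(xy$x, strictly = TRUE))
})

test_that("strip counts record each in-strip whale exactly once", {
  des <- survey_design()
  # all whales inside one strip segment of transect 4
  pos <- cbind(des$transect_x[4] + runif(25, -0.3, 0.3), runif(25, 7.05, 7.95))
  rec <- strip_counts(pos, des)
  expect_equal(sum(rec$count), 25)
  expect_equal(unique(rec$transect), 4)
  expect_equal(unique(rec$interval), 8L)
  # whales in different transects are never double-counted
  pos2 <- rbind(c(des$transect_x[1], 5.5), c(des$transect_x[9] + 0.2, 12.5))
  rec2 <- strip_counts(pos2, des)
  expect_equal(sum(rec2$count), 2)
  expect_equal(sort(rec2$transect), c(1, 9))
})

test_that("zero strip width warns and records nothing", {
  des <- survey_design(strip_halfwidth_km = 0)
  expect_warning(rec <- strip_counts(cbind(0, 5), des), "zero strip width")
  expect_equal(nrow(rec), 0)
})

test_that("uniform-density surveys count lambda times the strip area on average", {
  des <- survey_design()
  xr <- range(des$transect_x) + c(-1, 1) * des$spacing_km / 2
  frame_area <- diff(xr) * des$transect_length_km
  lambda <- 0.3
  n_whales <- round(lambda * frame_area)
  strip_area <- des$n_transects * des$transect_length_km * 2 * des$strip_halfwidth_km
  totals <- vapply(1:200, function(i) {
    sum(simulate_survey(des, n_whales, seed = 1000 + i)$count)
  }, numeric(1))
  expected <- lambda * strip_area
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se)
})
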