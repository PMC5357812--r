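# Synthetic study-system generators: habitat mosaic proportions, weather
# seasonality, track covariate structure, corruption and calibration.

test_that("habitat mosaic matches configured proportions and degenerates cleanly", {
  cfg <- small_sim(seed = 21)
  ew <- generate_environment(cfg)
  classes <- attr(ew$env$habitat, "classes")
  realized <- mean(ew$env$habitat == match("Low shrubland", classes))
  expect_gte(realized, 0.83)
  expect_lte(realized, 0.87)
  # all configured-positive classes within 2 percentage points
  props <- cfg$habitat_props[cfg$habitat_props > 0]
  for (cl in names(props)) {
    r <- mean(ew$env$habitat == match(cl, classes))
    expect_lt(abs(r - props[[cl]]), 0.02)
  }

  uni <- small_sim(seed = 21, habitat_props = c("Low shrubland" = 1))
  ew_uni <- generate_environment(uni)
  expect_true(all(ew_uni$env$habitat == 1L))
  expect_identical(attr(ew_uni$env$habitat, "classes"), "Low shrubland")
})

test_that("environment generation is deterministic and validates its config", {
  a <- generate_environment(small_sim(seed = 5))
  b <- generate_environment(small_sim(seed = 5))
  expect_identical(a, b)
  expect_error(sim_config(habitat_props = c("Low shrubland" = 0.5)),
               "sum to 1")
  expect_error(sim_config(artifact_rates = c(hdop = 2, time_offset = 0,
                                             z_error = 0, impossible_move = 0,
                                             incomplete = 0)), "\\[0, 1\\]")
  expect_error(sim_config(fix_interval_h = 0), "fix_interval_h")
  expect_error(generate_environment(small_sim(grid_extent_m = 100)),
               "too small")
})

test_that("DEM is smooth enough that clean fixes carry small z-error", {
  ew <- generate_environment(small_sim(seed = 9))
  dem <- ew$env$dem
  # max gradient per pixel step far below the 100 m screening threshold
  gx <- abs(dem[, -1] - dem[, -ncol(dem)])
  gy <- abs(dem[-1, ] - dem[-nrow(dem), ])
  expect_lt(max(gx, gy), 20)
})

test_that("water polygons are closed, non-self-intersecting rings", {
  ew <- generate_environment(small_sim(seed = 13))
  for (ring in ew$water$polygons) {
    expect_identical(ring[1, ], ring[nrow(ring), ])
    # star-shaped construction: vertices strictly ordered by angle from centre
    ctr <- colMeans(ring[-nrow(ring), ])
    ang <- atan2(ring[-nrow(ring), 2] - ctr[2], ring[-nrow(ring), 1] - ctr[1])
    expect_true(all(diff(sort(ang)) > 0))
  }
})

test_that("weather has austral seasonality, hourly spacing and valid rainfall", {
  cfg <- sim_config(n_individuals = 1, start = "2014-12-01",
                    end = "2015-11-30", seed = 31)
  w <- generate_weather(cfg)
  expect_true(all(diff(as.numeric(w$timestamp)) == 3600))
  expect_true(all(w$rain_mm >= 0))
  expect_true(all(is.finite(w$temp_c)))
  # summer days regularly exceed 30 C
  jan <- w[format(w$timestamp, "%m") == "01", ]
  daily_max <- tapply(jan$temp_c, format(jan$timestamp, "%d"), max)
  expect_gt(max(daily_max), 30)
  # oracle: direct monthly averaging orders winter < spring < summer
  mo <- format(w$timestamp, "%b")
  mmean <- tapply(w$temp_c, mo, mean)
  winter <- mean(mmean[c("Jun", "Jul", "Aug")])
  spring <- mean(mmean[c("Sep", "Oct", "Nov")])
  summer <- mean(mmean[c("Dec", "Jan", "Feb")])
  expect_lt(winter, spring)
  expect_lt(spring, summer)
})

test_that("zero-noise zero-amplitude weather is constant", {
  cfg <- small_sim(weather = list(seasonal_amp = 0, diel_amp = 0,
                                  noise_sd = 0, rain_p_hourly = 0))
  w <- generate_weather(cfg)
  expect_true(all(w$temp_c == w$temp_c[1]))
  expect_true(all(w$rain_mm == 0))
})

test_that("temperature effect on step length is recovered across quartiles", {
  # beta_temp > 0, all other effects zero: mean log-step must increase
  # monotonically across temperature quartiles (Monte Carlo, >= 1e4 steps)
  cfg <- sim_config(n_individuals = 3, start = "2014-12-01",
                    end = "2015-11-30", pixel_m = 20,
                    beta_temp = 0.02, beta_water = 0,
                    month_offsets = setNames(rep(0, 12), month.abb),
                    tod_offsets = setNames(rep(0, 12),
                                           sprintf("%02d", seq(0, 22, 2))),
                    indiv_sd = 0, seed = 17)
  ew <- generate_environment(cfg)
  w <- generate_weather(cfg)
  tr <- simulate_tracks(ew$env, ew$water, w, cfg)
  expect_gt(sum(!is.na(tr$step_true_m)), 1e4)
  # reconstruct the per-step temperature covariate the generator used
  idx <- match(as.numeric(tr$timestamp), as.numeric(w$timestamp))
  temp2h <- (w$temp_c[idx] + w$temp_c[pmax(idx - 1, 1)]) / 2
  ok <- !is.na(tr$step_true_m)
  q <- cut(temp2h[ok], breaks = quantile(temp2h[ok], 0:4 / 4),
           include.lowest = TRUE)
  m <- tapply(log10(tr$step_true_m[ok]), q, mean)
  expect_true(all(diff(m) > 0))
})

test_that("all-zero coefficients with zero noise give constant step length", {
  cfg <- small_sim(beta0 = 1, beta_temp = 0, beta_water = 0,
                   month_offsets = setNames(rep(0, 12), month.abb),
                   tod_offsets = setNames(rep(0, 12),
                                          sprintf("%02d", seq(0, 22, 2))),
                   indiv_sd = 0, resid_sd = 0)
  ew <- generate_environment(cfg)
  w <- generate_weather(cfg)
  tr <- simulate_tracks(ew$env, ew$water, w, cfg)
  st <- tr$step_true_m[!is.na(tr$step_true_m)]
  expect_equal(st, rep(10, length(st)), tolerance = 1e-12)
})

test_that("positions stay inside the grid and steps are nonnegative", {
  cfg <- small_sim(seed = 23)
  ew <- generate_environment(cfg)
  w <- generate_weather(cfg)
  tr <- simulate_tracks(ew$env, ew$water, w, cfg)
  expect_true(all(tr$x >= 0 & tr$x <= ew$env$extent_m[1]))
  expect_true(all(tr$y >= 0 & tr$y <= ew$env$extent_m[2]))
  expect_true(all(tr$step_true_m >= 0, na.rm = TRUE))
})

test_that("October is the peak month for mean daily distance under defaults", {
  for (seed in c(3, 7, 19)) {
    cfg <- sim_config(n_individuals = 1, pixel_m = 20, seed = seed)
    ew <- generate_environment(cfg)
    w <- generate_weather(cfg)
    tr <- simulate_tracks(ew$env, ew$water, w, cfg)
    day <- format(tr$timestamp, "%Y-%m-%d", tz = "Etc/GMT-2")
    daily <- tapply(tr$step_true_m, day, sum, na.rm = TRUE)
    mo <- format(as.Date(names(daily)), "%b")
    mmean <- tapply(daily, mo, mean)
    expect_identical(names(which.max(mmean)), "Oct")
  }
})

test_that("corruption with zero error and zero rates reproduces truth", {
  cfg <- small_sim(error_scale = 0,
                   artifact_rates = c(hdop = 0, time_offset = 0, z_error = 0,
                                      impossible_move = 0, incomplete = 0))
  ew <- generate_environment(cfg)
  w <- generate_weather(cfg)
  tr <- simulate_tracks(ew$env, ew$water, w, cfg)
  cf <- corrupt_fixes(tr, ew$env, cfg)
  expect_equal(cf$fixes$x, tr$x, tolerance = 1e-12)
  expect_equal(cf$fixes$y, tr$y, tolerance = 1e-12)
  expect_identical(cf$fixes$timestamp, tr$timestamp)
  expect_identical(nrow(cf$labels), 0L)
})

test_that("planted GPS error lengths average near 17 m and artifact fraction near 12.7%", {
  cfg <- sim_config(n_individuals = 3, start = "2015-01-01",
                    end = "2015-04-30", pixel_m = 10, seed = 41)
  ew <- generate_environment(cfg)
  w <- generate_weather(cfg)
  tr <- simulate_tracks(ew$env, ew$water, w, cfg)
  cf <- corrupt_fixes(tr, ew$env, cfg)
  n <- nrow(cf$fixes)
  expect_gt(n, 4000)
  clean <- setdiff(seq_len(n), cf$labels$fix_index[cf$labels$rule == "impossible_move"])
  err <- sqrt((cf$fixes$x[clean] - tr$x[clean])^2 +
              (cf$fixes$y[clean] - tr$y[clean])^2)
  expect_gt(mean(err), 15)
  expect_lt(mean(err), 19)
  frac <- nrow(cf$labels) / n
  p <- sum(cfg$artifact_rates)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
  # labels reference existing fixes, one rule per fix
  expect_true(all(cf$labels$fix_index %in% seq_len(n)))
  expect_identical(anyDuplicated(cf$labels$fix_index), 0L)
})

test_that("calibration fixes follow the configured error distribution", {
  cfg <- sim_config(seed = 8)
  cal <- generate_calibration(c(100, 200), 500, cfg)
  err <- sqrt((cal$x_obs - cal$x_true)^2 + (cal$y_obs - cal$y_true)^2)
  expect_gt(mean(err), 15)
  expect_lt(mean(err), 19)
  expect_identical(cal, generate_calibration(c(100, 200), 500, cfg))
  expect_error(generate_calibration(c(0, 0), 1, cfg), "at least 2")

  cal0 <- generate_calibration(c(5, 5), 10, sim_config(error_scale = 0))
  expect_true(all(cal0$x_obs == 5 & cal0$y_obs == 5))
})

test_that("generators are jointly deterministic under a fixed seed", {
  run <- function() {
    cfg <- small_sim(seed = 99)
    ew <- generate_environment(cfg)
    w <- generate_weather(cfg)
    tr <- simulate_tracks(ew$env, ew$water, w, cfg)
    cf <- corrupt_fixes(tr, ew$env, cfg)
    cal <- generate_calibration(c(0, 0), 50, cfg)
    list(ew, w, tr, cf, cal)
  }
  expect_identical(run(), run())
})
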