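# Synthetic study system: habitat mosaic + DEM, water features, hourly weather,
# correlated-random-walk tracks whose step lengths follow the same log10-linear
# covariate model the inference stage fits, corrupted GPS fixes with ground-truth
# artifact labels, and calibration fixes at a known point.

#' Habitat classes used by the synthetic land-cover mosaic
#'
#' The class catalogue mirrors a regrouped South African land-cover legend for
#' semi-arid Karoo rangeland: a dominant low-shrubland matrix with minority
#' bush, grassland, wetland, cultivated and water classes.
#' @export
HABITAT_CLASSES <- c(
  "Water seasonal", "Water permanent", "Wetlands", "Dense bush", "Open bush",
  "Grassland", "Low shrubland", "Cultivated commercial fields", "Non-vegetated"
)

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic study system. Defaults emulate a
#' 10-animal, 12-month bihourly telemetry deployment in semi-arid Karoo
#' shrubland: ~4,368 fixes per individual, GPS fix-error lengths with mean
#' about 17 m and a heavy right tail, about 12.75% of fixes corrupted by
#' transmitter artifacts, a habitat mosaic dominated (85%) by low shrubland,
#' and movement that increases with temperature, decreases with distance from
#' water, and peaks in October (austral spring) with a winter trough.
#'
#' @param n_individuals number of telemetered animals.
#' @param start,end first and last calendar date (local time, UTC+2) of the
#'   deployment, as `"YYYY-MM-DD"` strings.
#' @param fix_interval_h hours between programmed fixes (must be > 0).
#' @param grid_extent_m side length of the square study grid in metres.
#' @param pixel_m land-cover pixel size in metres (3 m mirrors the source
#'   land-cover product).
#' @param habitat_props named fractions per habitat class; must sum to 1.
#' @param n_water_points,n_water_polygons numbers of manmade water-source
#'   points and inland water polygons to place.
#' @param beta0 intercept of the log10 step-length model (log10 metres).
#' @param beta_temp temperature coefficient (log10 m per degree C).
#' @param beta_water distance-from-water coefficient (log10 m per metre).
#' @param month_offsets named (Jan..Dec) additive month effects; April is the
#'   reference (0).
#' @param tod_offsets named ("00".."22") additive time-of-day effects; midnight
#'   is the reference (0).
#' @param indiv_sd standard deviation of per-individual random intercepts.
#' @param resid_sd residual SD of log10 step length.
#' @param turn_sd SD (radians) of the heading increments of the correlated
#'   random walk.
#' @param error_log10_mean,error_log10_sd location and scale of the log10 GPS
#'   error-length distribution (defaults give mean error about 16.8 m,
#'   range roughly 1–150 m).
#' @param error_scale multiplier on all measurement noise (0 gives perfect
#'   fixes).
#' @param artifact_rates named per-rule corruption probabilities
#'   (`hdop`, `time_offset`, `z_error`, `impossible_move`, `incomplete`);
#'   each in \[0, 1\]. Defaults sum to 0.1275.
#' @param weather list of weather-generator parameters: `t_mean`,
#'   `seasonal_amp`, `diel_amp`, `noise_sd` (degrees C), `peak_doy` (day of
#'   year of the seasonal maximum; mid-January for the austral summer),
#'   `rain_p_hourly` (probability an hour is wet), `rain_event_mean_mm`.
#' @param seed integer root seed; the five generators draw from fixed offsets
#'   of it, so a fixed seed gives byte-identical outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 10,
                       start = "2014-12-01", end = "2015-11-30",
                       fix_interval_h = 2,
                       grid_extent_m = 6000, pixel_m = 3,
                       habitat_props = c(
                         "Water seasonal" = 0.001, "Water permanent" = 0.0005,
                         "Wetlands" = 0.0005, "Dense bush" = 0.08,
                         "Open bush" = 0.03, "Grassland" = 0.015,
                         "Low shrubland" = 0.85,
                         "Cultivated commercial fields" = 0.002,
                         "Non-vegetated" = 0.021),
                       n_water_points = 4, n_water_polygons = 2,
                       beta0 = 0.78, beta_temp = 0.02, beta_water = -1e-4,
                       month_offsets = c(
                         Jan = -0.01, Feb = -0.05, Mar = -0.02, Apr = 0,
                         May = -0.03, Jun = -0.20, Jul = -0.20, Aug = -0.10,
                         Sep = 0.10, Oct = 0.28, Nov = 0.08, Dec = 0.01),
                       tod_offsets = c(
                         "00" = 0, "02" = 0, "04" = 0.015, "06" = 0.02,
                         "08" = 0.06, "10" = 0.18, "12" = 0.23, "14" = 0.19,
                         "16" = 0.25, "18" = 0.28, "20" = 0.14, "22" = 0.02),
                       indiv_sd = 0.1, resid_sd = 0.25, turn_sd = 1.2,
                       error_log10_mean = 1.1, error_log10_sd = 0.33,
                       error_scale = 1,
                       artifact_rates = c(hdop = 0.04, time_offset = 0.03,
                                          z_error = 0.025,
                                          impossible_move = 0.02,
                                          incomplete = 0.0125),
                       weather = list(),
                       seed = 42) {
  wdef <- list(t_mean = 18, seasonal_amp = 7.2, diel_amp = 6, noise_sd = 2,
               peak_doy = 15, rain_p_hourly = 0.01, rain_event_mean_mm = 2)
  weather <- utils::modifyList(wdef, weather)

  if (abs(sum(habitat_props) - 1) > 1e-9)
    stop("habitat_props must sum to 1 (got ", sum(habitat_props), ")")
  if (!all(names(habitat_props) %in% HABITAT_CLASSES))
    stop("unknown habitat class in habitat_props")
  if (fix_interval_h <= 0) stop("fix_interval_h must be > 0")
  if (any(artifact_rates < 0 | artifact_rates > 1))
    stop("artifact_rates must lie in [0, 1]")
  need_rules <- c("hdop", "time_offset", "z_error", "impossible_move", "incomplete")
  if (!setequal(names(artifact_rates), need_rules))
    stop("artifact_rates must be named: ", paste(need_rules, collapse = ", "))
  if (!setequal(names(month_offsets), month.abb))
    stop("month_offsets must be named Jan..Dec")
  tod_levels <- sprintf("%02d", seq(0, 22, by = 2))
  if (!setequal(names(tod_offsets), tod_levels))
    stop("tod_offsets must be named '00','02',...,'22'")
  if (error_scale < 0) stop("error_scale must be >= 0")

  structure(list(
    n_individuals = as.integer(n_individuals), start = start, end = end,
    fix_interval_h = fix_interval_h, grid_extent_m = grid_extent_m,
    pixel_m = pixel_m, habitat_props = habitat_props,
    n_water_points = as.integer(n_water_points),
    n_water_polygons = as.integer(n_water_polygons),
    beta0 = beta0, beta_temp = beta_temp, beta_water = beta_water,
    month_offsets = month_offsets[month.abb],
    tod_offsets = tod_offsets[tod_levels],
    indiv_sd = indiv_sd, resid_sd = resid_sd, turn_sd = turn_sd,
    error_log10_mean = error_log10_mean, error_log10_sd = error_log10_sd,
    error_scale = error_scale,
    artifact_rates = artifact_rates[need_rules],
    weather = weather, seed = as.integer(seed)
  ), class = "sim_config")
}

# Fix schedule (local time) implied by a config.
fix_times <- function(config) {
  t0 <- as.POSIXct(paste(config$start, "00:00:00"), tz = TORTMOVE_TZ)
  t1 <- as.POSIXct(paste(config$end, "23:59:59"), tz = TORTMOVE_TZ)
  seq(t0, t1, by = config$fix_interval_h * 3600)
}

#' Generate the synthetic environment: habitat mosaic, DEM and water features
#'
#' The habitat raster is produced by thresholding a smooth random field at the
#' quantiles of the configured class proportions, which yields spatially
#' coherent patches whose realized class frequencies match the configured
#' proportions to within one pixel. The DEM is a smooth low-relief surface
#' (about 60 m relief over the grid) so that true fixes carry negligible
#' z-coordinate error. Water features are placed uniformly in the grid
#' interior: manmade points, and star-shaped (non-self-intersecting) closed
#' polygon rings for inland water bodies.
#'
#' @param config a [sim_config()].
#' @return list with elements `env` (class `env_grid`: `origin`, `pixel_m`,
#'   `habitat` integer matrix with a `classes` attribute, `dem`) and
#'   `water` (class `water_features`: `points` matrix, `polygons` list of
#'   closed rings).
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  extent <- config$grid_extent_m
  px <- config$pixel_m
  n_col <- as.integer(round(extent / px))
  n_row <- n_col
  if (n_col < 2) stop("grid too small: fewer than 2 pixels per side")
  if ((config$n_water_points + config$n_water_polygons) > 0 && extent < 400)
    stop("grid too small to place the requested water features")

  with_seed(config$seed + 1L, {
    # Smooth field -> quantile bands -> patchy mosaic with exact proportions.
    coarse <- matrix(stats::rnorm(24 * 24), 24, 24)
    field <- upsample_bilinear(coarse, n_row, n_col) +
      stats::rnorm(n_row * n_col, sd = 0.15)
    props <- config$habitat_props[config$habitat_props > 0]
    qs <- stats::quantile(field, cumsum(props), names = FALSE)
    qs[length(qs)] <- Inf
    codes <- findInterval(field, c(-Inf, qs[-length(qs)]))
    habitat <- matrix(as.integer(codes), n_row, n_col)
    attr(habitat, "classes") <- names(props)

    dem_field <- upsample_bilinear(matrix(stats::rnorm(8 * 8), 8, 8),
                                   n_row, n_col)
    dem <- 850 + 60 * (dem_field - mean(dem_field)) / stats::sd(dem_field)

    env <- structure(list(origin = c(0, 0), pixel_m = px,
                          n_row = n_row, n_col = n_col,
                          extent_m = c(n_col * px, n_row * px),
                          habitat = habitat, dem = dem),
                     class = "env_grid")

    pts <- if (config$n_water_points > 0) {
      cbind(x = stats::runif(config$n_water_points, 0.1, 0.9) * extent,
            y = stats::runif(config$n_water_points, 0.1, 0.9) * extent)
    } else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))

    polys <- vector("list", config$n_water_polygons)
    for (i in seq_len(config$n_water_polygons)) {
      cx <- stats::runif(1, 0.15, 0.85) * extent
      cy <- stats::runif(1, 0.15, 0.85) * extent
      r <- stats::runif(1, 30, 80)
      ang <- sort(stats::runif(12, 0, 2 * pi))
      rad <- r * stats::runif(12, 0.75, 1.25)
      ring <- cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
      ring <- rbind(ring, ring[1, , drop = FALSE])   # closed ring
      polys[[i]] <- ring
    }

    water <- structure(list(points = pts, polygons = polys),
                       class = "water_features")
    list(env = env, water = water)
  })
}

#' Generate hourly weather for the simulation window
#'
#' Temperature is the sum of a seasonal cosine (austral phasing: warmest
#' around mid-January, coolest in July), a diel cosine peaking at 14:00 local,
#' and Gaussian noise. Rainfall is sparse: each hour is wet with a small
#' probability and wet hours draw exponential amounts.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `weather_series` with `timestamp` (hourly,
#'   local time), `temp_c`, `rain_mm`.
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$weather
  t0 <- as.POSIXct(paste(config$start, "00:00:00"), tz = TORTMOVE_TZ)
  t1 <- as.POSIXct(paste(config$end, "23:00:00"), tz = TORTMOVE_TZ)
  if (as.numeric(difftime(t1, t0, units = "days")) < 1)
    stop("date range must cover at least one day")
  ts <- seq(t0, t1, by = 3600)
  doy <- as.integer(format(ts, "%j", tz = TORTMOVE_TZ))
  hr <- as.integer(format(ts, "%H", tz = TORTMOVE_TZ))
  with_seed(config$seed + 2L, {
    temp <- w$t_mean +
      w$seasonal_amp * cos(2 * pi * (doy - w$peak_doy) / 365.25) +
      w$diel_amp * cos(2 * pi * (hr - 14) / 24) +
      stats::rnorm(length(ts), sd = w$noise_sd)
    wet <- stats::runif(length(ts)) < w$rain_p_hourly
    rain <- ifelse(wet, stats::rexp(length(ts), rate = 1 / w$rain_event_mean_mm), 0)
    structure(data.frame(timestamp = ts, temp_c = temp, rain_mm = rain),
              class = c("weather_series", "data.frame"))
  })
}

# Fast closure computing distance from a single point to the water layer
# (point features + polygon boundaries; interior not special-cased -- tracks
# essentially never enter the small water polygons).
make_water_dist <- function(water) {
  px <- water$points[, 1]; py <- water$points[, 2]
  sx1 <- sy1 <- sx2 <- sy2 <- numeric(0)
  for (ring in water$polygons) {
    m <- nrow(ring)
    sx1 <- c(sx1, ring[-m, 1]); sy1 <- c(sy1, ring[-m, 2])
    sx2 <- c(sx2, ring[-1, 1]); sy2 <- c(sy2, ring[-1, 2])
  }
  ex <- sx2 - sx1; ey <- sy2 - sy1
  el2 <- ex^2 + ey^2
  function(x, y) {
    d2 <- Inf
    if (length(px)) d2 <- min((px - x)^2 + (py - y)^2)
    if (length(sx1)) {
      t <- pmin(1, pmax(0, ((x - sx1) * ex + (y - sy1) * ey) / el2))
      d2 <- min(d2, min((sx1 + t * ex - x)^2 + (sy1 + t * ey - y)^2))
    }
    sqrt(d2)
  }
}

#' Simulate true movement tracks
#'
#' Positions follow a correlated random walk with reflecting boundaries. Each
#' bihourly step length is `10^mu` with
#' `mu = beta0 + beta_temp * temp_2h + beta_water * dist_water + month offset +
#' time-of-day offset + individual intercept + N(0, resid_sd)`,
#' where `temp_2h` is the mean hourly temperature over the two hours before
#' the fix, and `dist_water` is the distance from the step's starting
#' position to the nearest water feature. The true coefficients and
#' random intercepts are retained as attributes for recovery tests.
#'
#' @param env,water output of [generate_environment()].
#' @param weather output of [generate_weather()].
#' @param config a [sim_config()].
#' @return data.frame of class `true_tracks` with one row per fix:
#'   `individual`, `sex`, `body_mass_g`, `timestamp`, `x`, `y`, `step_true_m`
#'   (NA for the first fix of each individual). Attributes: `coefficients`
#'   (list of true generator coefficients) and `random_intercepts`.
#' @export
simulate_tracks <- function(env, water, weather, config) {
  stopifnot(inherits(config, "sim_config"), inherits(env, "env_grid"))
  times <- fix_times(config)
  k <- length(times)
  extent <- min(env$extent_m)
  diag_m <- sqrt(sum(env$extent_m^2))
  if (!(min(weather$timestamp) <= times[1] && max(weather$timestamp) >= times[k]))
    stop("weather series does not cover the simulation window")

  # Per-fix covariates shared by all individuals.
  idx <- as.integer(round((as.numeric(times) - as.numeric(weather$timestamp[1])) / 3600)) + 1L
  if (any(idx < 2 | idx > nrow(weather)))
    idx <- pmin(pmax(idx, 2L), nrow(weather))
  temp2h <- (weather$temp_c[idx] + weather$temp_c[idx - 1L]) / 2
  mo <- config$month_offsets[format(times, "%b", tz = TORTMOVE_TZ)]
  td <- config$tod_offsets[format(times, "%H", tz = TORTMOVE_TZ)]
  if (anyNA(td))  # off-even-hour schedules fall back to the nearest bin
    td[is.na(td)] <- 0
  dist_water_fun <- make_water_dist(water)

  with_seed(config$seed + 3L, {
    out <- vector("list", config$n_individuals)
    b_all <- stats::rnorm(config$n_individuals, 0, config$indiv_sd)
    names(b_all) <- sprintf("LPD%03d", seq_len(config$n_individuals))
    for (i in seq_len(config$n_individuals)) {
      id <- sprintf("LPD%03d", i)
      sex <- if (i %% 2 == 1) "Female" else "Male"
      mass <- round(stats::runif(1, 7400, 26300))
      x <- numeric(k); y <- numeric(k); st <- rep(NA_real_, k)
      x[1] <- stats::runif(1, 0.25, 0.75) * extent
      y[1] <- stats::runif(1, 0.25, 0.75) * extent
      heading <- stats::runif(1, 0, 2 * pi)
      turns <- stats::rnorm(k, 0, config$turn_sd)
      eps <- stats::rnorm(k, 0, config$resid_sd)
      for (j in 2:k) {
        dw <- dist_water_fun(x[j - 1], y[j - 1])
        mu <- config$beta0 + config$beta_temp * temp2h[j] +
          config$beta_water * dw + mo[j] + td[j] + b_all[i]
        step <- 10^(mu + eps[j])
        if (step > diag_m)
          stop("movement coefficients produce steps beyond the grid diameter")
        heading <- heading + turns[j]
        xn <- x[j - 1] + step * cos(heading)
        yn <- y[j - 1] + step * sin(heading)
        # reflecting walls
        while (xn < 0 || xn > env$extent_m[1])
          xn <- if (xn < 0) -xn else 2 * env$extent_m[1] - xn
        while (yn < 0 || yn > env$extent_m[2])
          yn <- if (yn < 0) -yn else 2 * env$extent_m[2] - yn
        x[j] <- xn; y[j] <- yn
        st[j] <- step
      }
      out[[i]] <- data.frame(individual = id, sex = sex, body_mass_g = mass,
                             timestamp = times, x = x, y = y, step_true_m = st)
    }
    tracks <- do.call(rbind, out)
    rownames(tracks) <- NULL
    attr(tracks, "coefficients") <- list(
      beta0 = config$beta0, beta_temp = config$beta_temp,
      beta_water = config$beta_water,
      month_offsets = config$month_offsets, tod_offsets = config$tod_offsets,
      indiv_sd = config$indiv_sd, resid_sd = config$resid_sd)
    attr(tracks, "random_intercepts") <- b_all
    class(tracks) <- c("true_tracks", "data.frame")
    tracks
  })
}

#' Corrupt true tracks into observed GPS fixes with labelled artifacts
#'
#' Every fix is displaced by an error vector with uniform direction and
#' log-normal length (`error_scale * 10^N(error_log10_mean, error_log10_sd)`;
#' defaults give mean length about 17 m). Clean nuisance fields are bounded:
#' HDOP in \[0.8, 5\], clock jitter in \[0, 30\] s, altitude noise in
#' \[-15, 15\] m, so that none of them can trip a screening rule. Artifacts
#' are then planted per configured rates, at most one rule per fix:
#' HDOP spikes (100-200), clock offsets (1,200-3,600 s after the intended
#' fix), altitude errors (1,000-1,500 m), teleport displacements to the grid
#' corner farthest from the true position (at least half the grid diagonal
#' away), and incomplete records (negative activity count).
#'
#' @param tracks output of [simulate_tracks()].
#' @param env the `env_grid` (supplies the DEM for plausible altitudes).
#' @param config a [sim_config()].
#' @return list with `fixes` (data.frame: `individual`, `timestamp`,
#'   `intended_timestamp`, `x`, `y`, `altitude`, `hdop`, `activity`, `sex`,
#'   `body_mass_g`) and `labels` (data.frame: `fix_index` row number in
#'   `fixes`, `rule`).
#' @export
corrupt_fixes <- function(tracks, env, config) {
  stopifnot(inherits(config, "sim_config"), inherits(env, "env_grid"))
  n <- nrow(tracks)
  es <- config$error_scale
  with_seed(config$seed + 4L, {
    len <- es * 10^stats::rnorm(n, config$error_log10_mean, config$error_log10_sd)
    theta <- stats::runif(n, 0, 2 * pi)
    x_obs <- tracks$x + len * cos(theta)
    y_obs <- tracks$y + len * sin(theta)
    alt <- dem_at(env, tracks$x, tracks$y) + es * stats::runif(n, -15, 15)
    hdop <- stats::runif(n, 0.8, 5)
    activity <- stats::rpois(n, 50)
    ts <- tracks$timestamp + es * stats::runif(n, 0, 30)

    rates <- config$artifact_rates
    u <- stats::runif(n)
    rule_idx <- findInterval(u, cumsum(c(0, rates)), left.open = TRUE)
    rule_idx[u >= sum(rates)] <- 0L   # clean
    rules <- names(rates)

    for (r in seq_along(rules)) {
      ii <- which(rule_idx == r)
      if (!length(ii)) next
      switch(rules[r],
        hdop = { hdop[ii] <- stats::runif(length(ii), 100, 200) },
        time_offset = {
          ts[ii] <- tracks$timestamp[ii] + stats::runif(length(ii), 1200, 3600)
        },
        z_error = {
          alt[ii] <- alt[ii] + sample(c(-1, 1), length(ii), TRUE) *
            stats::runif(length(ii), 1000, 1500)
        },
        impossible_move = {
          ex <- env$extent_m[1]; ey <- env$extent_m[2]
          cx <- ifelse(tracks$x[ii] < ex / 2, ex, 0)
          cy <- ifelse(tracks$y[ii] < ey / 2, ey, 0)
          inset_x <- stats::runif(length(ii), 10, 60)
          inset_y <- stats::runif(length(ii), 10, 60)
          x_obs[ii] <- abs(cx - inset_x)
          y_obs[ii] <- abs(cy - inset_y)
        },
        incomplete = { activity[ii] <- -1L }
      )
    }

    fixes <- data.frame(
      individual = tracks$individual, timestamp = ts,
      intended_timestamp = tracks$timestamp,
      x = x_obs, y = y_obs, altitude = alt, hdop = hdop,
      activity = activity, sex = tracks$sex,
      body_mass_g = tracks$body_mass_g)
    lab_ii <- which(rule_idx > 0L)
    labels <- data.frame(fix_index = lab_ii,
                         rule = rules[rule_idx[lab_ii]])
    list(fixes = fixes, labels = labels)
  })
}

#' Generate calibration fixes around a known transmitter location
#'
#' Scatters `n` fixes around a known point using the configured GPS error
#' distribution (uniform direction, log-normal length), emulating a
#' pre-deployment stationary test.
#'
#' @param known_point numeric length-2 `c(x, y)` in metres.
#' @param n number of calibration fixes (>= 2).
#' @param config a [sim_config()].
#' @return data.frame with columns `x_obs`, `y_obs`, `x_true`, `y_true`.
#' @export
generate_calibration <- function(known_point, n, config) {
  stopifnot(inherits(config, "sim_config"), length(known_point) == 2)
  if (n < 2) stop("at least 2 calibration fixes are required")
  with_seed(config$seed + 5L, {
    len <- config$error_scale *
      10^stats::rnorm(n, config$error_log10_mean, config$error_log10_sd)
    theta <- stats::runif(n, 0, 2 * pi)
    data.frame(x_obs = known_point[1] + len * cos(theta),
               y_obs = known_point[2] + len * sin(theta),
               x_true = known_point[1], y_true = known_point[2])
  })
}
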