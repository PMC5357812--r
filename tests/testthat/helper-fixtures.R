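# Shared in-code fixtures: hand-built grids with known geometry and small
# simulation configs sized for fast tests.

# Flat-DEM environment with a single habitat class; exact geometry known.
flat_env <- function(n_col = 40, n_row = 40, pixel = 3, dem_value = 350,
                     class_name = "Low shrubland") {
  habitat <- matrix(1L, n_row, n_col)
  attr(habitat, "classes") <- class_name
  structure(list(origin = c(0, 0), pixel_m = pixel,
                 n_row = n_row, n_col = n_col,
                 extent_m = c(n_col * pixel, n_row * pixel),
                 habitat = habitat,
                 dem = matrix(dem_value, n_row, n_col)),
            class = "env_grid")
}

# Environment with explicit class codes per cell (matrix of class names).
class_env <- function(class_mat, pixel = 3) {
  classes <- unique(as.vector(class_mat))
  habitat <- matrix(match(class_mat, classes), nrow(class_mat), ncol(class_mat))
  attr(habitat, "classes") <- classes
  structure(list(origin = c(0, 0), pixel_m = pixel,
                 n_row = nrow(class_mat), n_col = ncol(class_mat),
                 extent_m = c(ncol(class_mat), nrow(class_mat)) * pixel,
                 habitat = habitat,
                 dem = matrix(350, nrow(class_mat), ncol(class_mat))),
            class = "env_grid")
}

# Minimal fix table builder (flat DEM assumed at 350 m).
make_fixes <- function(n, individual = "LPD001", t0 = "2015-01-01 00:00:00",
                       x = 50, y = 50, altitude = 350, hdop = 2,
                       activity = 10, offset_s = 0, sex = "Female",
                       body_mass_g = 12000) {
  intended <- as.POSIXct(t0, tz = "Etc/GMT-2") + (seq_len(n) - 1) * 7200
  data.frame(individual = rep_len(individual, n),
             timestamp = intended + offset_s,
             intended_timestamp = intended,
             x = rep_len(x, n), y = rep_len(y, n),
             altitude = rep_len(altitude, n), hdop = rep_len(hdop, n),
             activity = rep_len(activity, n), sex = rep_len(sex, n),
             body_mass_g = rep_len(body_mass_g, n))
}

# Small simulation config for fast generator tests.
small_sim <- function(seed = 11, ...) {
  args <- list(n_individuals = 2, start = "2015-01-01", end = "2015-01-31",
               pixel_m = 10, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Constant hourly weather covering a window.
const_weather <- function(start = "2015-01-01", end = "2015-01-31",
                          temp = 20, rain = 0) {
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "Etc/GMT-2"),
            as.POSIXct(paste(end, "23:00:00"), tz = "Etc/GMT-2"), by = 3600)
  structure(data.frame(timestamp = ts, temp_c = temp, rain_mm = rain),
            class = c("weather_series", "data.frame"))
}

# Independent brute-force oracle for the rank-quantile step correction:
# explicit counting ranks and explicit piecewise-linear interpolation
# between sorted log10 errors at Hazen positions, per step.
oracle_correct <- function(d, errors) {
  n <- length(d)
  le <- sort(log10(errors))
  m <- length(le)
  pe <- (seq_len(m) - 0.5) / m
  vapply(seq_len(n), function(i) {
    rnk <- sum(d < d[i]) + (sum(d == d[i]) + 1) / 2
    p <- (rnk - 0.5) / n
    if (p <= pe[1]) q <- le[1]
    else if (p >= pe[m]) q <- le[m]
    else {
      j <- max(which(pe <= p))
      q <- le[j] + (le[j + 1] - le[j]) * (p - pe[j]) / (pe[j + 1] - pe[j])
    }
    max(0, d[i] - 10^q)
  }, numeric(1))
}

# Directly simulated random-intercept Gaussian data for modeling tests.
sim_lmm_data <- function(n_per_group = 50, n_groups = 10,
                         beta = c(intercept = 1, x = 0.5, z = -0.3),
                         tau = 0.2, sigma = 0.4, seed = 1) {
  set.seed(seed)
  g <- rep(sprintf("G%02d", seq_len(n_groups)), each = n_per_group)
  n <- length(g)
  x <- rnorm(n); z <- rnorm(n)
  b <- rnorm(n_groups, 0, tau)[as.integer(factor(g))]
  y <- beta["intercept"] + beta["x"] * x + beta["z"] * z + b +
    rnorm(n, 0, sigma)
  data.frame(log_d = y, x = x, z = z, individual = g)
}
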