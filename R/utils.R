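# Internal helpers shared across modules.

# Local timezone of the study region (UTC+2; POSIX "Etc" zones invert the sign).
TORTMOVE_TZ <- "Etc/GMT-2"

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are deterministic without
#' disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Standard error of the mean; NA for n < 2.
se_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Euclidean distance between paired points.
euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

# Squared distances from each query point to each reference point, chunked to
# bound memory; returns the per-query minimum distance.
min_dist_to_points <- function(px, py, qx, qy, chunk = 500L) {
  n <- length(px)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    dx <- outer(px[i0:i1], qx, "-")
    dy <- outer(py[i0:i1], qy, "-")
    out[i0:i1] <- sqrt(apply(dx * dx + dy * dy, 1L, min))
  }
  out
}

# Bilinear upsampling of a coarse matrix to n_row x n_col (used for smooth
# random fields: habitat mosaic and DEM).
upsample_bilinear <- function(m, n_row, n_col) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq(1, nr, length.out = n_row)
  ci <- seq(1, nc, length.out = n_col)
  r0 <- pmin(floor(ri), nr - 1L); r1 <- r0 + 1L; fr <- ri - r0
  c0 <- pmin(floor(ci), nc - 1L); c1 <- c0 + 1L; fc <- ci - c0
  a <- m[r0, c0]; b <- m[r1, c0]; cc <- m[r0, c1]; d <- m[r1, c1]
  fr_m <- matrix(fr, n_row, n_col)
  fc_m <- matrix(fc, n_row, n_col, byrow = TRUE)
  a * (1 - fr_m) * (1 - fc_m) + b * fr_m * (1 - fc_m) +
    cc * (1 - fr_m) * fc_m + d * fr_m * fc_m
}

# Format POSIXct as ISO-8601 with explicit UTC offset; parse the same.
format_iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%S%z", tz = TORTMOVE_TZ)
parse_iso8601 <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S%z", tz = TORTMOVE_TZ)

`%||%` <- function(a, b) if (is.null(a)) b else a
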