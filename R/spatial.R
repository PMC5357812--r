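# Habitat extraction, resource regrouping, and Euclidean distances to water
# and resource features. All coordinates are planar projected metres; grid
# cells are half-open [x0 + i*s, x0 + (i+1)*s) in both axes, so a point on a
# cell boundary belongs to the higher cell.

as_xy <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) >= 2)
    list(x = points[, 1], y = points[, 2])
  } else if (is.data.frame(points)) {
    stopifnot(all(c("x", "y") %in% names(points)))
    list(x = points$x, y = points$y)
  } else stop("points must be a matrix or data.frame with x and y")
}

# 1-based (col, row) cell indices; NA outside the grid.
cell_index <- function(env, x, y) {
  ix <- floor((x - env$origin[1]) / env$pixel_m) + 1
  iy <- floor((y - env$origin[2]) / env$pixel_m) + 1
  bad <- ix < 1 | ix > env$n_col | iy < 1 | iy > env$n_row |
    !is.finite(x) | !is.finite(y)
  ix[bad] <- NA_integer_; iy[bad] <- NA_integer_
  list(col = as.integer(ix), row = as.integer(iy))
}

#' Elevation of the DEM cell containing each point
#'
#' @param env an `env_grid`.
#' @param x,y point coordinates in metres.
#' @return numeric vector of elevations; NA for points outside the grid.
#' @export
dem_at <- function(env, x, y) {
  ci <- cell_index(env, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(ci$col)
  out[ok] <- env$dem[cbind(ci$row[ok], ci$col[ok])]
  out
}

#' Habitat class of the raster cell containing each point
#'
#' Cells are half-open, so a point exactly on a cell boundary belongs to the
#' higher-indexed cell. Points outside the grid return NA (an explicit
#' out-of-grid marker, counted by downstream stages).
#'
#' @param points matrix or data.frame with columns `x`, `y` (metres).
#' @param env an `env_grid`.
#' @return character vector of habitat class names, NA out of grid.
#' @export
habitat_at <- function(points, env) {
  p <- as_xy(points)
  ci <- cell_index(env, p$x, p$y)
  classes <- attr(env$habitat, "classes")
  out <- rep(NA_character_, length(p$x))
  ok <- !is.na(ci$col)
  out[ok] <- classes[env$habitat[cbind(ci$row[ok], ci$col[ok])]]
  out
}

#' Convert a habitat raster to one point per pixel centre
#'
#' Mirrors the workflow of converting a land-cover raster to a point layer:
#' each pixel is represented by its centre, carrying the pixel's class.
#'
#' @param env an `env_grid`.
#' @return data.frame with `x`, `y` (pixel centres, metres) and `habitat`.
#' @export
grid_to_points <- function(env) {
  if (env$n_row < 1 || env$n_col < 1) stop("empty grid")
  xc <- env$origin[1] + (seq_len(env$n_col) - 0.5) * env$pixel_m
  yc <- env$origin[2] + (seq_len(env$n_row) - 0.5) * env$pixel_m
  classes <- attr(env$habitat, "classes")
  data.frame(x = rep(xc, each = env$n_row),
             y = rep(yc, times = env$n_col),
             habitat = classes[as.vector(env$habitat)])
}

#' Resource category of each habitat class
#'
#' Total mapping from habitat classes to the resource categories
#' `water`, `food`, `none`, based on expected access to increased food
#' resources and to water: water classes map to water; wetlands, bush,
#' grassland and cultivated fields to food; low shrubland and non-vegetated
#' land to none.
#'
#' @param classes character vector of habitat class names.
#' @return factor with levels `water`, `food`, `none`.
#' @export
resource_category <- function(classes) {
  map <- c("Water seasonal" = "water", "Water permanent" = "water",
           "Wetlands" = "food", "Dense bush" = "food", "Open bush" = "food",
           "Grassland" = "food", "Low shrubland" = "none",
           "Cultivated commercial fields" = "food", "Non-vegetated" = "none")
  unknown <- setdiff(unique(classes[!is.na(classes)]), names(map))
  if (length(unknown))
    stop("no resource category for habitat class: ",
         paste(unknown, collapse = ", "))
  factor(unname(map[classes]), levels = c("water", "food", "none"))
}

# Minimum distance from each point to a set of polygon boundary segments.
dist_to_rings <- function(x, y, rings) {
  sx1 <- sy1 <- sx2 <- sy2 <- numeric(0)
  for (ring in rings) {
    m <- nrow(ring)
    sx1 <- c(sx1, ring[-m, 1]); sy1 <- c(sy1, ring[-m, 2])
    sx2 <- c(sx2, ring[-1, 1]); sy2 <- c(sy2, ring[-1, 2])
  }
  best <- rep(Inf, length(x))
  for (s in seq_along(sx1)) {
    ex <- sx2[s] - sx1[s]; ey <- sy2[s] - sy1[s]
    el2 <- ex^2 + ey^2
    t <- if (el2 > 0) pmin(1, pmax(0, ((x - sx1[s]) * ex + (y - sy1[s]) * ey) / el2)) else 0
    d2 <- (sx1[s] + t * ex - x)^2 + (sy1[s] + t * ey - y)^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Minimum Euclidean distance from points to a feature layer
#'
#' For a `water_features` layer the distance is the minimum over manmade
#' water-source points and inland water polygons; the distance to a polygon is
#' zero for interior points and otherwise the distance to its boundary. A
#' plain matrix or data.frame of points (e.g. food-pixel centres) is treated
#' as a point set.
#'
#' @param points matrix or data.frame with `x`, `y`.
#' @param features a `water_features` object, or a matrix/data.frame of
#'   feature points.
#' @return numeric vector of distances in metres.
#' @export
distance_to_features <- function(points, features) {
  p <- as_xy(points)
  if (inherits(features, "water_features")) {
    n_feat <- nrow(features$points) + length(features$polygons)
    if (n_feat == 0)
      stop("empty feature layer: no water features to measure distance to")
    best <- rep(Inf, length(p$x))
    if (nrow(features$points) > 0)
      best <- pmin(best, min_dist_to_points(p$x, p$y,
                                            features$points[, 1],
                                            features$points[, 2]))
    if (length(features$polygons) > 0) {
      d <- dist_to_rings(p$x, p$y, features$polygons)
      inside <- rep(FALSE, length(p$x))
      for (ring in features$polygons) {
        inside <- inside | as.logical(
          pracma::inpolygon(p$x, p$y, ring[, 1], ring[, 2], boundary = TRUE))
      }
      d[inside] <- 0
      best <- pmin(best, d)
    }
    best
  } else {
    f <- as_xy(features)
    if (!length(f$x))
      stop("empty feature layer: no feature points supplied")
    min_dist_to_points(p$x, p$y, f$x, f$y)
  }
}

#' Distance from points to the nearest pixel centre of given habitat classes
#'
#' Reproduces the raster-to-point workflow: the distance to a habitat
#' category is the distance to the nearest pixel centre of any pixel in that
#' category. Exact brute force is used when the problem is small; for large
#' grids a Euclidean distance transform (EBImage, if installed) evaluated at
#' the containing pixel is used, which is accurate to within half a pixel
#' diagonal.
#'
#' @param points matrix or data.frame with `x`, `y`.
#' @param env an `env_grid`.
#' @param classes habitat class names defining the target set.
#' @param method `"auto"`, `"exact"` or `"distmap"`.
#' @return numeric vector of distances in metres.
#' @export
distance_to_class <- function(points, env, classes,
                              method = c("auto", "exact", "distmap")) {
  method <- match.arg(method)
  p <- as_xy(points)
  all_classes <- attr(env$habitat, "classes")
  codes <- match(classes, all_classes)
  if (anyNA(codes)) stop("unknown habitat class: ",
                         paste(classes[is.na(codes)], collapse = ", "))
  mask <- matrix(env$habitat %in% codes, env$n_row, env$n_col)
  n_target <- sum(mask)
  if (n_target == 0)
    stop("no pixels of the requested class in the grid")
  if (method == "auto") {
    method <- if (as.double(n_target) * length(p$x) <= 5e7 ||
                  !requireNamespace("EBImage", quietly = TRUE))
      "exact" else "distmap"
  }
  if (method == "exact") {
    idx <- which(mask, arr.ind = TRUE)
    qx <- env$origin[1] + (idx[, 2] - 0.5) * env$pixel_m
    qy <- env$origin[2] + (idx[, 1] - 0.5) * env$pixel_m
    min_dist_to_points(p$x, p$y, qx, qy)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("method 'distmap' requires the EBImage package")
    dm <- EBImage::distmap(matrix(as.numeric(!mask), env$n_row, env$n_col))
    dm <- dm * env$pixel_m
    ci <- cell_index(env, p$x, p$y)
    out <- rep(NA_real_, length(p$x))
    ok <- !is.na(ci$col)
    out[ok] <- dm[cbind(ci$row[ok], ci$col[ok])]
    out
  }
}

#' Proximity flags at a radius
#'
#' Inclusive at the boundary: a distance of exactly `radius` counts as
#' within, matching the convention that "away" is strictly greater than the
#' radius.
#'
#' @param dist numeric distances in metres.
#' @param radius metres (default 250).
#' @return logical vector.
#' @export
proximity_flags <- function(dist, radius = 250) {
  dist <= radius
}

#' Annotate fixes with habitat, resource category and feature distances
#'
#' Adds, per fix: habitat class of the containing pixel (NA out of grid,
#' counted in the `n_out_of_grid` attribute), resource category, distance to
#' water features, distance to the nearest food-category pixel centre,
#' distance to the nearest cultivated-field pixel centre (NA when the grid
#' has none), and inclusive 250 m proximity flags for each group.
#'
#' @param fixes data.frame with at least `x`, `y`.
#' @param env an `env_grid`.
#' @param water a `water_features` layer.
#' @param radius proximity radius in metres.
#' @return `fixes` with annotation columns appended.
#' @export
annotate_fixes <- function(fixes, env, water, radius = 250) {
  hab <- habitat_at(fixes, env)
  res <- resource_category(hab)
  dw <- distance_to_features(fixes, water)
  food_classes <- HABITAT_CLASSES[resource_category(HABITAT_CLASSES) == "food"]
  food_present <- intersect(food_classes, attr(env$habitat, "classes"))
  df <- if (length(food_present) &&
            any(env$habitat %in% match(food_present, attr(env$habitat, "classes"))))
    distance_to_class(fixes, env, food_present) else rep(NA_real_, nrow(fixes))
  cult <- "Cultivated commercial fields"
  dc <- if (cult %in% attr(env$habitat, "classes") &&
            any(env$habitat == match(cult, attr(env$habitat, "classes"))))
    distance_to_class(fixes, env, cult) else rep(NA_real_, nrow(fixes))
  out <- fixes
  out$habitat <- hab
  out$resource <- res
  out$dist_water_m <- dw
  out$dist_food_m <- df
  out$dist_cultivation_m <- dc
  out$within_water <- proximity_flags(dw, radius)
  out$within_food <- proximity_flags(df, radius)
  out$within_cultivation <- proximity_flags(dc, radius)
  attr(out, "n_out_of_grid") <- sum(is.na(hab))
  out
}
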