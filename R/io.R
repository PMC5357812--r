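# Plain-text interchange: fix tables and weather as CSV (ISO-8601 timestamps
# with explicit UTC offset), habitat/DEM as Esri ASCII grids with a JSON
# class legend, water features as GeoJSON, ground truth as JSON.

#' Read and write fix tables
#'
#' CSV with header `individual,timestamp,intended_timestamp,x,y,altitude,
#' hdop,activity,sex,body_mass_g`; timestamps ISO-8601 with explicit UTC
#' offset.
#'
#' @param fixes fix data.frame.
#' @param path file path.
#' @return `read_fixes` returns the fix data.frame with POSIXct timestamps.
#' @export
write_fixes <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format_iso8601(out$timestamp)
  out$intended_timestamp <- format_iso8601(out$intended_timestamp)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fixes
#' @export
read_fixes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- parse_iso8601(x$timestamp)
  x$intended_timestamp <- parse_iso8601(x$intended_timestamp)
  x
}

#' Read and write hourly weather series
#'
#' CSV with header `timestamp,temp_c,rain_mm`.
#' @param weather a `weather_series` data.frame.
#' @param path file path.
#' @return `read_weather` returns the `weather_series`.
#' @export
write_weather <- function(weather, path) {
  out <- data.frame(timestamp = format_iso8601(weather$timestamp),
                    temp_c = weather$temp_c, rain_mm = weather$rain_mm)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather
#' @export
read_weather <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- parse_iso8601(x$timestamp)
  class(x) <- c("weather_series", "data.frame")
  x
}

#' Write a matrix as an Esri ASCII grid
#'
#' Standard `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header
#' followed by rows written north to south (the matrix is stored south-up:
#' row 1 is the southernmost row).
#'
#' @param mat numeric matrix (row 1 = southernmost row).
#' @param path file path.
#' @param origin `c(x, y)` of the lower-left corner, metres.
#' @param cellsize pixel size, metres.
#' @param nodata NODATA sentinel.
#' @return `read_ascii_grid` returns a list with `mat`, `origin`,
#'   `cellsize`, `nodata`.
#' @export
write_ascii_grid <- function(mat, path, origin = c(0, 0), cellsize = 1,
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(mat)), paste("nrows", nrow(mat)),
               paste("xllcorner", origin[1]), paste("yllcorner", origin[2]),
               paste("cellsize", cellsize), paste("NODATA_value", nodata)),
             con)
  m <- mat
  m[is.na(m)] <- nodata
  for (i in rev(seq_len(nrow(m))))   # north to south
    writeLines(paste(m[i, ], collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]   # back to south-up
  nodata <- hdr[["nodata_value"]] %||% -9999
  m[m == nodata] <- NA
  list(mat = m, origin = c(hdr$xllcorner, hdr$yllcorner),
       cellsize = hdr$cellsize, nodata = nodata)
}

#' Persist and restore an environment grid (habitat + DEM)
#'
#' Writes `habitat.asc`, `dem.asc` and `habitat_legend.json` (integer code to
#' class name) into a directory.
#'
#' @param env an `env_grid`.
#' @param dir directory path (created if needed).
#' @return `read_env` returns the restored `env_grid`.
#' @export
write_env <- function(env, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ascii_grid(env$habitat, file.path(dir, "habitat.asc"),
                   origin = env$origin, cellsize = env$pixel_m)
  write_ascii_grid(env$dem, file.path(dir, "dem.asc"),
                   origin = env$origin, cellsize = env$pixel_m)
  jsonlite::write_json(as.list(stats::setNames(
    attr(env$habitat, "classes"),
    seq_along(attr(env$habitat, "classes")))),
    file.path(dir, "habitat_legend.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_env
#' @export
read_env <- function(dir) {
  hab <- read_ascii_grid(file.path(dir, "habitat.asc"))
  dem <- read_ascii_grid(file.path(dir, "dem.asc"))
  legend <- jsonlite::read_json(file.path(dir, "habitat_legend.json"),
                                simplifyVector = TRUE)
  habitat <- matrix(as.integer(hab$mat), nrow(hab$mat), ncol(hab$mat))
  attr(habitat, "classes") <- unname(unlist(legend))
  structure(list(origin = hab$origin, pixel_m = hab$cellsize,
                 n_row = nrow(habitat), n_col = ncol(habitat),
                 extent_m = c(ncol(habitat), nrow(habitat)) * hab$cellsize,
                 habitat = habitat, dem = dem$mat),
            class = "env_grid")
}

#' Read and write water features as GeoJSON
#'
#' A FeatureCollection of Point features (`kind: manmade`) and Polygon
#' features (`kind: inland`), coordinates in projected metres.
#'
#' @param water a `water_features` object.
#' @param path file path.
#' @return `read_water_geojson` returns the `water_features`.
#' @export
write_water_geojson <- function(water, path) {
  feats <- list()
  for (i in seq_len(nrow(water$points))) {
    feats[[length(feats) + 1]] <- list(
      type = "Feature", properties = list(kind = "manmade"),
      geometry = list(type = "Point",
                      coordinates = as.numeric(water$points[i, ])))
  }
  for (ring in water$polygons) {
    coords <- lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ]))
    feats[[length(feats) + 1]] <- list(
      type = "Feature", properties = list(kind = "inland"),
      geometry = list(type = "Polygon", coordinates = list(coords)))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_water_geojson
#' @export
read_water_geojson <- function(path) {
  x <- jsonlite::read_json(path)
  pts <- list(); polys <- list()
  for (f in x$features) {
    g <- f$geometry
    if (g$type == "Point") {
      pts[[length(pts) + 1]] <- unlist(g$coordinates)
    } else if (g$type == "Polygon") {
      ring <- do.call(rbind, lapply(g$coordinates[[1]], unlist))
      colnames(ring) <- c("x", "y")
      polys[[length(polys) + 1]] <- ring
    }
  }
  pmat <- if (length(pts)) do.call(rbind, pts) else
    matrix(numeric(0), 0, 2)
  colnames(pmat) <- c("x", "y")
  structure(list(points = pmat, polygons = polys), class = "water_features")
}

#' Persist and restore the simulation ground truth
#'
#' JSON sidecar with the true movement coefficients, per-individual random
#' intercepts and planted artifact labels.
#'
#' @param tracks a `true_tracks` data.frame.
#' @param labels artifact label data.frame from [corrupt_fixes()].
#' @param path file path.
#' @return `read_truth` returns a list with `coefficients`,
#'   `random_intercepts`, `labels`.
#' @export
write_truth <- function(tracks, labels, path) {
  jsonlite::write_json(list(
    coefficients = attr(tracks, "coefficients"),
    random_intercepts = as.list(attr(tracks, "random_intercepts")),
    labels = labels), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$random_intercepts <- unlist(x$random_intercepts)
  x
}

#' Write a corrected step table
#'
#' CSV with header `individual,t_start,t_end,dt_h,d_est_m,p,d_corr_m`.
#' @param steps corrected steps.
#' @param path file path.
#' @export
write_steps <- function(steps, path) {
  out <- data.frame(individual = steps$individual,
                    t_start = format_iso8601(steps$t_start),
                    t_end = format_iso8601(steps$t_end),
                    dt_h = steps$dt_h, d_est_m = steps$d_est_m,
                    p = steps$p %||% NA, d_corr_m = steps$d_corr_m %||% NA)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
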