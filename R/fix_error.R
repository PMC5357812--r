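# Transmitter fix-error quantification and the empirical log10-scale quantile
# model that supplies the rank-matched deduction for step-length correction.

#' Per-fix Euclidean errors of calibration data
#'
#' Computes the Euclidean distance between each observed calibration fix and
#' the known transmitter location, with summary statistics (mean, SE =
#' sd/sqrt(n), min, max).
#'
#' @param calibration data.frame with columns `x_obs`, `y_obs`, `x_true`,
#'   `y_true` (metres).
#' @return list of class `fix_error_summary`: `errors` (metres, input order),
#'   `n`, `mean`, `se`, `min`, `max`.
#' @export
compute_fix_errors <- function(calibration) {
  need <- c("x_obs", "y_obs", "x_true", "y_true")
  stopifnot(all(need %in% names(calibration)))
  if (nrow(calibration) < 2)
    stop("at least 2 calibration fixes are required")
  err <- euclid(calibration$x_obs, calibration$y_obs,
                calibration$x_true, calibration$y_true)
  structure(list(errors = err, n = length(err), mean = mean(err),
                 se = stats::sd(err) / sqrt(length(err)),
                 min = min(err), max = max(err)),
            class = "fix_error_summary")
}

#' @export
print.fix_error_summary <- function(x, ...) {
  cat(sprintf("Calibration fix error: n = %d, mean %.2f +/- %.2f m (range: %.2f to %.2f m)\n",
              x$n, x$mean, x$se, x$min, x$max))
  invisible(x)
}

#' Build the empirical log10 error-quantile model
#'
#' Sorts the log10-transformed calibration error distances and attaches
#' plotting positions. The quantile function `Q_log10(p)` interpolates
#' linearly between order statistics at Hazen plotting positions
#' `p_i = (i - 0.5)/n` (default), or uses the inverse empirical CDF
#' (`type = "ecdf"`). It is nondecreasing by construction and constant beyond
#' the extreme plotting positions, so `Q_log10(0)` and `Q_log10(1)` return
#' the smallest and largest log10 error.
#'
#' Zero errors (exact hits) are replaced by half the smallest positive error
#' before the log transform, keeping the log defined without discarding
#' calibration mass; a model in which all errors are zero is degenerate and
#' rejected.
#'
#' @param errors numeric vector of error distances in metres (>= 0), or a
#'   `fix_error_summary`.
#' @param type `"hazen"` (default) or `"ecdf"`.
#' @return list of class `error_model`: `log10_errors` (sorted), `pp`
#'   (plotting positions), `n`, `type`, `summary`.
#' @export
build_error_model <- function(errors, type = c("hazen", "ecdf")) {
  type <- match.arg(type)
  if (inherits(errors, "fix_error_summary")) errors <- errors$errors
  errors <- errors[is.finite(errors)]
  if (any(errors < 0)) stop("negative error distances are not allowed")
  if (length(errors) < 2) stop("at least 2 error distances are required")
  if (all(errors == 0))
    stop("degenerate error model: all calibration errors are zero")
  if (any(errors == 0)) {
    half_min_pos <- min(errors[errors > 0]) / 2
    errors[errors == 0] <- half_min_pos
  }
  le <- sort(log10(errors))
  n <- length(le)
  structure(list(log10_errors = le, pp = (seq_len(n) - 0.5) / n, n = n,
                 type = type,
                 summary = c(mean = mean(10^le), min = 10^le[1], max = 10^le[n])),
            class = "error_model")
}

#' Evaluate the log10 error-quantile function
#'
#' @param model an [build_error_model()] object.
#' @param p probabilities in \[0, 1\].
#' @return `Q_log10(p)`, the log10 error quantile at each `p`.
#' @export
quantile_log10 <- function(model, p) {
  stopifnot(inherits(model, "error_model"))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  if (model$type == "hazen") {
    if (model$n == 1 || all(model$log10_errors == model$log10_errors[1]))
      return(rep(model$log10_errors[1], length(p)))
    stats::approx(model$pp, model$log10_errors, xout = p, rule = 2,
                  ties = "ordered")$y
  } else {
    # inverse ECDF: Q(p) = smallest order statistic with i/n >= p
    idx <- pmax(1L, ceiling(p * model$n))
    model$log10_errors[idx]
  }
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("Empirical log10 error-quantile model (%s): n = %d, median %.2f m, range %.2f-%.2f m\n",
              x$type, x$n, 10^quantile_log10(x, 0.5), x$summary["min"],
              x$summary["max"]))
  invisible(x)
}

#' Serialize / restore an error model as JSON
#'
#' @param model an `error_model`.
#' @param path file path.
#' @return `read_error_model` returns the restored `error_model`.
#' @export
write_error_model <- function(model, path) {
  stopifnot(inherits(model, "error_model"))
  jsonlite::write_json(
    list(log10_errors = model$log10_errors, pp = model$pp, n = model$n,
         type = model$type, summary = as.list(model$summary)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_error_model
#' @export
read_error_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(log10_errors = as.numeric(x$log10_errors),
                 pp = as.numeric(x$pp), n = as.integer(x$n), type = x$type,
                 summary = unlist(x$summary)),
            class = "error_model")
}
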