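# Step distances between successive retained fixes and the rank-quantile
# error-deduction correction: each step's raw distance is reduced by the
# calibration-error quantile matched to the step's rank percentile, on a
# log10 scale, flooring negative results at zero.

#' Compute movement steps from screened fixes
#'
#' One step per successive pair of fixes of the same individual, never
#' spanning individuals. An individual with a single fix yields no steps.
#'
#' @param fixes screened fixes (`individual`, `timestamp`, `x`, `y`).
#' @return data.frame of class `move_steps`: `individual`, `t_start`,
#'   `t_end`, `dt_h`, `d_est_m`, `x_start`, `y_start`, `x_end`, `y_end`.
#' @export
compute_steps <- function(fixes) {
  stopifnot(all(c("individual", "timestamp", "x", "y") %in% names(fixes)))
  ord <- order(fixes$individual, fixes$timestamp)
  f <- fixes[ord, , drop = FALSE]
  n <- nrow(f)
  if (n < 2) {
    out <- data.frame(individual = character(0), t_start = f$timestamp[0],
                      t_end = f$timestamp[0], dt_h = numeric(0),
                      d_est_m = numeric(0), x_start = numeric(0),
                      y_start = numeric(0), x_end = numeric(0),
                      y_end = numeric(0))
    class(out) <- c("move_steps", "data.frame")
    return(out)
  }
  same <- f$individual[-1] == f$individual[-n]
  i0 <- which(same)        # index of step start
  out <- data.frame(
    individual = f$individual[i0],
    t_start = f$timestamp[i0], t_end = f$timestamp[i0 + 1],
    dt_h = as.numeric(difftime(f$timestamp[i0 + 1], f$timestamp[i0],
                               units = "hours")),
    d_est_m = euclid(f$x[i0], f$y[i0], f$x[i0 + 1], f$y[i0 + 1]),
    x_start = f$x[i0], y_start = f$y[i0],
    x_end = f$x[i0 + 1], y_end = f$y[i0 + 1])
  rownames(out) <- NULL
  class(out) <- c("move_steps", "data.frame")
  out
}

#' Assign rank percentiles to step distances
#'
#' Larger steps are assumed to carry larger fix errors, so each step is
#' assigned the percentile of its distance rank: `p = (rank - 0.5) / N` with
#' ascending ranks and ties averaged. Ranking is pooled over the whole step
#' set by default; `scope = "individual"` ranks within each individual.
#'
#' @param steps a `move_steps` data.frame.
#' @param scope `"pooled"` (default) or `"individual"`.
#' @return `steps` with a percentile column `p` added.
#' @export
assign_rank_percentiles <- function(steps, scope = c("pooled", "individual")) {
  scope <- match.arg(scope)
  if (nrow(steps) == 0) { steps$p <- numeric(0); return(steps) }
  hazen <- function(d) (rank(d, ties.method = "average") - 0.5) / length(d)
  steps$p <- if (scope == "pooled") hazen(steps$d_est_m)
  else stats::ave(steps$d_est_m, steps$individual, FUN = hazen)
  steps
}

#' Correct step distances by the rank-matched error quantile
#'
#' Applies `d_corr = max(0, d_est - 10^Q_log10(p))`: the deduction for a step
#' at rank percentile `p` is the back-transformed `p`-quantile of the
#' log10-transformed calibration error distribution. The largest step is
#' corrected by (approximately) the largest calibration error and the
#' smallest by the smallest; negative corrected distances are floored at
#' zero.
#'
#' @param steps a `move_steps` data.frame with percentiles assigned.
#' @param error_model an [build_error_model()] object.
#' @return `steps` with columns `deduction_m` and `d_corr_m` added.
#' @export
correct_distances <- function(steps, error_model) {
  if (missing(error_model) || !inherits(error_model, "error_model"))
    stop("a fitted error_model is required")
  if (is.null(steps$p))
    stop("rank percentiles must be assigned before correction")
  ded <- 10^quantile_log10(error_model, steps$p)
  steps$deduction_m <- ded
  steps$d_corr_m <- pmax(0, steps$d_est_m - ded)
  steps
}
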