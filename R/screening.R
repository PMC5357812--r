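# Multi-rule fix screening. Rules are applied in a fixed, documented order so
# that removal attribution is reproducible; a fix failing several rules is
# counted once, under the first rule that catches it.

SCREEN_RULES <- c("incomplete", "window", "time_offset", "hdop",
                  "out_of_grid", "z_error", "impossible_move")

#' Screening configuration
#'
#' Thresholds for the fix-discard rules. The clock-offset (120 s) and
#' z-coordinate (100 m) cut-offs follow standard telemetry practice for this
#' transmitter class; "extreme HDOP" and "improbable movement distance" are
#' not standardized, so conventional defaults are used (HDOP 10; 4,000 m per
#' bihourly interval, comfortably above any plausible tortoise displacement).
#'
#' @param max_hdop maximum acceptable horizontal dilution of precision.
#' @param max_time_offset_s maximum |actual - intended| fix time, seconds.
#' @param max_z_error_m maximum |transmitter altitude - DEM altitude|, metres.
#' @param max_step_m maximum plausible displacement from the previous
#'   retained fix of the same individual, metres.
#' @param deployment optional data.frame (`individual`, `start`, `end`,
#'   POSIXct) giving the valid deployment window per individual; fixes
#'   time-stamped outside it (e.g. wrong time zone) are discarded. When NULL
#'   the rule is skipped.
#' @return list of class `screening_config`.
#' @export
screening_config <- function(max_hdop = 10, max_time_offset_s = 120,
                             max_z_error_m = 100, max_step_m = 4000,
                             deployment = NULL) {
  stopifnot(max_hdop > 0, max_time_offset_s > 0, max_z_error_m > 0,
            max_step_m > 0)
  structure(list(max_hdop = max_hdop, max_time_offset_s = max_time_offset_s,
                 max_z_error_m = max_z_error_m, max_step_m = max_step_m,
                 deployment = deployment),
            class = "screening_config")
}

#' Screen fixes with the multi-rule artifact filters
#'
#' Rules, applied in fixed order per fix (the first triggering rule is
#' attributed):
#' \enumerate{
#'   \item `incomplete`: missing required fields or negative activity count;
#'   \item `window`: timestamp outside the individual's deployment window
#'     (incorrect time zone or transmitter clock failure);
#'   \item `time_offset`: |timestamp - intended timestamp| above threshold;
#'   \item `hdop`: HDOP above threshold;
#'   \item `out_of_grid`: position outside the DEM (altitude unverifiable);
#'   \item `z_error`: |altitude - DEM(x, y)| above threshold;
#'   \item `impossible_move`: displacement from the previous \emph{retained}
#'     fix of the same individual above threshold. Anchoring on the previous
#'     retained fix means a single teleporting fix cannot cascade removals.
#' }
#'
#' @param fixes data.frame with columns `individual`, `timestamp`,
#'   `intended_timestamp`, `x`, `y`, `altitude`, `hdop`, `activity`.
#' @param env an `env_grid` supplying the DEM.
#' @param config a [screening_config()].
#' @return list with `retained` (screened fixes, original order) and
#'   `report` (class `screening_report`): `total`, `removed` named counts per
#'   rule, `retained`, `by_individual` removed counts.
#' @export
screen_fixes <- function(fixes, env, config = screening_config()) {
  stopifnot(inherits(config, "screening_config"))
  n <- nrow(fixes)
  if (n == 0) {
    rep0 <- structure(list(total = 0L,
                           removed = stats::setNames(integer(length(SCREEN_RULES)), SCREEN_RULES),
                           retained = 0L, by_individual = integer(0)),
                      class = "screening_report")
    return(list(retained = fixes, report = rep0))
  }
  reason <- rep(NA_character_, n)

  required <- fixes[, c("individual", "timestamp", "intended_timestamp",
                        "x", "y", "altitude", "hdop", "activity")]
  miss <- Reduce(`|`, lapply(required, is.na))
  bad_act <- !is.na(fixes$activity) & fixes$activity < 0
  reason[miss | bad_act] <- "incomplete"

  if (!is.null(config$deployment)) {
    dep <- config$deployment
    stopifnot(all(c("individual", "start", "end") %in% names(dep)))
    unknown <- setdiff(unique(fixes$individual), dep$individual)
    if (length(unknown))
      stop("individual(s) missing from deployment table: ",
           paste(unknown, collapse = ", "))
    mi <- match(fixes$individual, dep$individual)
    out_win <- !is.na(fixes$timestamp) &
      (fixes$timestamp < dep$start[mi] | fixes$timestamp > dep$end[mi])
    reason[is.na(reason) & out_win] <- "window"
  }

  offs <- abs(as.numeric(difftime(fixes$timestamp, fixes$intended_timestamp,
                                  units = "secs")))
  reason[is.na(reason) & !is.na(offs) & offs > config$max_time_offset_s] <- "time_offset"

  reason[is.na(reason) & !is.na(fixes$hdop) & fixes$hdop > config$max_hdop] <- "hdop"

  dem_z <- dem_at(env, fixes$x, fixes$y)
  reason[is.na(reason) & is.na(dem_z) & !is.na(fixes$x)] <- "out_of_grid"
  zerr <- abs(fixes$altitude - dem_z)
  reason[is.na(reason) & !is.na(zerr) & zerr > config$max_z_error_m] <- "z_error"

  # Speed filter: iterate over each individual's surviving fixes in time
  # order, anchoring on the previous retained fix.
  surv <- which(is.na(reason))
  for (id in unique(fixes$individual[surv])) {
    ii <- surv[fixes$individual[surv] == id]
    ii <- ii[order(fixes$timestamp[ii])]
    if (length(ii) < 2) next
    anchor <- ii[1]
    for (j in ii[-1]) {
      d <- euclid(fixes$x[anchor], fixes$y[anchor], fixes$x[j], fixes$y[j])
      if (d > config$max_step_m) {
        reason[j] <- "impossible_move"
      } else {
        anchor <- j
      }
    }
  }

  removed_tab <- stats::setNames(integer(length(SCREEN_RULES)), SCREEN_RULES)
  tt <- table(reason)
  removed_tab[names(tt)] <- as.integer(tt)
  by_ind <- tapply(!is.na(reason), fixes$individual, sum)
  report <- structure(list(total = n, removed = removed_tab,
                           retained = sum(is.na(reason)),
                           by_individual = by_ind,
                           reasons = reason),
                      class = "screening_report")
  list(retained = fixes[is.na(reason), , drop = FALSE], report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Fix screening: %d in, %d removed, %d retained\n",
              x$total, sum(x$removed), x$retained))
  for (r in names(x$removed))
    cat(sprintf("  rule %-15s removed %d\n", r, x$removed[r]))
  invisible(x)
}
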