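# Model-ready bihourly and daily record tables joining movement, spatial
# annotation and weather, plus monthly summary tables. Days and time-of-day
# bins are local time (UTC+2, the study region).

local_day <- function(t) format(t, "%Y-%m-%d", tz = TORTMOVE_TZ)
local_month <- function(t) format(t, "%b", tz = TORTMOVE_TZ)
local_tod_bin <- function(t, width_h = 2) {
  hr <- as.integer(format(t, "%H", tz = TORTMOVE_TZ))
  sprintf("%02d", (hr %/% width_h) * width_h)
}

# Mean temperature and summed rainfall over the (t - window, t] interval of
# an hourly weather series; NA when no stamp falls in the window.
weather_window <- function(weather, t_end, window_s = 7200) {
  wts <- as.numeric(weather$timestamp)
  stopifnot(!is.unsorted(wts))
  ctemp <- cumsum(weather$temp_c)
  crain <- cumsum(weather$rain_mm)
  a <- findInterval(as.numeric(t_end) - window_s, wts)
  b <- findInterval(as.numeric(t_end), wts)
  cnt <- b - a
  temp <- ifelse(cnt > 0,
                 (ctemp[pmax(b, 1)] - ifelse(a > 0, ctemp[pmax(a, 1)], 0)) / cnt,
                 NA_real_)
  rain <- ifelse(cnt > 0,
                 crain[pmax(b, 1)] - ifelse(a > 0, crain[pmax(a, 1)], 0),
                 NA_real_)
  data.frame(temp = temp, rain = rain, n = cnt)
}

# Join annotation columns onto steps by (individual, fix timestamp).
join_annotation <- function(steps, annotations, at = c("start", "end")) {
  at <- match.arg(at)
  t_key <- if (at == "start") steps$t_start else steps$t_end
  key_s <- paste(steps$individual, as.numeric(t_key))
  key_a <- paste(annotations$individual, as.numeric(annotations$timestamp))
  mi <- match(key_s, key_a)
  if (anyNA(mi))
    stop("annotation join failed for ", sum(is.na(mi)), " step(s)")
  annotations[mi, , drop = FALSE]
}

#' Build bihourly model records
#'
#' One record per retained nominal-interval step (dt within
#' `nominal_dt_h` plus/minus `dt_tol_min`): log10 corrected distance as the
#' response; month and local time-of-day bin of the step's end fix; sex;
#' habitat class and distance-to-water of the step's start fix (switchable to
#' the end fix); mean temperature and summed rainfall over the two hours
#' before the end fix; individual id. Steps without weather coverage and
#' steps whose anchor fix lies out of the habitat grid are dropped and
#' counted.
#'
#' @param steps corrected steps ([correct_distances()] output).
#' @param annotations annotated fixes ([annotate_fixes()] output, including
#'   `sex`).
#' @param weather hourly `weather_series`.
#' @param nominal_dt_h nominal fix interval in hours.
#' @param dt_tol_min tolerance around the nominal interval, minutes.
#' @param eps floor (metres) applied to corrected distances before the log,
#'   so zero-distance steps stay finite; 0.1 m is below any resolvable
#'   movement.
#' @param habitat_from `"start"` (default) or `"end"`: which fix supplies
#'   habitat and distance covariates.
#' @return data.frame of class `bihourly_records` with columns `log_d`,
#'   `d_corr_m`, `month`, `time_of_day`, `sex`, `habitat`, `dist_water_m`,
#'   `temp_2h`, `rain_2h`, `individual`. Attributes `n_offnominal`,
#'   `n_no_weather`, `n_out_of_grid` count exclusions.
#' @export
build_bihourly_records <- function(steps, annotations, weather,
                                   nominal_dt_h = 2, dt_tol_min = 10,
                                   eps = 0.1,
                                   habitat_from = c("start", "end")) {
  habitat_from <- match.arg(habitat_from)
  if (is.null(steps$d_corr_m)) stop("steps must be corrected first")
  tol_h <- dt_tol_min / 60
  nominal <- abs(steps$dt_h - nominal_dt_h) <= tol_h
  n_off <- sum(!nominal)
  s <- steps[nominal, , drop = FALSE]
  ann <- join_annotation(s, annotations, at = habitat_from)
  ww <- weather_window(weather, s$t_end, window_s = nominal_dt_h * 3600)
  keep_w <- ww$n > 0
  keep_g <- !is.na(ann$habitat)
  keep <- keep_w & keep_g
  out <- data.frame(
    log_d = log10(pmax(s$d_corr_m[keep], eps)),
    d_corr_m = s$d_corr_m[keep],
    month = factor(local_month(s$t_end[keep]), levels = month.abb),
    time_of_day = factor(local_tod_bin(s$t_end[keep]),
                         levels = sprintf("%02d", seq(0, 22, by = 2))),
    sex = ann$sex[keep],
    habitat = ann$habitat[keep],
    dist_water_m = ann$dist_water_m[keep],
    temp_2h = ww$temp[keep],
    rain_2h = ww$rain[keep],
    individual = s$individual[keep])
  attr(out, "n_offnominal") <- n_off
  attr(out, "n_no_weather") <- sum(!keep_w)
  attr(out, "n_out_of_grid") <- sum(keep_w & !keep_g)
  class(out) <- c("bihourly_records", "data.frame")
  out
}

#' Build daily model records
#'
#' Per individual and local calendar day: cumulative corrected distance over
#' all that day's steps (nominal and off-nominal alike, so daily totals are
#' conserved); the day's modal habitat (ties broken by the earliest habitat
#' observed that day); mean distance-to-water over the day's step anchors;
#' daily mean temperature and total rainfall; month; sex; individual.
#' Individuals listed in `exclude_individuals` are dropped (e.g. an animal
#' that died mid-study); days whose modal habitat occurs on fewer than
#' `rare_habitat_min_days` days across the dataset are excluded, mirroring
#' the exclusion of single-day habitat levels before daily model fitting.
#'
#' @param steps corrected steps.
#' @param annotations annotated fixes.
#' @param weather hourly `weather_series`.
#' @param eps floor (metres) for the log response.
#' @param exclude_individuals character vector of ids to drop.
#' @param rare_habitat_min_days minimum number of daily records a modal
#'   habitat must have to be kept (default 2; set to 1 to keep all).
#' @param habitat_from `"start"` or `"end"` fix for habitat/distance.
#' @return data.frame of class `daily_records` with columns `log_d`,
#'   `d_day_m`, `habitat`, `dist_water_m`, `temp_mean`, `rain_total`,
#'   `month`, `sex`, `individual`, `day`. Attributes `n_excluded_individual`,
#'   `n_rare_habitat_days` count exclusions.
#' @export
build_daily_records <- function(steps, annotations, weather, eps = 0.1,
                                exclude_individuals = NULL,
                                rare_habitat_min_days = 2,
                                habitat_from = c("start", "end")) {
  habitat_from <- match.arg(habitat_from)
  if (is.null(steps$d_corr_m)) stop("steps must be corrected first")
  n_excl_ind <- sum(steps$individual %in% exclude_individuals)
  s <- steps[!(steps$individual %in% exclude_individuals), , drop = FALSE]
  if (nrow(s) == 0) stop("no steps left after exclusions")
  ann <- join_annotation(s, annotations, at = habitat_from)
  day <- local_day(s$t_end)
  key <- paste(s$individual, day)
  ord <- order(s$individual, s$t_start)

  groups <- split(ord, key[ord])
  rows <- lapply(groups, function(ii) {
    hab <- ann$habitat[ii]
    hab_ok <- hab[!is.na(hab)]
    modal <- if (length(hab_ok)) {
      tab <- table(hab_ok)
      cand <- names(tab)[tab == max(tab)]
      # tie-break: earliest-occurring habitat that day
      cand[which.min(match(cand, hab_ok))]
    } else NA_character_
    data.frame(
      individual = s$individual[ii[1]],
      day = local_day(s$t_end[ii[1]]),
      d_day_m = sum(s$d_corr_m[ii]),
      habitat = modal,
      dist_water_m = mean(ann$dist_water_m[ii]),
      sex = ann$sex[ii[1]],
      n_steps = length(ii))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  # daily weather by local calendar day
  wday <- local_day(weather$timestamp)
  temp_by_day <- tapply(weather$temp_c, wday, mean)
  rain_by_day <- tapply(weather$rain_mm, wday, sum)
  out$temp_mean <- as.numeric(temp_by_day[out$day])
  out$rain_total <- as.numeric(rain_by_day[out$day])
  out$month <- factor(format(as.Date(out$day), "%b"), levels = month.abb)
  out$log_d <- log10(pmax(out$d_day_m, eps))

  keep <- !is.na(out$habitat)
  out <- out[keep, , drop = FALSE]
  hab_days <- table(out$habitat)
  rare <- names(hab_days)[hab_days < rare_habitat_min_days]
  n_rare <- sum(out$habitat %in% rare)
  out <- out[!(out$habitat %in% rare), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_individual") <- n_excl_ind
  attr(out, "n_rare_habitat_days") <- n_rare
  attr(out, "rare_habitats_dropped") <- rare
  class(out) <- c("daily_records", "data.frame")
  out
}

#' Append row mean, SE and a Total row to a habitat-by-month count table
#'
#' @param tab numeric matrix (habitats x months).
#' @return data.frame with `Mean` and `SE` columns and a final `Total` row
#'   (totals over habitats per month; Mean/SE of the totals row are the mean
#'   and SE of the monthly totals).
#' @export
summarize_count_table <- function(tab) {
  tab <- as.matrix(tab)
  means <- rowMeans(tab)
  ses <- apply(tab, 1, se_mean)
  total <- colSums(tab)
  out <- data.frame(tab, Mean = means, SE = ses, check.names = FALSE)
  out["Total", ] <- c(total, mean(total), se_mean(total))
  out
}

#' Monthly summary tables: daily distance by sex, habitat use by month
#'
#' @param daily a `daily_records` data.frame.
#' @param annotations optional annotated fixes for the habitat-by-month count
#'   table (omitted when NULL).
#' @return list of class `monthly_summary`: `distance` (per month: mean,
#'   SE and n of daily distance overall and by sex, plus mean temperature and
#'   total rainfall over the month's unique days) and `habitat` (count table
#'   with Mean/SE columns and Total row), or NULL.
#' @export
monthly_summary <- function(daily, annotations = NULL) {
  stopifnot(nrow(daily) >= 1)
  months <- levels(daily$month)
  row_for <- function(d) c(mean = mean(d), se = se_mean(d), n = length(d))
  dist <- lapply(months, function(m) {
    dm <- daily[daily$month == m, , drop = FALSE]
    if (nrow(dm) == 0)
      return(data.frame(month = m, mean = NA, se = NA, n = 0,
                        mean_male = NA, se_male = NA,
                        mean_female = NA, se_female = NA,
                        avg_temp_c = NA, total_rain_mm = NA))
    all_r <- row_for(dm$d_day_m)
    mal <- dm$d_day_m[dm$sex == "Male"]
    fem <- dm$d_day_m[dm$sex == "Female"]
    ud <- !duplicated(dm$day)
    data.frame(month = m, mean = all_r["mean"], se = all_r["se"],
               n = all_r["n"],
               mean_male = if (length(mal)) mean(mal) else NA,
               se_male = se_mean(mal),
               mean_female = if (length(fem)) mean(fem) else NA,
               se_female = se_mean(fem),
               avg_temp_c = mean(dm$temp_mean[ud]),
               total_rain_mm = sum(dm$rain_total[ud]))
  })
  dist <- do.call(rbind, dist)
  rownames(dist) <- NULL

  hab <- NULL
  if (!is.null(annotations)) {
    mo <- factor(local_month(annotations$timestamp), levels = month.abb)
    ok <- !is.na(annotations$habitat)
    tab <- table(annotations$habitat[ok], mo[ok])
    hab <- summarize_count_table(unclass(tab)[, month.abb, drop = FALSE])
  }
  structure(list(distance = dist, habitat = hab), class = "monthly_summary")
}

#' @export
print.monthly_summary <- function(x, digits = 2, ...) {
  cat("Daily distance moved (mean +/- SE) by month:\n")
  d <- x$distance
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %s  total %7.1f +/- %6.2f   male %7.1f   female %7.1f   temp %5.1f C  rain %6.1f mm\n",
                d$month[i], d$mean[i], d$se[i], d$mean_male[i],
                d$mean_female[i], d$avg_temp_c[i], d$total_rain_mm[i]))
  }
  if (!is.null(x$habitat)) {
    cat("\nHabitat use (fix counts) by month:\n")
    print(round(x$habitat, digits))
  }
  invisible(x)
}
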