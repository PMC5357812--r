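# Orchestration: one configuration drives simulate -> calibrate -> screen ->
# annotate -> steps -> aggregate -> model -> report, with every stage output
# persisted as plain text and a rerun under the same config + seed producing
# byte-identical files.

PIPELINE_STAGES <- c("simulate", "calibrate", "screen", "extract", "steps",
                     "aggregate", "model", "report")

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed root seed; overrides the simulation config's seed so all
#'   randomness flows from one value.
#' @param sim a [sim_config()].
#' @param screening a [screening_config()].
#' @param calibration_n number of calibration fixes to generate.
#' @param rank_scope step-ranking scope, `"pooled"` or `"individual"`.
#' @param eps response floor in metres for zero corrected distances.
#' @param exclude_individuals ids dropped from daily aggregation.
#' @param rare_habitat_min_days minimum daily records per modal habitat.
#' @param bihourly_terms,daily_terms candidate predictor sets for the two
#'   model scales.
#' @param delta_cut top-set threshold on delta AICc.
#' @param average `"full"` or `"conditional"` model averaging.
#' @param run_deviance logical: run interaction deviance tests on important
#'   predictors (relative importance >= 0.8).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "tortmove_run", seed = 1,
                            sim = sim_config(),
                            screening = screening_config(),
                            calibration_n = 500,
                            rank_scope = "pooled", eps = 0.1,
                            exclude_individuals = NULL,
                            rare_habitat_min_days = 2,
                            bihourly_terms = c("habitat", "month", "sex",
                                               "time_of_day", "dist_water_m",
                                               "temp_2h", "rain_2h"),
                            daily_terms = c("habitat", "month", "sex",
                                            "dist_water_m", "temp_mean",
                                            "rain_total"),
                            delta_cut = 2, average = "full",
                            run_deviance = FALSE) {
  stopifnot(delta_cut > 0)
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 screening = screening, calibration_n = calibration_n,
                 rank_scope = rank_scope, eps = eps,
                 exclude_individuals = exclude_individuals,
                 rare_habitat_min_days = rare_habitat_min_days,
                 bihourly_terms = bihourly_terms, daily_terms = daily_terms,
                 delta_cut = delta_cut, average = average,
                 run_deviance = run_deviance),
            class = "pipeline_config")
}

#' Small demonstration configuration
#'
#' Four individuals over three months on a coarser (10 m pixel) grid, with
#' reduced candidate term sets, so a full run completes in a couple of
#' minutes on one CPU.
#'
#' @param out_dir output directory.
#' @param seed root seed.
#' @return a `pipeline_config`.
#' @export
demo_config <- function(out_dir = "tortmove_demo", seed = 1) {
  pipeline_config(
    out_dir = out_dir, seed = seed,
    sim = sim_config(n_individuals = 4, start = "2015-01-01",
                     end = "2015-03-31", pixel_m = 10, seed = seed),
    calibration_n = 200,
    bihourly_terms = c("month", "time_of_day", "dist_water_m", "temp_2h"),
    daily_terms = c("month", "dist_water_m", "temp_mean"))
}

write_config_yaml <- function(config, path) {
  ser <- rapply(unclass(config), function(x) {
    if (inherits(x, "POSIXct")) format_iso8601(x) else x
  }, how = "replace")
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Run the full movement-analysis pipeline
#'
#' Executes, in order: simulate (environment, weather, tracks, corrupted
#' fixes, calibration) -> calibrate (error model) -> screen -> extract
#' (habitat/distance annotation) -> steps (distances, rank percentiles,
#' error-quantile correction) -> aggregate (bihourly/daily records, monthly
#' summaries) -> model (all-subsets AICc averaging at both scales, optional
#' deviance tests) -> report. Every stage output is persisted as plain text
#' under `config$out_dir`; a rerun with the same config and seed is
#' byte-identical. Any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param through_stage last stage to execute (default `"report"`).
#' @param verbose print per-stage log lines.
#' @return a `run_report` (invisibly): per-stage record counts, screening
#'   report, model sets, summaries, provenance (config hash, seed).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         through_stage = "report", verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  through_stage <- match.arg(through_stage, PIPELINE_STAGES)
  n_stage <- match(through_stage, PIPELINE_STAGES)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) if (verbose) message(sprintf(...))
  counts <- list()
  res <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_config_yaml(config, cfg_path)

  ## simulate ----
  run_stage("simulate", function() {
    ew <- generate_environment(config$sim)
    res$env <- ew$env; res$water <- ew$water
    res$weather <- generate_weather(config$sim)
    res$tracks <- simulate_tracks(res$env, res$water, res$weather, config$sim)
    cf <- corrupt_fixes(res$tracks, res$env, config$sim)
    res$fixes <- cf$fixes; res$labels <- cf$labels
    centre <- res$env$extent_m / 2
    res$calibration <- generate_calibration(centre, config$calibration_n,
                                            config$sim)
    write_env(res$env, file.path(config$out_dir, "environment"))
    write_water_geojson(res$water, file.path(config$out_dir, "water.geojson"))
    write_weather(res$weather, file.path(config$out_dir, "weather.csv"))
    write_fixes(res$fixes, file.path(config$out_dir, "fixes.csv"))
    write_truth(res$tracks, res$labels, file.path(config$out_dir, "truth.json"))
    utils::write.csv(res$calibration,
                     file.path(config$out_dir, "calibration.csv"),
                     row.names = FALSE, quote = FALSE)
    counts$fixes_simulated <<- nrow(res$fixes)
    log_line("simulate: %d fixes, %d planted artifacts",
             nrow(res$fixes), nrow(res$labels))
  })
  if (n_stage < 2) return(invisible(make_run_report(config, counts, res)))

  ## calibrate ----
  run_stage("calibrate", function() {
    res$fix_error <- compute_fix_errors(res$calibration)
    # A perfect calibration set (all errors zero, e.g. noise-free synthetic
    # data) admits no log-scale quantile model; the correction degenerates
    # to a zero deduction, so d_corr = d_est.
    res$error_model <- if (res$fix_error$max == 0) {
      structure(list(log10_errors = c(-Inf, -Inf), pp = c(0.25, 0.75),
                     n = 2L, type = "hazen",
                     summary = c(mean = 0, min = 0, max = 0)),
                class = "error_model")
    } else build_error_model(res$fix_error)
    write_error_model(res$error_model,
                      file.path(config$out_dir, "error_model.json"))
    counts$calibration_fixes <<- res$fix_error$n
    log_line("calibrate: mean fix error %.2f m", res$fix_error$mean)
  })
  if (n_stage < 3) return(invisible(make_run_report(config, counts, res)))

  ## screen ----
  run_stage("screen", function() {
    scr <- screen_fixes(res$fixes, res$env, config$screening)
    res$retained <- scr$retained; res$screening_report <- scr$report
    write_fixes(res$retained, file.path(config$out_dir, "fixes_screened.csv"))
    rep <- scr$report
    jsonlite::write_json(
      list(total = rep$total, removed = as.list(rep$removed),
           retained = rep$retained,
           by_individual = as.list(rep$by_individual)),
      file.path(config$out_dir, "screening_report.json"),
      auto_unbox = TRUE, digits = NA)
    counts$fixes_retained <<- rep$retained
    for (r in names(rep$removed))
      log_line("screen: rule %s removed %d", r, rep$removed[r])
  })
  if (n_stage < 4) return(invisible(make_run_report(config, counts, res)))

  ## extract ----
  run_stage("extract", function() {
    res$annotated <- annotate_fixes(res$retained, res$env, res$water)
    out <- res$annotated
    out$timestamp <- format_iso8601(out$timestamp)
    out$intended_timestamp <- format_iso8601(out$intended_timestamp)
    utils::write.csv(out, file.path(config$out_dir, "fixes_annotated.csv"),
                     row.names = FALSE, quote = FALSE)
    counts$fixes_annotated <<- nrow(res$annotated)
    log_line("extract: %d fixes annotated (%d out of grid)",
             nrow(res$annotated), attr(res$annotated, "n_out_of_grid"))
  })
  if (n_stage < 5) return(invisible(make_run_report(config, counts, res)))

  ## steps ----
  run_stage("steps", function() {
    st <- compute_steps(res$retained)
    st <- assign_rank_percentiles(st, scope = config$rank_scope)
    st <- correct_distances(st, res$error_model)
    res$steps <- st
    write_steps(st, file.path(config$out_dir, "steps.csv"))
    counts$steps <<- nrow(st)
    log_line("steps: %d steps", nrow(st))
  })
  if (n_stage < 6) return(invisible(make_run_report(config, counts, res)))

  ## aggregate ----
  run_stage("aggregate", function() {
    res$bihourly <- build_bihourly_records(res$steps, res$annotated,
                                           res$weather, eps = config$eps)
    res$daily <- build_daily_records(
      res$steps, res$annotated, res$weather, eps = config$eps,
      exclude_individuals = config$exclude_individuals,
      rare_habitat_min_days = config$rare_habitat_min_days)
    res$monthly <- monthly_summary(res$daily, res$annotated)
    utils::write.csv(res$bihourly,
                     file.path(config$out_dir, "records_bihourly.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(res$daily,
                     file.path(config$out_dir, "records_daily.csv"),
                     row.names = FALSE, quote = FALSE)
    counts$bihourly_records <<- nrow(res$bihourly)
    counts$daily_records <<- nrow(res$daily)
    log_line("aggregate: %d bihourly, %d daily records",
             nrow(res$bihourly), nrow(res$daily))
  })
  if (n_stage < 7) return(invisible(make_run_report(config, counts, res)))

  ## model ----
  run_stage("model", function() {
    fit_scale <- function(records, terms) {
      des <- withCallingHandlers(
        standardize_design(records, terms),
        warning = function(w) {
          log_line("model: %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      fits <- fit_all_subsets(des)
      ms <- rank_and_average(fits, delta_cut = config$delta_cut,
                             average = config$average)
      list(design = des, ms = ms)
    }
    b <- fit_scale(res$bihourly, config$bihourly_terms)
    d <- fit_scale(res$daily, config$daily_terms)
    res$model_bihourly <- b$ms; res$model_daily <- d$ms
    if (isTRUE(config$run_deviance)) {
      res$deviance_bihourly <- important_term_deviance(
        b$design, b$ms, moderators = c("month", "time_of_day"))
      res$deviance_daily <- important_term_deviance(
        d$design, d$ms, moderators = c("month", "habitat"))
    }
    counts$candidates_bihourly <<- nrow(b$ms$table)
    counts$candidates_daily <<- nrow(d$ms$table)
    log_line("model: %d + %d candidate models",
             nrow(b$ms$table), nrow(d$ms$table))
  })
  if (n_stage < 8) return(invisible(make_run_report(config, counts, res)))

  ## report ----
  run_stage("report", function() {
    report_tables(res, config$out_dir)
    report <- make_run_report(config, counts, res)
    # provenance hash over the scientific configuration only (the output
    # path is incidental and must not break rerun comparisons)
    canon <- tempfile(fileext = ".yaml")
    cfg_no_path <- config
    cfg_no_path$out_dir <- NULL
    write_config_yaml(cfg_no_path, canon)
    cfg_md5 <- unname(tools::md5sum(canon))
    unlink(canon)
    jsonlite::write_json(
      list(seed = config$seed, config_md5 = cfg_md5,
           counts = counts),
      file.path(config$out_dir, "run_report.json"),
      auto_unbox = TRUE, digits = NA)
    res$report <- report
  })
  invisible(make_run_report(config, counts, res))
}

# Deviance tests for important (RI >= 0.8) predictors: each important main
# effect, plus each moderator x other-important-term interaction.
important_term_deviance <- function(design, ms, moderators, ri_min = 0.8) {
  imp <- names(ms$ri)[ms$ri >= ri_min]
  imp <- intersect(imp, design$terms)
  if (length(imp) < 1) return(NULL)
  effects <- as.list(imp)
  for (m in intersect(moderators, imp))
    for (o in setdiff(imp, m))
      effects[[length(effects) + 1]] <- c(m, o)
  interaction_deviance(design, imp, effects)
}

make_run_report <- function(config, counts, res) {
  structure(list(seed = config$seed, out_dir = config$out_dir,
                 counts = counts,
                 screening = res$screening_report %||% NULL,
                 model_bihourly = res$model_bihourly %||% NULL,
                 model_daily = res$model_daily %||% NULL,
                 monthly = res$monthly %||% NULL),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("tortmove pipeline run (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  if (!is.null(x$screening)) print(x$screening)
  invisible(x)
}

#' Write formatted result tables
#'
#' Persists, per model scale, the full candidate ranking (model, df, logLik,
#' AICc, delta AICc, weight, top-set flag), the model-averaged coefficient
#' table (term, beta, SE, z, confidence interval, relative importance) and
#' any deviance tables; plus the monthly distance and habitat-use summaries,
#' as CSV and an aligned-text report.
#'
#' @param res environment or list with pipeline results (`model_bihourly`,
#'   `model_daily`, `monthly`, optional deviance tables).
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
report_tables <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  fmt_tab <- function(ms) {
    tab <- ms$table
    tab$logLik <- sprintf("%.2f", tab$logLik)
    tab$AICc <- sprintf("%.2f", tab$AICc)
    tab$delta <- sprintf("%.2f", tab$delta)
    tab$weight <- sprintf("%.3f", tab$weight)
    tab
  }
  if (!is.null(res$model_bihourly)) {
    wr(fmt_tab(res$model_bihourly), "models_bihourly.csv")
    wr(res$model_bihourly$averaged, "averaged_bihourly.csv")
  }
  if (!is.null(res$model_daily)) {
    wr(fmt_tab(res$model_daily), "models_daily.csv")
    wr(res$model_daily$averaged, "averaged_daily.csv")
  }
  if (!is.null(res$deviance_bihourly %||% NULL))
    wr(res$deviance_bihourly, "deviance_bihourly.csv")
  if (!is.null(res$deviance_daily %||% NULL))
    wr(res$deviance_daily, "deviance_daily.csv")
  if (!is.null(res$monthly)) {
    wr(res$monthly$distance, "monthly_distance.csv")
    if (!is.null(res$monthly$habitat)) {
      hab <- data.frame(habitat = rownames(res$monthly$habitat),
                        res$monthly$habitat, check.names = FALSE)
      wr(hab, "monthly_habitat.csv")
    }
  }
  txt <- file.path(out_dir, "report.txt")
  con <- file(txt, "w")
  sink(con)
  on.exit({ sink(); close(con) })
  if (!is.null(res$model_bihourly)) {
    cat("== Bihourly movement models ==\n"); print(res$model_bihourly)
  }
  if (!is.null(res$model_daily)) {
    cat("\n== Daily movement models ==\n"); print(res$model_daily)
  }
  if (!is.null(res$monthly)) {
    cat("\n== Monthly summaries ==\n"); print(res$monthly)
  }
  paths <- c(paths, txt)
  invisible(paths)
}
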