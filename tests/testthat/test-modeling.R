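# Standardization, ML mixed models, AICc machinery, averaging, deviance
# tests and the Welch t utility.

test_that("standardization centres and scales by two standard deviations", {
  rec <- data.frame(log_d = rnorm(4), x = c(0, 2, 0, 2),
                    b = c(0, 1, 0, 1), individual = c("A", "A", "B", "B"))
  des <- standardize_design(rec, c("x", "b"))
  # x in {0, 2}: mean 1, sd sqrt(4/3)... computed directly
  expect_equal(des$data$x, (rec$x - mean(rec$x)) / (2 * sd(rec$x)),
               tolerance = 1e-12)
  # two distinct values exactly: closed form for the {0,2} pair case
  rec2 <- data.frame(log_d = rnorm(2), x = c(0, 2), individual = c("A", "B"))
  des2 <- standardize_design(rec2, "x")
  expect_equal(des2$data$x, c(-0.35355339, 0.35355339), tolerance = 1e-6)
  # balanced binary -> centred to -0.5 / +0.5
  expect_equal(des$data$b, c(-0.5, 0.5, -0.5, 0.5))
  # standardized continuous: mean 0, sd 0.5
  set.seed(2)
  rec3 <- data.frame(log_d = rnorm(100), x = rnorm(100, 50, 9),
                     individual = rep(c("A", "B"), 50))
  des3 <- standardize_design(rec3, "x")
  expect_equal(mean(des3$data$x), 0, tolerance = 1e-10)
  expect_equal(sd(des3$data$x), 0.5, tolerance = 1e-10)
})

test_that("categoricals are reference-coded with the conventional levels", {
  set.seed(3)
  n <- 240
  rec <- data.frame(
    log_d = rnorm(n),
    month = sample(month.abb, n, TRUE),
    time_of_day = sample(sprintf("%02d", seq(0, 22, 2)), n, TRUE),
    habitat = sample(c("Low shrubland", "Dense bush", "Grassland"), n, TRUE),
    individual = sample(c("A", "B", "C"), n, TRUE))
  des <- standardize_design(rec, c("month", "time_of_day", "habitat"))
  fit <- fit_lmm(des)
  nm <- fit$coef$name
  expect_identical(sum(fit$coef$term == "month"), 11L)    # April absent
  expect_false("monthApr" %in% nm)
  expect_false("time_of_day00" %in% nm)
  expect_false("habitatLow shrubland" %in% nm)
  # constant predictor is dropped with a warning, not silently zeroed
  rec$const <- 1
  expect_warning(standardize_design(rec, c("month", "const")),
                 "constant predictor")
})

test_that("the bihourly parameter-count convention gives k = 27", {
  set.seed(8)
  n <- 600
  rec <- data.frame(
    log_d = rnorm(n),
    month = sample(month.abb, n, TRUE),
    time_of_day = sample(sprintf("%02d", seq(0, 22, 2)), n, TRUE),
    dist_water_m = runif(n, 0, 2000), temp_2h = runif(n, 5, 35),
    individual = rep(sprintf("I%d", 1:10), length.out = n))
  des <- standardize_design(rec, c("month", "time_of_day", "dist_water_m",
                                   "temp_2h"))
  fit <- fit_lmm(des)
  expect_identical(fit$k, 27L)   # 11 + 11 + 1 + 1 dummies + intercept + 2
  expect_identical(fit$n, as.integer(n))
  expect_lt(fit$aic, fit$aicc)
  expect_true(is.finite(fit$logLik))
})

test_that("rank-deficient designs fail loudly naming aliased columns", {
  rec <- data.frame(log_d = rnorm(40), x = rnorm(40), individual = rep(c("A", "B"), 20))
  rec$x2 <- rec$x * 2
  des <- standardize_design(rec, c("x", "x2"))
  expect_error(fit_lmm(des), "aliased")
})

test_that("zero between-group variance collapses to the OLS likelihood", {
  set.seed(5)
  dat <- sim_lmm_data(n_per_group = 40, n_groups = 8, tau = 0, sigma = 0.5)
  des <- standardize_design(dat, c("x", "z"))
  fit <- fit_lmm(des)
  expect_lt(fit$tau2, 1e-6)
  ols <- stats::lm(.y ~ x + z, data = des$data)
  expect_equal(fit$logLik, as.numeric(stats::logLik(ols)), tolerance = 1e-4)
})

test_that("the mixed-model ML likelihood matches a direct profile optimum", {
  # independent oracle: profile the marginal ML likelihood over the
  # variance ratio by direct 1-D optimization with GLS at each ratio
  set.seed(6)
  dat <- sim_lmm_data(n_per_group = 30, n_groups = 6, tau = 0.3, sigma = 0.4)
  des <- standardize_design(dat, c("x", "z"))
  fit <- fit_lmm(des)
  X <- stats::model.matrix(~ x + z, des$data)
  y <- des$data$.y
  g <- as.integer(factor(des$data$.id))
  n <- length(y)
  prof_ll <- function(log_ratio) {
    ratio <- exp(log_ratio)   # tau2 / sigma2
    # V = I + ratio * Z Z' is block diagonal; invert per group
    ll_parts <- 0; XtVX <- 0; XtVy <- 0
    for (k in unique(g)) {
      i <- which(g == k); m <- length(i)
      Vi <- diag(m) - matrix(ratio / (1 + m * ratio), m, m)
      XtVX <- XtVX + t(X[i, , drop = FALSE]) %*% Vi %*% X[i, , drop = FALSE]
      XtVy <- XtVy + t(X[i, , drop = FALSE]) %*% Vi %*% y[i]
    }
    beta <- solve(XtVX, XtVy)
    rss <- 0; logdet <- 0
    for (k in unique(g)) {
      i <- which(g == k); m <- length(i)
      Vi <- diag(m) - matrix(ratio / (1 + m * ratio), m, m)
      r <- y[i] - X[i, , drop = FALSE] %*% beta
      rss <- rss + t(r) %*% Vi %*% r
      logdet <- logdet + log1p(m * ratio)
    }
    sigma2 <- as.numeric(rss) / n
    -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  }
  opt <- stats::optimize(prof_ll, c(-10, 5), maximum = TRUE)
  expect_equal(fit$logLik, opt$objective, tolerance = 1e-4)
})

test_that("AICc follows its closed form with guarded domain", {
  expect_equal(aicc(-10, k = 3, n = 10), 30)        # AIC 26 + 24/6
  expect_error(aicc(-10, k = 3, n = 4), "undefined")
  # limit: correction vanishes for large n
  expect_lt(aicc(-10, k = 3, n = 1e8) - 26, 1e-5)
})

test_that("all-subsets enumeration is complete, ordered and guarded", {
  s <- all_subsets(c("a", "b", "c"))
  expect_identical(length(s), 8L)
  expect_identical(s[[1]], character(0))
  expect_identical(length(all_subsets(character(0))), 1L)
  expect_error(all_subsets(letters[1:13]), "refusing")
  expect_identical(length(all_subsets(letters[1:13], force = TRUE)), 8192L)
  # deterministic ordering
  expect_identical(all_subsets(c("a", "b", "c")), all_subsets(c("a", "b", "c")))
})

# Minimal fit stubs for averaging arithmetic driven by known AICc values.
stub_fit <- function(terms, aicc, coef = NULL) {
  if (is.null(coef))
    coef <- data.frame(name = "(Intercept)", term = "(Intercept)",
                       est = 1, se = 0.1)
  list(coef = coef, terms = terms, logLik = NA_real_, n = 100L,
       k = nrow(coef) + 2L, aic = NA_real_, aicc = aicc)
}

test_that("weights, top set and relative importance follow the AICc ranking", {
  fits <- list(stub_fit(c("month", "time", "water", "temp"), 47017.82),
               stub_fit(c("month", "time", "water", "rain", "temp"), 47018.30),
               stub_fit(c("month", "sex", "time", "water", "temp"), 47023.10),
               stub_fit(c("month", "sex", "time", "water", "rain", "temp"), 47023.58),
               stub_fit(c("habitat", "month", "time", "water", "temp"), 47028.67),
               stub_fit(c("habitat", "month", "time", "water", "rain", "temp"), 47029.65))
  ms <- rank_and_average(fits)
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-12)
  expect_equal(min(ms$table$delta), 0)
  expect_identical(sum(ms$table$top), 2L)
  expect_equal(unname(round(ms$table$weight, 3)),
               c(0.521, 0.409, 0.037, 0.029, 0.002, 0.001))
  # renormalized top-set weights give the printed relative importances
  expect_equal(unname(round(ms$ri["rain"], 2)), 0.44)
  expect_equal(unname(ms$ri["month"]), 1)
})

test_that("a single top model is returned unchanged by averaging", {
  co <- data.frame(name = c("(Intercept)", "x"), term = c("(Intercept)", "x"),
                   est = c(1.2, -0.4), se = c(0.05, 0.02))
  fits <- list(stub_fit("x", 100, coef = co), stub_fit(character(0), 150))
  ms <- rank_and_average(fits)
  expect_identical(length(ms$top_index), 1L)
  expect_equal(ms$averaged$beta, co$est)
  expect_equal(ms$averaged$se, co$se)
  expect_equal(ms$averaged$ri[ms$averaged$term == "x"], 1)
  expect_error(rank_and_average(list()), "empty")
})

test_that("full averaging uses zero substitution and inflated unconditional SEs", {
  co1 <- data.frame(name = c("(Intercept)", "x"), term = c("(Intercept)", "x"),
                    est = c(1, 0.5), se = c(0.1, 0.2))
  co2 <- data.frame(name = "(Intercept)", term = "(Intercept)",
                    est = 1.1, se = 0.1)
  fits <- list(stub_fit("x", 10, co1), stub_fit(character(0), 10.5, co2))
  ms <- rank_and_average(fits)
  w <- akaike_weights(c(0, 0.5))
  beta_bar <- w[1] * 0.5 + w[2] * 0
  se_bar <- w[1] * sqrt(0.2^2 + (0.5 - beta_bar)^2) +
    w[2] * sqrt(0 + (0 - beta_bar)^2)
  row <- ms$averaged[ms$averaged$name == "x", ]
  expect_equal(row$beta, beta_bar, tolerance = 1e-12)
  expect_equal(row$se, se_bar, tolerance = 1e-12)
  expect_equal(row$ri, unname(w[1]), tolerance = 1e-12)
  expect_equal(c(row$lower, row$upper),
               c(beta_bar - 1.96 * se_bar, beta_bar + 1.96 * se_bar))
  # conditional averaging restricted to models containing the term
  msc <- rank_and_average(fits, average = "conditional")
  expect_equal(msc$averaged[msc$averaged$name == "x", "beta"], 0.5)
})

test_that("model fitting recovers known simulation coefficients", {
  dat <- sim_lmm_data(n_per_group = 100, n_groups = 10,
                      beta = c(intercept = 1, x = 0.5, z = -0.3),
                      tau = 0.2, sigma = 0.4, seed = 42)
  des <- standardize_design(dat, c("x", "z"), standardize = FALSE)
  fit <- fit_lmm(des)
  cx <- fit$coef[fit$coef$name == "x", ]
  cz <- fit$coef[fit$coef$name == "z", ]
  expect_lt(abs(cx$est - 0.5), 3 * cx$se)
  expect_lt(abs(cz$est + 0.3), 3 * cz$se)
  expect_gt(fit$tau2, 0.005)
})

test_that("deviance tests are nested likelihood-ratio comparisons", {
  dat <- sim_lmm_data(n_per_group = 60, n_groups = 6, seed = 10)
  des <- standardize_design(dat, c("x", "z"))
  dev <- interaction_deviance(des, c("x", "z"),
                              list("x", "z", c("x", "z")))
  expect_true(all(dev$LR >= 0))
  expect_true(all(dev$df >= 1))
  expect_true(all(dev$p >= 0 & dev$p <= 1))
  # the strong main effects are detected; labels carry the effects
  expect_identical(dev$effect, c("x", "z", "x : z"))
  expect_lt(dev$p[1], 1e-6)
  expect_error(interaction_deviance(des, "x", list("z")), "not in the base")
  expect_error(interaction_deviance(des, "x", list(c("x", "z"))),
               "must all be in the base")
})

test_that("Welch t matches its closed form and conventions", {
  r <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4, tolerance = 1e-9)
  expect_equal(r$p, 0.2878641, tolerance = 1e-6)
  # antisymmetry
  r2 <- welch_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  # identical samples
  ri <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ri$t, 0)
  expect_equal(ri$p, 1)
  # zero-variance conventions
  rz <- welch_t(c(2, 2), c(2, 2))
  expect_identical(rz$t, 0)
  expect_identical(rz$p, 1)
  expect_error(welch_t(c(2, 2), c(3, 3)), "infinite")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})
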