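# Inference: predictor standardization, random-intercept Gaussian mixed
# models fit by maximum likelihood, all-subsets candidate generation, AICc
# ranking, Akaike-weight model averaging with relative importance,
# nested-model deviance tests, and the Welch two-sample t utility.
#
# Estimation is ML (not REML) throughout because AICc comparisons across
# fixed-effect structures require the full ML likelihood. The parameter count
# convention is k = (number of fixed coefficients, intercept included) + 2
# (random-intercept variance and residual variance).

#' Standardize predictors for a mixed-model design
#'
#' Continuous predictors are centred and divided by two standard deviations,
#' putting them on the same scale as centred binary predictors; binary
#' predictors (0/1-valued, or two-level factors such as sex) are coded 0/1
#' and centred; categorical predictors are reference-coded with the
#' conventional reference levels (April for month, midnight for time of day,
#' low shrubland for habitat) unless overridden. Constant predictors are
#' dropped with a warning rather than silently zeroed.
#'
#' @param records a data.frame of model records (e.g.
#'   [build_bihourly_records()] output).
#' @param terms character vector of predictor columns.
#' @param response name of the response column.
#' @param group name of the grouping column for the random intercept.
#' @param refs named list of reference levels for categorical terms.
#' @param standardize logical; FALSE keeps predictors on their raw scale
#'   (categoricals are still reference-coded).
#' @return list of class `std_design`: `data` (transformed), `terms` (kept),
#'   `response`, `group`, `term_type`, `scale` (centre/spread per continuous
#'   term), `dropped`.
#' @export
standardize_design <- function(records, terms,
                               response = "log_d", group = "individual",
                               refs = list(month = "Apr", time_of_day = "00",
                                           habitat = "Low shrubland"),
                               standardize = TRUE) {
  stopifnot(response %in% names(records), group %in% names(records))
  missing_terms <- setdiff(terms, names(records))
  if (length(missing_terms))
    stop("term(s) not in records: ", paste(missing_terms, collapse = ", "))
  dat <- data.frame(.y = records[[response]],
                    .id = factor(records[[group]]))
  term_type <- character(0)
  scale_info <- list()
  kept <- character(0)
  dropped <- character(0)
  for (tm in terms) {
    x <- records[[tm]]
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) x <- droplevels(x)
    n_dist <- if (is.factor(x)) nlevels(x) else length(unique(x[!is.na(x)]))
    if (n_dist < 2) {
      warning("dropping constant predictor: ", tm)
      dropped <- c(dropped, tm)
      next
    }
    is_binary <- (is.factor(x) && n_dist == 2) ||
      (!is.factor(x) && all(x[!is.na(x)] %in% c(0, 1)))
    if (is.factor(x) && n_dist > 2) {
      ref <- refs[[tm]]
      if (!is.null(ref) && ref %in% levels(x)) x <- stats::relevel(x, ref)
      dat[[tm]] <- x
      term_type[tm] <- "categorical"
    } else if (is_binary) {
      # 0/1 (or two-level factor) predictors are centred, not rescaled
      if (is.factor(x)) x <- as.numeric(x) - 1
      dat[[tm]] <- if (standardize) x - mean(x, na.rm = TRUE) else x
      term_type[tm] <- "binary"
      scale_info[[tm]] <- c(centre = mean(x, na.rm = TRUE), spread = 1)
    } else {
      ctr <- mean(x, na.rm = TRUE)
      spr <- 2 * stats::sd(x, na.rm = TRUE)
      if (!is.finite(spr) || spr == 0) {
        warning("dropping constant predictor: ", tm)
        dropped <- c(dropped, tm)
        next
      }
      dat[[tm]] <- if (standardize) (x - ctr) / spr else x
      term_type[tm] <- "continuous"
      scale_info[[tm]] <- c(centre = ctr, spread = spr)
    }
    kept <- c(kept, tm)
  }
  structure(list(data = dat, terms = kept, response = response,
                 group = group, term_type = term_type, scale = scale_info,
                 dropped = dropped, standardized = standardize),
            class = "std_design")
}

#' Fit a Gaussian random-intercept linear mixed model by ML
#'
#' Fits `response ~ fixed terms + (1 | group)` by maximum likelihood
#' (`lme4::lmer` with `REML = FALSE`). The reported log-likelihood is the ML
#' log-likelihood and the parameter count is k = fixed coefficients + 2
#' variance parameters. Interaction labels such as `"month:temp_2h"` are
#' accepted alongside plain term names.
#'
#' @param design a [standardize_design()] object.
#' @param terms character vector of fixed-effect terms to include (default:
#'   all terms in the design; `character(0)` fits the intercept-only model).
#' @return list of class `lmm_fit`: `coef` (name, term, est, se), `terms`,
#'   `logLik`, `n`, `k`, `aic`, `aicc`, `sigma2` (residual variance), `tau2`
#'   (random-intercept variance), `model` (the underlying lmerMod).
#' @export
fit_lmm <- function(design, terms = design$terms) {
  stopifnot(inherits(design, "std_design"))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fixed <- stats::as.formula(paste(".y ~", rhs))
  mm <- stats::model.matrix(fixed, design$data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  n_groups <- length(unique(design$data$.id))
  if (n_groups < 2) stop("at least 2 grouping levels are required")
  form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .id)"))
  fit <- lme4::lmer(form, data = design$data, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  k <- length(fe) + 2L
  n <- stats::nobs(fit)
  if (n <= k + 1) stop("too few records for the requested model (n <= k + 1)")
  ll <- as.numeric(stats::logLik(fit))
  vc <- lme4::VarCorr(fit)
  # map each coefficient to the term that generated it
  assign_idx <- attr(mm, "assign")
  labels <- c("(Intercept)", attr(stats::terms(fixed), "term.labels"))
  coef_term <- labels[assign_idx + 1L]
  structure(list(
    coef = data.frame(name = names(fe), term = coef_term,
                      est = unname(fe), se = unname(se)),
    terms = terms, logLik = ll, n = n, k = k,
    aic = -2 * ll + 2 * k, aicc = aicc(ll, k, n),
    sigma2 = attr(vc, "sc")^2, tau2 = as.numeric(vc$.id),
    model = fit), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (ML): %s\n",
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept only)"))
  cat(sprintf("  n = %d, k = %d, logLik = %.2f, AICc = %.2f\n",
              x$n, x$k, x$logLik, x$aicc))
  invisible(x)
}

#' Small-sample corrected Akaike Information Criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1). Undefined for n <= k + 1.
#'
#' @param object an `lmm_fit`, or the ML log-likelihood as a number.
#' @param k,n parameter count (fixed coefficients + 2 variances) and number
#'   of records; taken from the fit when `object` is an `lmm_fit`.
#' @return AICc value.
#' @export
aicc <- function(object, k = NULL, n = NULL) {
  if (inherits(object, "lmm_fit")) {
    ll <- object$logLik; k <- object$k; n <- object$n
  } else {
    ll <- as.numeric(object)
    if (is.null(k) || is.null(n)) stop("k and n are required")
  }
  if (n <= k + 1) stop("AICc undefined: n <= k + 1")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fixed-effect parameter count for a term set
#'
#' k = 1 (intercept) + one column per continuous or binary term + (levels - 1)
#' columns per categorical term + 2 variance parameters.
#'
#' @param terms character vector of term names.
#' @param n_levels named integer vector giving the number of levels of each
#'   categorical term; terms absent from it count one column.
#' @return integer k.
#' @export
count_parameters <- function(terms, n_levels = integer(0)) {
  cols <- vapply(terms, function(tm) {
    if (tm %in% names(n_levels)) as.integer(n_levels[[tm]]) - 1L else 1L
  }, integer(1))
  1L + sum(cols) + 2L
}

#' All subsets of a term list
#'
#' Generates every subset of the candidate terms, including the intercept-only
#' (empty) model, in deterministic order (by subset size, then by term
#' order). Refuses more than `max_terms` terms unless forced.
#'
#' @param terms character vector of candidate terms (0 to 12 by default).
#' @param max_terms combinatorial guard.
#' @param force set TRUE to bypass the guard.
#' @return list of character vectors; length `2^length(terms)`.
#' @export
all_subsets <- function(terms, max_terms = 12, force = FALSE) {
  m <- length(terms)
  if (m > max_terms && !force)
    stop("refusing to enumerate 2^", m, " candidate models; ",
         "set force = TRUE to override")
  out <- list(character(0))
  for (size in seq_len(m)) {
    combos <- utils::combn(terms, size, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

#' Akaike weights from AICc differences
#'
#' @param delta numeric vector of AICc differences from the best model.
#' @return weights `exp(-delta/2)` normalized to sum to 1.
#' @export
akaike_weights <- function(delta) {
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Fit every candidate model of an all-subsets enumeration
#'
#' @param design a `std_design`.
#' @param subsets list of term sets (default: all subsets of the design's
#'   terms).
#' @return list of `lmm_fit` objects.
#' @export
fit_all_subsets <- function(design, subsets = all_subsets(design$terms)) {
  lapply(subsets, function(tt) fit_lmm(design, tt))
}

#' Rank candidate models by AICc and model-average the top set
#'
#' Computes AICc differences and Akaike weights over the whole candidate set,
#' selects the top set (delta AICc below `delta_cut`), renormalizes the
#' top-set weights, and averages coefficients over the top set. With
#' `average = "full"` (the default) a model not containing a coefficient
#' contributes zero — the unconditional average — and the unconditional
#' standard error is `sum_j w_j * sqrt(se_j^2 + (beta_j - beta_bar)^2)`;
#' `"conditional"` averages only over models containing the coefficient.
#' Relative importance of a term is the summed renormalized weight of the
#' top-set models containing it. Confidence intervals are normal-based
#' (1.96 unconditional SE).
#'
#' @param fits list of `lmm_fit` objects (one per candidate).
#' @param delta_cut top-set threshold on delta AICc (default 2).
#' @param average `"full"` or `"conditional"`.
#' @return list of class `model_set`: `table` (model, df, logLik, AICc,
#'   delta, weight, top — sorted by AICc), `averaged` (coefficient table
#'   with `term`, `beta`, `se`, `z`, `lower`, `upper`, `ri`), `ri` (per-term
#'   relative importance), `top_index` (indices into `fits`, best first),
#'   `weights_top` (renormalized), `fits`.
#' @export
rank_and_average <- function(fits, delta_cut = 2,
                             average = c("full", "conditional")) {
  average <- match.arg(average)
  if (!length(fits)) stop("empty candidate list")
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  delta <- aiccs - min(aiccs)
  w_all <- akaike_weights(delta)
  label <- vapply(fits, function(f)
    if (length(f$terms)) paste(f$terms, collapse = " + ") else "(intercept)",
    character(1))
  ord <- order(aiccs)
  tab <- data.frame(model = label, df = vapply(fits, function(f) f$k, numeric(1)),
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    AICc = aiccs, delta = delta, weight = w_all,
                    top = delta < delta_cut)[ord, ]
  rownames(tab) <- NULL

  top_index <- ord[delta[ord] < delta_cut]
  w_top <- akaike_weights(delta[top_index])

  top_fits <- fits[top_index]
  coef_names <- unique(unlist(lapply(top_fits, function(f) f$coef$name)))
  coef_term <- stats::setNames(
    unlist(lapply(top_fits, function(f) f$coef$term)),
    unlist(lapply(top_fits, function(f) f$coef$name)))[coef_names]

  avg <- lapply(coef_names, function(cn) {
    est <- vapply(top_fits, function(f) {
      i <- match(cn, f$coef$name); if (is.na(i)) 0 else f$coef$est[i]
    }, numeric(1))
    ses <- vapply(top_fits, function(f) {
      i <- match(cn, f$coef$name); if (is.na(i)) 0 else f$coef$se[i]
    }, numeric(1))
    present <- vapply(top_fits, function(f) cn %in% f$coef$name, logical(1))
    if (average == "full") {
      w <- w_top
    } else {
      w <- w_top[present] / sum(w_top[present])
      est <- est[present]; ses <- ses[present]
    }
    beta <- sum(w * est)
    se_u <- sum(w * sqrt(ses^2 + (est - beta)^2))
    data.frame(name = cn, term = unname(coef_term[cn]), beta = beta,
               se = se_u,
               z = if (se_u > 0) abs(beta) / se_u else NA_real_,
               lower = beta - 1.96 * se_u, upper = beta + 1.96 * se_u)
  })
  avg <- do.call(rbind, avg)

  all_terms <- unique(unlist(lapply(top_fits, function(f) f$terms)))
  ri <- vapply(all_terms, function(tm)
    sum(w_top[vapply(top_fits, function(f) tm %in% f$terms, logical(1))]),
    numeric(1))
  avg$ri <- ifelse(avg$term == "(Intercept)", NA_real_,
                   as.numeric(ri[avg$term]))
  rownames(avg) <- NULL

  structure(list(table = tab, averaged = avg,
                 ri = stats::setNames(as.numeric(ri), all_terms),
                 top_index = top_index, weights_top = w_top,
                 delta_cut = delta_cut, average = average, fits = fits),
            class = "model_set")
}

#' @export
print.model_set <- function(x, max_rows = 10, ...) {
  cat(sprintf("Candidate set: %d models; top set (delta AICc < %g): %d\n",
              nrow(x$table), x$delta_cut, length(x$top_index)))
  tab <- utils::head(x$table, max_rows)
  tab$logLik <- sprintf("%.2f", tab$logLik)
  tab$AICc <- sprintf("%.2f", tab$AICc)
  tab$delta <- sprintf("%.2f", tab$delta)
  tab$weight <- sprintf("%.3f", tab$weight)
  print(tab, row.names = FALSE)
  cat("\nModel-averaged coefficients (top set):\n")
  av <- x$averaged
  av[c("beta", "se", "z", "lower", "upper", "ri")] <-
    lapply(av[c("beta", "se", "z", "lower", "upper", "ri")],
           function(v) round(v, 3))
  print(av, row.names = FALSE)
  invisible(x)
}

#' Analysis-of-deviance (likelihood-ratio) tests for terms and interactions
#'
#' Each requested effect is tested by a likelihood-ratio comparison of nested
#' ML fits: a main effect against the base model without it, and an
#' interaction (two or three terms, all of which must be in the base model)
#' by adding the interaction columns to the base model. LR =
#' 2 (logLik_large - logLik_small), compared to chi-squared with df equal to
#' the number of added fixed-effect columns.
#'
#' @param design a `std_design`.
#' @param base_terms character vector of base-model terms.
#' @param effects list of character vectors: length-1 for main effects,
#'   length-2/3 for interactions.
#' @return data.frame of class `deviance_table`: `effect`, `LR`, `df`, `p`.
#' @export
interaction_deviance <- function(design, base_terms, effects) {
  base_fit <- fit_lmm(design, base_terms)
  rows <- lapply(effects, function(ef) {
    if (length(ef) == 1) {
      if (!(ef %in% base_terms))
        stop("main effect '", ef, "' is not in the base model; ",
             "comparison would not be nested")
      small <- fit_lmm(design, setdiff(base_terms, ef))
      big <- base_fit
      label <- ef
    } else {
      if (!all(ef %in% base_terms))
        stop("interaction terms must all be in the base model: ",
             paste(ef, collapse = ":"))
      small <- base_fit
      big <- fit_lmm(design, c(base_terms, paste(ef, collapse = ":")))
      label <- paste(ef, collapse = " : ")
    }
    df <- big$k - small$k
    if (df < 1) {
      lr <- max(0, 2 * (big$logLik - small$logLik))
      return(data.frame(effect = label, LR = lr, df = df, p = NA_real_))
    }
    lr <- max(0, 2 * (big$logLik - small$logLik))
    data.frame(effect = label, LR = lr, df = df,
               p = stats::pchisq(lr, df, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("deviance_table", "data.frame")
  out
}

#' Welch two-sample t-test
#'
#' Mean comparison without assuming equal variances, with Satterthwaite
#' degrees of freedom (wraps `stats::t.test`). When both samples have zero
#' variance and equal means the statistic is 0 with p = 1 by convention;
#' zero variances with unequal means give an infinite statistic and are an
#' error.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("infinite t statistic: zero variance in both samples with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
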