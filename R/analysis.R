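#' Covariate adjustment design matrix
#'
#' The adjustment set used by every analysis stage: age, sex, assessment
#' center (one-hot indicators dropping the first center) and the genetic
#' principal components. An intercept column is prepended for linear
#' models; Cox models absorb it into the baseline hazard.
#'
#' @param data cohort data.frame with `age`, `sex`, `center`, `pc*`.
#' @param intercept add an intercept column?
#' @return numeric matrix with named columns.
#' @export
adjustment_design <- function(data, intercept = FALSE) {
  centers <- sort(unique(data$center))
  cm <- NULL
  if (length(centers) > 1) {
    cm <- vapply(centers[-1], function(k) as.numeric(data$center == k),
                 numeric(nrow(data)))
    colnames(cm) <- paste0("center", centers[-1])
  }
  pc_cols <- grep("^pc[0-9]+$", names(data), value = TRUE)
  X <- cbind(age = data$age, sex = data$sex, cm,
             as.matrix(data[pc_cols]))
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

cohort_outcome <- function(cohort, outcome) {
  tcol <- paste0("time_", outcome); ecol <- paste0("event_", outcome)
  if (!all(c(tcol, ecol) %in% names(cohort$data)))
    stop2("outcome '", outcome, "' not present in cohort")
  list(time = cohort$data[[tcol]], event = cohort$data[[ecol]])
}

#' Association of a median-split genetic score with a measured biomarker
#'
#' Multivariable linear regression of the biomarker on the lower-group
#' indicator, adjusted for age, sex, assessment center and the principal
#' components. The reported coefficient is the lower-vs-higher group
#' contrast in biomarker units: negative means the score-lowering "arm"
#' lowers the biomarker.
#'
#' @param cohort an `mr_cohort`.
#' @param scores numeric score vector (see [compute_score()]).
#' @param biomarker name of a biomarker column.
#' @return list with `contrast` (one-row data.frame: term, estimate, se,
#'   z, p, ci_low, ci_high) and `fit` (the full `linear_fit`).
#' @export
biomarker_association <- function(cohort, scores, biomarker) {
  if (!biomarker %in% names(cohort$data))
    stop2("biomarker '", biomarker, "' not present in cohort")
  grp <- dichotomize(as.numeric(scores))
  X <- cbind(lower = as.numeric(grp == "lower"),
             adjustment_design(cohort$data, intercept = TRUE))
  fit <- fit_linear(cohort$data[[biomarker]], X)
  tf <- tidy_fit(fit)
  list(contrast = tf[tf$term == "lower", , drop = FALSE], fit = fit)
}

#' Hazard ratio per 50-mg/dL decrease in a genetically predicted lipid
#'
#' Fits a Cox model with the continuous score (mg/dL) plus the adjustment
#' set, then rescales: `HR = exp(-50 * beta)` with confidence limits
#' `exp(-50 * (beta -+ 1.96 se))` ordered so `ci_low <= ci_high`. Only
#' defined for scores in mg/dL; other arms report per-SD via
#' [per_sd_hr()].
#'
#' @param cohort an `mr_cohort`.
#' @param scores a `score_vector` in mg/dL (attribute `units`).
#' @param outcome outcome name (e.g. `"pad"`).
#' @return list of class `scaled_hr`: `hr`, `ci_low`, `ci_high`,
#'   `log_hr_per50` (= -50 beta), `se_per50`, `p`, `outcome`, `scale`,
#'   `n`, `n_events`, `fit`.
#' @export
per50_hr <- function(cohort, scores, outcome) {
  units <- attr(scores, "units")
  if (is.null(units) || units != "mg/dL")
    stop2("per-50-mg/dL scaling requires a score in mg/dL (got '",
          if (is.null(units)) "?" else units,
          "'); use per_sd_hr() for non-lipid arms")
  fit <- score_cox_fit(cohort, scores, outcome)
  # re-orient so beta is always per trait-increasing unit: the reported
  # per-decrease HR is then invariant to flipping the stored score
  b <- orientation_sign(scores) * fit$coefficients[["score"]]
  se <- fit$se[["score"]]
  if (!is.finite(se) || se <= 0) stop2("degenerate fit: se not positive")
  q <- qnorm(0.975)
  ci <- sort(exp(-50 * (b + c(-1, 1) * q * se)))
  structure(list(hr = exp(-50 * b), ci_low = ci[1], ci_high = ci[2],
                 log_hr_per50 = -50 * b, se_per50 = 50 * se,
                 p = 2 * pnorm(-abs(b / se)), outcome = outcome,
                 scale = "per 50 mg/dL decrease", n = fit$n,
                 n_events = fit$n_events, fit = fit),
            class = "scaled_hr")
}

#' Hazard ratio per 1-SD decrease in a genetic score
#'
#' The reporting fallback for arms without an mg/dL scale (BMI, SBP,
#' lifestyle): `HR = exp(-sd(score) * beta)` from the same continuous-score
#' Cox fit.
#'
#' @inheritParams per50_hr
#' @return list of class `scaled_hr` (scale `"per SD decrease"`).
#' @export
per_sd_hr <- function(cohort, scores, outcome) {
  fit <- score_cox_fit(cohort, scores, outcome)
  s <- sd(as.numeric(scores))
  b <- orientation_sign(scores) * fit$coefficients[["score"]]
  se <- fit$se[["score"]]
  q <- qnorm(0.975)
  ci <- sort(exp(-s * (b + c(-1, 1) * q * se)))
  structure(list(hr = exp(-s * b), ci_low = ci[1], ci_high = ci[2],
                 log_hr_per50 = NA_real_, se_per50 = NA_real_,
                 p = 2 * pnorm(-abs(b / se)), outcome = outcome,
                 scale = "per SD decrease", n = fit$n,
                 n_events = fit$n_events, fit = fit),
            class = "scaled_hr")
}

score_cox_fit <- function(cohort, scores, outcome) {
  y <- cohort_outcome(cohort, outcome)
  X <- cbind(score = as.numeric(scores), adjustment_design(cohort$data))
  fit_cox(y$time, y$event, X)
}

#' @export
print.scaled_hr <- function(x, ...) {
  cat(sprintf("%s: HR %.3f (95%% CI %.3f, %.3f) %s; n=%d, events=%d\n",
              x$outcome, x$hr, x$ci_low, x$ci_high, x$scale, x$n,
              x$n_events))
  invisible(x)
}

#' Factorial subgroup hazard ratios
#'
#' One Cox fit with indicators for the three non-reference factorial
#' groups plus the adjustment set. The reference group (higher on both
#' scores) has HR 1 by construction and heads the table.
#'
#' @param cohort an `mr_cohort`.
#' @param allocation factor from [allocate_factorial()].
#' @param outcome outcome name.
#' @return list with `table` (four rows: group, n, n_events, hr, ci_low,
#'   ci_high, p) and `fit`.
#' @export
factorial_contrasts <- function(cohort, allocation, outcome) {
  if (!all(levels(allocation) == FACTORIAL_LEVELS))
    stop2("allocation must come from allocate_factorial()")
  counts <- table(allocation)
  if (any(counts == 0))
    stop2("empty factorial group(s): ",
          paste(names(counts)[counts == 0], collapse = ", "))
  y <- cohort_outcome(cohort, outcome)
  ind <- vapply(FACTORIAL_LEVELS[-1], function(g) as.numeric(allocation == g),
                numeric(length(allocation)))
  X <- cbind(ind, adjustment_design(cohort$data))
  fit <- fit_cox(y$time, y$event, X)
  tf <- tidy_fit(fit)
  rows <- tf[match(FACTORIAL_LEVELS[-1], tf$term), ]
  tab <- data.frame(
    group = FACTORIAL_LEVELS,
    n = as.integer(counts[FACTORIAL_LEVELS]),
    n_events = vapply(FACTORIAL_LEVELS, function(g)
      sum(y$event[allocation == g]), numeric(1)),
    hr = c(1, exp(rows$estimate)),
    ci_low = c(NA, exp(rows$ci_low)),
    ci_high = c(NA, exp(rows$ci_high)),
    p = c(NA, rows$p), row.names = NULL
  )
  list(table = tab, fit = fit)
}

#' Continuous-score interaction test
#'
#' Cox fit with the two standardized continuous scores and their product,
#' plus the adjustment set; the interaction p-value is the Wald p on the
#' product term. Standardization decouples the product coefficient from
#' the arms' native scales; set `standardize = FALSE` for raw-scale
#' products.
#'
#' @param cohort an `mr_cohort`.
#' @param scoresA,scoresB continuous, non-constant score vectors.
#' @param outcome outcome name.
#' @param standardize standardize scores to mean 0, SD 1 first?
#' @return list of class `interaction_result`: `product_coefficient`,
#'   `se`, `p_interaction`, `outcome`, `n`, `n_events`, `fit`.
#' @export
interaction_test <- function(cohort, scoresA, scoresB, outcome,
                             standardize = TRUE) {
  a <- as.numeric(scoresA); b <- as.numeric(scoresB)
  if (sd(a) == 0 || sd(b) == 0)
    stop2("constant score vector: interaction test undefined")
  if (standardize) { a <- as.numeric(scale(a)); b <- as.numeric(scale(b)) }
  y <- cohort_outcome(cohort, outcome)
  X <- cbind(scoreA = a, scoreB = b, product = a * b,
             adjustment_design(cohort$data))
  fit <- fit_cox(y$time, y$event, X)
  coefp <- fit$coefficients[["product"]]; sep <- fit$se[["product"]]
  structure(list(product_coefficient = coefp, se = sep,
                 p_interaction = 2 * pnorm(-abs(coefp / sep)),
                 outcome = outcome, n = fit$n, n_events = fit$n_events,
                 converged = fit$converged, fit = fit),
            class = "interaction_result")
}

#' Dichotomized 2x2 interaction test
#'
#' The inefficient comparator: Cox fit with the two lower-group indicators
#' and their product. Provided for the power comparison against the
#' continuous product test.
#'
#' @inheritParams interaction_test
#' @return list of class `interaction_result`.
#' @export
interaction_test_dichotomized <- function(cohort, scoresA, scoresB, outcome) {
  ga <- as.numeric(dichotomize(as.numeric(scoresA)) == "lower")
  gb <- as.numeric(dichotomize(as.numeric(scoresB)) == "lower")
  y <- cohort_outcome(cohort, outcome)
  X <- cbind(lowerA = ga, lowerB = gb, product = ga * gb,
             adjustment_design(cohort$data))
  fit <- fit_cox(y$time, y$event, X)
  coefp <- fit$coefficients[["product"]]; sep <- fit$se[["product"]]
  structure(list(product_coefficient = coefp, se = sep,
                 p_interaction = 2 * pnorm(-abs(coefp / sep)),
                 outcome = outcome, n = fit$n, n_events = fit$n_events,
                 converged = fit$converged, fit = fit),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("Interaction (%s): coef %.4f (se %.4f), p = %.4g\n",
              x$outcome, x$product_coefficient, x$se, x$p_interaction))
  invisible(x)
}

#' First-event composite outcome
#'
#' Builds a composite endpoint (e.g. 3- or 4-point MACE) from component
#' outcomes: the composite event occurs if any component does, at the
#' earliest component event time; otherwise follow-up is censored at the
#' shortest component censoring time.
#'
#' @param cohort an `mr_cohort`.
#' @param components character vector of two or more outcome names.
#' @param name name for the new outcome (adds `time_<name>`,
#'   `event_<name>` columns).
#' @return the cohort with the composite columns added.
#' @export
composite_outcome <- function(cohort, components, name) {
  if (length(components) < 2) stop2("need at least 2 component outcomes")
  comp <- lapply(components, function(o) cohort_outcome(cohort, o))
  n <- nrow(cohort$data)
  if (any(vapply(comp, function(y) length(y$time), integer(1)) != n))
    stop2("component outcome lengths mismatch")
  ev_times <- vapply(comp, function(y) ifelse(y$event == 1, y$time, Inf),
                     numeric(n))
  all_times <- vapply(comp, `[[`, numeric(n), "time")
  any_event <- apply(ev_times, 1L, min) < Inf
  time <- ifelse(any_event, apply(ev_times, 1L, min),
                 apply(all_times, 1L, min))
  cohort$data[[paste0("time_", name)]] <- time
  cohort$data[[paste0("event_", name)]] <- as.integer(any_event)
  cohort
}
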