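#' Options controlling the Cox partial-likelihood maximizer
#'
#' @param max_iter maximum Newton-Raphson iterations.
#' @param grad_tol convergence when `max(abs(gradient)) < grad_tol`.
#' @param step_tol convergence when `max(abs(step)) < step_tol`.
#' @param max_halvings step-halvings allowed per iteration when a step would
#'   decrease the log partial likelihood.
#' @param coef_bound `|beta|` beyond which the likelihood is treated as
#'   monotone (perfect separation) and the fit flagged non-converged.
#' @return list of options for [fit_cox()].
#' @export
cox_options <- function(max_iter = 50L, grad_tol = 1e-8, step_tol = 1e-10,
                        max_halvings = 20L, coef_bound = 15) {
  list(max_iter = as.integer(max_iter), grad_tol = grad_tol,
       step_tol = step_tol, max_halvings = as.integer(max_halvings),
       coef_bound = coef_bound)
}

#' Cox proportional-hazards regression (Breslow ties, Newton-Raphson)
#'
#' Maximizes the Breslow-approximation log partial likelihood by
#' Newton-Raphson starting at \eqn{\beta = 0}, with step-halving whenever a
#' full step would decrease the likelihood. Standard errors come from the
#' inverse observed information at the maximum. A monotone likelihood
#' (perfect separation) is flagged via `converged = FALSE`, never silently.
#'
#' @param time follow-up times, all > 0.
#' @param event event indicators in `{0, 1}`; at least one event required.
#' @param design numeric covariate matrix (no intercept: the Cox partial
#'   likelihood absorbs it into the baseline hazard).
#' @param options see [cox_options()].
#' @return an object of class `cox_fit`: `coefficients`, `se`, `loglik`
#'   (maximized log partial likelihood), `loglik_null`, `n`, `n_events`,
#'   `iterations`, `converged`.
#' @export
fit_cox <- function(time, event, design, options = cox_options()) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  if (length(time) != n || length(event) != n)
    stop2("time, event and design must have matching lengths")
  if (anyNA(time) || anyNA(event) || anyNA(design))
    stop2("missing values in time, event or design")
  if (any(time <= 0)) stop2("all times must be > 0")
  if (!all(event %in% c(0, 1))) stop2("event must be 0/1")
  if (sum(event) < 1) stop2("no events: cannot fit a Cox model")
  if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(p))

  qx <- qr(design)
  if (qx$rank < p) {
    bad <- colnames(design)[qx$pivot[(qx$rank + 1L):p]]
    stop2("design is rank deficient; collinear column(s): ",
          paste(bad, collapse = ", "))
  }

  # sort by decreasing time; center columns for numerical conditioning
  # (centering shifts eta by a constant, which cancels in the partial
  # likelihood, so coefficients and information are unchanged)
  ord <- order(time, decreasing = TRUE)
  ctr <- colMeans(design)
  Xs <- sweep(design[ord, , drop = FALSE], 2L, ctr)
  ts <- time[ord]
  ev <- as.integer(event[ord])

  beta <- rep(0, p)
  d <- .cox_breslow_deriv(Xs, ts, ev, beta)
  ll <- d$loglik
  loglik_null <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < options$max_iter) {
    iter <- iter + 1L
    if (max(abs(d$gradient)) < options$grad_tol) { converged <- TRUE; break }
    step <- tryCatch(solve(d$information, d$gradient),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # line search on the cheap likelihood-only path; tolerance relative to
    # |ll| so floating-point noise at the optimum never triggers halving
    ll_tol <- 1e-9 * (abs(ll) + 1)
    new_beta <- beta + step
    new_ll <- .cox_breslow_loglik(Xs, ts, ev, new_beta)
    h <- 0L
    while (new_ll < ll - ll_tol && h < options$max_halvings) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- .cox_breslow_loglik(Xs, ts, ev, new_beta)
      h <- h + 1L
    }
    small_step <- max(abs(step)) < options$step_tol
    beta <- new_beta
    d <- .cox_breslow_deriv(Xs, ts, ev, beta)
    ll <- d$loglik
    if (small_step) {
      converged <- max(abs(d$gradient)) < sqrt(options$grad_tol)
      break
    }
  }
  if (max(abs(d$gradient)) < options$grad_tol) converged <- TRUE
  if (any(abs(beta) > options$coef_bound)) converged <- FALSE
  vcov <- tryCatch(solve(d$information), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <- colnames(design)
  structure(list(coefficients = beta, se = se, loglik = d$loglik,
                 loglik_null = loglik_null, vcov = vcov,
                 n = n, n_events = sum(ev), iterations = iter,
                 converged = converged),
            class = "cox_fit")
}

#' Log partial likelihood of a Cox model at a fixed coefficient vector
#'
#' Evaluates the Breslow log partial likelihood without fitting; used for
#' profile checks and by the grid-search oracle in the test-suite.
#'
#' @inheritParams fit_cox
#' @param beta coefficient vector.
#' @return scalar log partial likelihood.
#' @export
cox_loglik <- function(time, event, design, beta) {
  design <- as.matrix(design)
  ord <- order(time, decreasing = TRUE)
  .cox_breslow_deriv(design[ord, , drop = FALSE], time[ord],
                     as.integer(event[ord]), beta)$loglik
}

#' Score test statistic at beta = 0
#'
#' \eqn{U(0)' I(0)^{-1} U(0)}; with a single binary covariate and no
#' censoring this equals the log-rank chi-squared statistic.
#'
#' @inheritParams fit_cox
#' @return scalar chi-squared statistic.
#' @export
cox_score_test <- function(time, event, design) {
  design <- as.matrix(design)
  ord <- order(time, decreasing = TRUE)
  d <- .cox_breslow_deriv(design[ord, , drop = FALSE], time[ord],
                          as.integer(event[ord]), rep(0, ncol(design)))
  as.numeric(crossprod(d$gradient, solve(d$information, d$gradient)))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit: n =", x$n, ", events =", x$n_events,
      ", iterations =", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(tidy_fit(x), digits = 4)
  invisible(x)
}
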