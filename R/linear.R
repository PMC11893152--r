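#' Ordinary least squares with Wald inference
#'
#' Fits \eqn{y = X\beta + \epsilon} by QR-decomposed least squares. Standard
#' errors are \eqn{\sqrt{\hat\sigma^2 [(X'X)^{-1}]_{jj}}} with
#' \eqn{\hat\sigma^2 = RSS/(n - p)}. The design must be full rank and must
#' include its own intercept column if one is wanted.
#'
#' @param y numeric response vector.
#' @param design numeric matrix, `n x p`, with column names.
#' @return an object of class `linear_fit`: list with `coefficients`,
#'   `se`, `residual_variance`, `residuals`, `n`, `p`.
#' @export
fit_linear <- function(y, design) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  if (length(y) != n) stop2("length(y) must equal nrow(design)")
  if (anyNA(y) || anyNA(design)) stop2("missing values in y or design")
  if (n <= p) stop2("need n > p to fit ", p, " coefficients on ", n, " rows")
  if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(p))
  qx <- qr(design)
  if (qx$rank < p) {
    bad <- colnames(design)[qx$pivot[(qx$rank + 1L):p]]
    stop2("design is rank deficient; collinear column(s): ",
          paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qx, y)
  res <- y - design %*% coef
  rss <- sum(res^2)
  rv <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(rv * diag(xtx_inv))
  names(se) <- names(coef)
  structure(list(coefficients = coef, se = se, residual_variance = rv,
                 residuals = as.numeric(res), n = n, p = p),
            class = "linear_fit")
}

#' Wald z test and 95% confidence interval
#'
#' @param coef estimate(s).
#' @param se standard error(s), all > 0.
#' @param level confidence level (default 0.95).
#' @return data.frame with `estimate`, `se`, `z`, `p`, `ci_low`, `ci_high`.
#' @export
wald <- function(coef, se, level = 0.95) {
  if (any(!is.finite(se)) || any(se <= 0)) stop2("se must be finite and > 0")
  z <- coef / se
  q <- qnorm(1 - (1 - level) / 2)
  data.frame(estimate = coef, se = se, z = z,
             p = 2 * pnorm(-abs(z)),
             ci_low = coef - q * se, ci_high = coef + q * se,
             row.names = names(coef))
}

#' Tidy summary of a fit as the standard output table
#'
#' The common serialization atom for every stage: one row per term with
#' estimate, SE, z, p and 95% CI.
#'
#' @param fit a `linear_fit` or `cox_fit` object.
#' @return data.frame with columns `term`, `estimate`, `se`, `z`, `p`,
#'   `ci_low`, `ci_high`.
#' @export
tidy_fit <- function(fit) {
  w <- wald(fit$coefficients, fit$se)
  cbind(data.frame(term = names(fit$coefficients)), w, row.names = NULL)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear fit: n =", x$n, ", p =", x$p,
      ", residual variance =", signif(x$residual_variance, 5), "\n")
  print(tidy_fit(x), digits = 4)
  invisible(x)
}
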