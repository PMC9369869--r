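#' Polynomial quantile regression by iteratively reweighted least squares
#'
#' Fits the tau-th conditional quantile of `values` as a raw polynomial in
#' `ages`, minimizing the pinball (check) loss
#' \deqn{\sum_i \rho_\tau(y_i - \beta_0 - \beta_1 a_i - \dots -
#'   \beta_d a_i^d), \quad \rho_\tau(r) = r(\tau - 1\{r < 0\}).}
#' The solver is Schlossmacher-style IRLS: weights
#' `|tau - 1{r < 0}| / max(|r|, eps)` with `eps = 1e-6`, iterated until the
#' maximum coefficient change falls below `1e-8`, the relative decrease of
#' the pinball objective falls below `1e-10` (late iterations only polish
#' residuals already at the `eps` floor), or `maxit` iterations.
#'
#' @param values Numeric response (index values).
#' @param ages Numeric covariate (years); must not be constant when
#'   `degree >= 1`.
#' @param tau Quantile level in (0, 1).
#' @param degree Polynomial degree (default 2).
#' @param maxit Iteration cap (default 500; convergence is linear, and a few
#'   hundred iterations are typically needed for the 1e-8 tolerance at
#'   n in the thousands).
#' @return A `"quantile_fit"` with fields `tau`, `degree`, `coefficients`
#'   (length degree+1, raw polynomial basis `1, age, age^2, ...`),
#'   `converged`, `n_iter`.
#' @export
fit_quantile_curve <- function(values, ages, tau, degree = 2, maxit = 500L) {
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  if (length(values) != length(ages)) stop("values and ages lengths differ")
  n <- length(values)
  if (n < 10 * (degree + 1)) {
    stop("need at least ", 10 * (degree + 1), " observations for degree ",
         degree)
  }
  if (degree >= 1 && diff(range(ages)) == 0) {
    stop("ages are degenerate (all equal); cannot fit degree >= 1")
  }
  X <- stats::poly(ages, degree = max(degree, 1), raw = TRUE, simple = TRUE)
  X <- cbind(1, X[, seq_len(degree), drop = FALSE])
  eps <- 1e-6
  beta <- qr.coef(qr(X), values)  # LS start
  beta[is.na(beta)] <- 0
  pinball <- function(b) {
    r <- values - drop(X %*% b)
    sum(r * (tau - (r < 0)))
  }
  converged <- FALSE
  iter <- 0L
  old_loss <- pinball(beta)
  for (iter in seq_len(maxit)) {
    r <- values - drop(X %*% beta)
    w <- abs(tau - (r < 0)) / pmax(abs(r), eps)
    fit <- stats::lm.wfit(X, values, w)
    new_beta <- fit$coefficients
    new_beta[is.na(new_beta)] <- 0
    new_loss <- pinball(new_beta)
    if (max(abs(new_beta - beta)) < 1e-8 ||
        abs(old_loss - new_loss) < 1e-10 * max(old_loss, 1)) {
      beta <- new_beta
      converged <- TRUE
      break
    }
    beta <- new_beta
    old_loss <- new_loss
  }
  structure(
    list(tau = tau, degree = degree,
         coefficients = unname(beta),
         converged = converged, n_iter = iter),
    class = "quantile_fit"
  )
}

#' Evaluate a fitted quantile curve
#' @param object A `"quantile_fit"`.
#' @param newdata Ages at which to evaluate.
#' @param ... Unused.
#' @return Fitted quantile values.
#' @export
predict.quantile_fit <- function(object, newdata, ...) {
  drop(outer(newdata, 0:object$degree, `^`) %*% object$coefficients)
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Quantile fit: tau = %.2f, degree %d, %s in %d iterations\n",
              x$tau, x$degree,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("  coefficients:", signif(x$coefficients, 6), "\n")
  invisible(x)
}

#' Age-standardize values via quantile-regression residuals
#'
#' Fits the conditional 25th, 50th and 75th percentile curves of `values`
#' against `ages` (polynomial quantile regression, [fit_quantile_curve()])
#' and returns the standardized residuals
#' \deqn{z_i = \frac{y_i - \hat q_{0.5}(a_i)}
#'   {(\hat q_{0.75}(a_i) - \hat q_{0.25}(a_i)) / 1.349},}
#' i.e. value minus fitted median, scaled by the normal-consistent fitted
#' IQR. These residuals represent age-adjusted index values, an alternative
#' to LMS-type centile standardization without a skewness parameter.
#'
#' @inheritParams fit_quantile_curve
#' @param degree Polynomial degree for all three quantile fits (default 2).
#' @return An `"age_standardized"` object: list with `z` (per-subject
#'   standardized residual), `location_fit`, `q1_fit`, `q3_fit`
#'   (`"quantile_fit"` objects) and `degree`.
#' @export
standardize_by_age <- function(values, ages, degree = 2) {
  if (diff(range(values)) == 0) {
    stop("all values identical: zero scale, cannot standardize")
  }
  q1_fit <- fit_quantile_curve(values, ages, tau = 0.25, degree = degree)
  loc_fit <- fit_quantile_curve(values, ages, tau = 0.50, degree = degree)
  q3_fit <- fit_quantile_curve(values, ages, tau = 0.75, degree = degree)
  grid <- sort(unique(c(ages, seq(min(ages), max(ages), length.out = 101))))
  iqr_grid <- predict(q3_fit, grid) - predict(q1_fit, grid)
  if (min(iqr_grid) <= 0) {
    stop("fitted quantile curves cross on the observed age range ",
         "(q75 < q25); try a lower polynomial degree")
  }
  scale <- (predict(q3_fit, ages) - predict(q1_fit, ages)) / 1.349
  z <- (values - predict(loc_fit, ages)) / scale
  structure(
    list(z = z, location_fit = loc_fit, q1_fit = q1_fit, q3_fit = q3_fit,
         degree = degree),
    class = "age_standardized"
  )
}

#' @export
print.age_standardized <- function(x, ...) {
  cat(sprintf(
    "Age-standardized values: n = %d, degree %d, median(z) = %.3f, sd(z) = %.3f\n",
    length(x$z), x$degree, stats::median(x$z), stats::sd(x$z)
  ))
  invisible(x)
}
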