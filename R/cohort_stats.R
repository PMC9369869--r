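#' Flag extreme values on the z-score scale
#'
#' Flags observations whose absolute z-score `|x - mean| / sd` exceeds
#' `cutoff_sds` (default 4.5). Only flags are returned; whether to exclude
#' is the caller's decision. With zero variance nothing can be flagged and a
#' warning is issued.
#'
#' @param values Numeric vector (length >= 3).
#' @param cutoff_sds Z-score cutoff (default 4.5).
#' @return Logical vector of flags.
#' @export
outlier_screen <- function(values, cutoff_sds = 4.5) {
  if (length(values) < 3) stop("need at least 3 values")
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero variance: no outliers can be flagged")
    return(rep(FALSE, length(values)))
  }
  abs(values - mean(values)) / s > cutoff_sds
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) comparison
#'
#' Two-tailed Mann-Whitney U test with midranks for ties, the tie- and
#' continuity-corrected normal approximation, reported alongside the group
#' medians and IQRs.
#'
#' @param x,y Nonempty numeric samples.
#' @param variable Label carried into the result.
#' @return A `"group_comparison"`: list with `variable`, `test`
#'   (`"wilcoxon_ranksum"`), `statistic` (U for the first sample),
#'   `p_value`, and per-group `median`/`q1`/`q3`.
#' @export
ranksum_test <- function(x, y, variable = "value") {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ht <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                           correct = TRUE)
  structure(
    list(
      variable = variable, test = "wilcoxon_ranksum",
      statistic = unname(ht$statistic), p_value = ht$p.value,
      groups = data.frame(
        group = c("x", "y"),
        n = c(length(x), length(y)),
        median = c(stats::median(x), stats::median(y)),
        q1 = c(stats::quantile(x, 0.25, names = FALSE),
               stats::quantile(y, 0.25, names = FALSE)),
        q3 = c(stats::quantile(x, 0.75, names = FALSE),
               stats::quantile(y, 0.75, names = FALSE))
      )
    ),
    class = "group_comparison"
  )
}

#' Kruskal-Wallis comparison of two or more groups
#'
#' Nonparametric one-way ANOVA: tie-corrected H statistic with a chi-square
#' p-value on k-1 degrees of freedom.
#'
#' @param groups List of >= 2 nonempty numeric vectors.
#' @param variable Label carried into the result.
#' @return A `"group_comparison"` with `test = "kruskal_wallis"`.
#' @export
kruskal_wallis <- function(groups, variable = "value") {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least 2 groups")
  }
  if (any(!lengths(groups))) stop("all groups must be nonempty")
  ht <- stats::kruskal.test(groups)
  gn <- if (is.null(names(groups))) {
    paste0("g", seq_along(groups))
  } else {
    names(groups)
  }
  structure(
    list(
      variable = variable, test = "kruskal_wallis",
      statistic = unname(ht$statistic), p_value = ht$p.value,
      groups = data.frame(
        group = gn,
        n = lengths(groups),
        median = vapply(groups, stats::median, numeric(1)),
        q1 = vapply(groups, stats::quantile, numeric(1), probs = 0.25),
        q3 = vapply(groups, stats::quantile, numeric(1), probs = 0.75)
      )
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %.4g, p = %.4g\n",
              x$variable, x$test, x$statistic, x$p_value))
  print.data.frame(x$groups, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a two-sided p-value from the t
#' approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom. If either variable has zero rank variance the coefficient is
#' undefined and returned as `NA` with `defined = FALSE`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`, `defined`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, defined = TRUE)
}

#' Age-adjusted logistic odds ratio for a binary exposure
#'
#' Fits `outcome ~ exposure (+ age)` by maximum-likelihood logistic
#' regression (iteratively reweighted least squares, i.e. Newton-Raphson
#' for the canonical logit link; convergence tolerance 1e-10, at most 50
#' iterations) and reports the exposure odds ratio with a Wald 95% CI and
#' Nagelkerke's pseudo-R-squared.
#'
#' Degenerate problems are detected rather than reported as numbers: a
#' one-class outcome returns `status = "not_calculable"` with reason
#' "all observations have the same response", and (quasi-)complete
#' separation (fitted probabilities numerically 0/1 with a diverging
#' exposure coefficient) returns `status = "not_calculable"` citing
#' separation.
#'
#' @param outcome Binary 0/1 (or logical) response.
#' @param exposure Binary 0/1 (or logical) exposure, e.g. an index above its
#'   Youden cutoff.
#' @param age Optional numeric covariate; when supplied the OR is
#'   age-adjusted.
#' @return A `"logistic_or"`: list with `or_point`, `ci95`, `log_or`, `se`,
#'   `p_value`, `pseudo_r2` (Nagelkerke), `n`, `status`
#'   (`"ok"`/`"not_calculable"`), `reason`.
#' @export
logistic_or <- function(outcome, exposure, age = NULL) {
  outcome <- as.integer(outcome)
  exposure <- as.integer(exposure)
  if (!all(outcome %in% 0:1) || !all(exposure %in% 0:1)) {
    stop("outcome and exposure must be binary 0/1")
  }
  n <- length(outcome)
  if (n < 20) stop("need at least 20 observations")
  not_calc <- function(reason) {
    structure(
      list(or_point = NA_real_, ci95 = c(NA_real_, NA_real_),
           log_or = NA_real_, se = NA_real_, p_value = NA_real_,
           pseudo_r2 = NA_real_, n = n,
           status = "not_calculable", reason = reason),
      class = "logistic_or"
    )
  }
  if (length(unique(outcome)) < 2L) {
    return(not_calc("all observations have the same response"))
  }
  if (length(unique(exposure)) < 2L) {
    return(not_calc("exposure has a single level"))
  }
  df <- data.frame(outcome = outcome, exposure = exposure)
  form <- outcome ~ exposure
  if (!is.null(age)) {
    df$age <- age
    form <- outcome ~ exposure + age
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-10, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  b <- stats::coef(fit)["exposure"]
  se <- sqrt(diag(stats::vcov(fit)))["exposure"]
  if ((sep_warn && abs(b) > 10) || abs(b) > 15 || se > 100) {
    return(not_calc("complete or quasi-complete separation"))
  }
  dev0 <- fit$null.deviance
  dev1 <- fit$deviance
  r2_cs <- 1 - exp((dev1 - dev0) / n)
  r2 <- r2_cs / (1 - exp(-dev0 / n))
  structure(
    list(
      or_point = exp(unname(b)),
      ci95 = exp(unname(b) + c(-1, 1) * stats::qnorm(0.975) * unname(se)),
      log_or = unname(b), se = unname(se),
      p_value = 2 * stats::pnorm(-abs(unname(b) / unname(se))),
      pseudo_r2 = r2, n = n, status = "ok", reason = NULL
    ),
    class = "logistic_or"
  )
}

#' @export
print.logistic_or <- function(x, ...) {
  if (x$status == "not_calculable") {
    cat("Logistic OR: n.c. (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "Logistic OR: %.2f (95%% CI %.2f-%.2f), p = %.3g, Nagelkerke R2 = %.3f, n = %d\n",
      x$or_point, x$ci95[1], x$ci95[2], x$p_value, x$pseudo_r2, x$n
    ))
  }
  invisible(x)
}
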