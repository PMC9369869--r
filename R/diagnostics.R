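# placement values: for each positive, the fraction of negatives it beats
# (ties count 1/2); and symmetrically for negatives
placement_values <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_pos) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class; ROC is undefined")
  }
  labels
}

#' Empirical ROC curve with DeLong AUC standard error
#'
#' Sweeps the decision rule `score >= threshold` over all distinct observed
#' score values (plus a +Inf sentinel), recording sensitivity and false
#' positive rate at each threshold. The AUC is the trapezoidal area, which
#' with midrank tie handling equals the Mann-Whitney statistic
#' P(X_pos > X_neg) + 0.5 P(X_pos = X_neg). The AUC standard error and 95%
#' CI use DeLong's placement-value variance estimator.
#'
#' @param scores Numeric predictor; higher = more likely positive.
#' @param labels Binary 0/1 outcome (both classes must be present).
#' @return A `"roc_curve"`: list with `thresholds` (decreasing, `Inf`
#'   first), `sens`, `fpr` (nondecreasing, from (0,0) to (1,1)), `auc`,
#'   `auc_se`, `auc_ci95`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels)) stop("scores/labels lengths differ")
  if (anyNA(scores)) stop("scores contain NA")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  # counts of positives/negatives at each distinct score, swept high to low
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  y_sorted <- labels[ord]
  grp <- cumsum(!duplicated(s_sorted))
  tp <- c(0, cumsum(tapply(y_sorted, grp, sum)))
  fp <- c(0, cumsum(tapply(1 - y_sorted, grp, sum)))
  pv <- placement_values(scores, labels)
  auc_var <- stats::var(pv$v10) / n1 + stats::var(pv$v01) / n0
  se <- sqrt(auc_var)
  ci <- pmin(pmax(pv$auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  structure(
    list(thresholds = thr, sens = unname(tp) / n1, fpr = unname(fp) / n0,
         auc = pv$auc, auc_se = se, auc_ci95 = ci, n_pos = n1, n_neg = n0),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "ROC curve: %d positives / %d negatives, AUC = %.3f (95%% CI %.3f-%.3f)\n",
    x$n_pos, x$n_neg, x$auc, x$auc_ci95[1], x$auc_ci95[2]
  ))
  invisible(x)
}

#' DeLong test comparing two paired AUCs
#'
#' Compares the AUCs of two predictors measured on the same subjects using
#' DeLong's nonparametric covariance of the placement values, with a
#' two-sided normal p-value. Antisymmetric in the two predictors; a
#' rank-preserving transform of a predictor leaves its AUC (and the test)
#' unchanged.
#'
#' @param scores_a,scores_b Paired numeric predictors.
#' @param labels Binary 0/1 outcome.
#' @return List with `auc_a`, `auc_b`, `delta`, `se`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    stop("scores and labels must have equal lengths")
  }
  pa <- placement_values(scores_a, labels)
  pb <- placement_values(scores_b, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- pa$auc - pb$auc
  if (var_delta <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
       se = sqrt(max(var_delta, 0)), z = z, p = p)
}

#' Youden-optimal cutoff from a ROC curve
#'
#' Maximizes the Youden index J = sensitivity + specificity - 1 over the
#' swept thresholds; ties are broken by the smallest threshold attaining
#' the maximum.
#'
#' @param roc A [roc_curve()].
#' @return List with `cutoff` (a finite threshold) and `J`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  finite <- is.finite(roc$thresholds)
  j <- roc$sens[finite] - roc$fpr[finite]
  thr <- roc$thresholds[finite]
  jmax <- max(j)
  cutoff <- min(thr[j >= jmax - 1e-12])
  list(cutoff = cutoff, J = jmax)
}

wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(center - half, center + half)
}

wald_ci <- function(p, n) {
  half <- stats::qnorm(0.975) * sqrt(p * (1 - p) / n)
  c(p - half, p + half)
}

#' Diagnostic metrics at a cutoff
#'
#' Builds the 2x2 table for the rule `score >= cutoff` and reports
#' sensitivity, specificity, PPV and NPV with 95% confidence intervals, and
#' the positive/negative likelihood ratios PLR = sens/(1-spec),
#' NLR = (1-sens)/spec computed from the unrounded proportions.
#'
#' Two CI conventions are offered: `"wilson_subgroup"` (Wilson score
#' interval on each metric's own denominator — the statistically standard
#' choice) and `"wald_total_n"` (Wald interval `p +/- 1.96 sqrt(p(1-p)/N)`
#' with `N` the full sample size — a convention some screening reports use;
#' provided for replication).
#'
#' A metric whose denominator is empty, or a likelihood ratio whose
#' denominator proportion is 0, is returned as `NA` and named in
#' `not_calculable`.
#'
#' @param scores,labels Numeric predictor and binary 0/1 outcome.
#' @param cutoff Decision threshold (positive when `score >= cutoff`).
#' @param ci_mode `"wilson_subgroup"` (default) or `"wald_total_n"`.
#' @return A `"diagnostic_metrics"` list: `cutoff`, `table` (tp/fp/fn/tn),
#'   `sens`, `spec`, `ppv`, `npv` (each with `ci95`), `plr`, `nlr`,
#'   `ci_mode`, `not_calculable` (character).
#' @export
confusion_metrics <- function(scores, labels, cutoff,
                              ci_mode = c("wilson_subgroup", "wald_total_n")) {
  ci_mode <- match.arg(ci_mode)
  labels <- check_binary_labels(labels)
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0)
  N <- length(labels)
  nc <- character(0)
  prop <- function(x, n, name) {
    if (n == 0) {
      nc <<- c(nc, name)
      return(list(est = NA_real_, ci95 = c(NA_real_, NA_real_)))
    }
    p <- x / n
    ci <- if (ci_mode == "wilson_subgroup") wilson_ci(x, n) else wald_ci(p, N)
    list(est = p, ci95 = ci)
  }
  sens <- prop(tp, tp + fn, "sens")
  spec <- prop(tn, tn + fp, "spec")
  ppv <- prop(tp, tp + fp, "ppv")
  npv <- prop(tn, tn + fn, "npv")
  plr <- if (!is.na(spec$est) && spec$est < 1 && !is.na(sens$est)) {
    sens$est / (1 - spec$est)
  } else {
    nc <- c(nc, "plr")
    NA_real_
  }
  nlr <- if (!is.na(spec$est) && spec$est > 0 && !is.na(sens$est)) {
    (1 - sens$est) / spec$est
  } else {
    nc <- c(nc, "nlr")
    NA_real_
  }
  structure(
    list(cutoff = cutoff, table = c(tp = tp, fp = fp, fn = fn, tn = tn),
         sens = sens, spec = spec, ppv = ppv, npv = npv,
         plr = plr, nlr = nlr, ci_mode = ci_mode, not_calculable = nc),
    class = "diagnostic_metrics"
  )
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  fmt <- function(m) {
    if (is.na(m$est)) return("n.c.")
    sprintf("%.3f (%.3f-%.3f)", m$est, m$ci95[1], m$ci95[2])
  }
  cat(sprintf("Diagnostic metrics at cutoff %.4g (%s CIs)\n",
              x$cutoff, x$ci_mode))
  cat("  sensitivity:", fmt(x$sens), "\n")
  cat("  specificity:", fmt(x$spec), "\n")
  cat("  PPV:        ", fmt(x$ppv), "\n")
  cat("  NPV:        ", fmt(x$npv), "\n")
  cat(sprintf("  PLR: %s   NLR: %s\n",
              ifelse(is.na(x$plr), "n.c.", sprintf("%.1f", x$plr)),
              ifelse(is.na(x$nlr), "n.c.", sprintf("%.1f", x$nlr))))
  invisible(x)
}

#' Likelihood ratios from sensitivity and specificity
#'
#' PLR = sens/(1 - spec), NLR = (1 - sens)/spec. Useful for checking the
#' internal consistency of a published sensitivity/specificity/likelihood
#' ratio table.
#'
#' @param sens,spec Proportions in `[0, 1]`.
#' @return List with `plr` and `nlr` (`NA` where the denominator is 0).
#' @export
likelihood_ratios <- function(sens, spec) {
  list(
    plr = ifelse(spec < 1, sens / (1 - spec), NA_real_),
    nlr = ifelse(spec > 0, (1 - sens) / spec, NA_real_)
  )
}

#' Age-by-sex trend of the Youden-optimal cutoff
#'
#' For each sex and completed year of age, estimates the Youden cutoff of
#' `scores` for `labels` within the stratum, with a class-stratified
#' bootstrap percentile 95% band, and tests the per-age sex difference by
#' bootstrapping the difference of cutoffs. Strata with fewer than `min_n`
#' subjects or a single outcome class are flagged (`estimable = FALSE`)
#' and excluded from the trend rather than silently estimated.
#'
#' Deterministic given `seed`; the caller's RNG state is restored.
#'
#' @param scores,labels,ages,sex Parallel subject-level vectors.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param min_n Minimum stratum size (default 30).
#' @param seed Integer seed.
#' @return A `"cutoff_trend"` data.frame with columns `sex`, `age`, `n`,
#'   `n_pos`, `cutoff`, `lo95`, `hi95`, `estimable`, and attribute
#'   `sex_diff`: data.frame of per-age bootstrap p-values for the
#'   male-female cutoff difference.
#' @export
cutoff_trend <- function(scores, labels, ages, sex, n_boot = 1000,
                         min_n = 30, seed = 1L) {
  labels <- check_binary_labels(labels)
  n <- length(scores)
  stopifnot(length(labels) == n, length(ages) == n, length(sex) == n)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  yr <- floor(ages)
  all_ages <- sort(unique(yr))
  rows <- list()
  boots <- list()
  for (s in c("M", "F")) {
    for (a in all_ages) {
      idx <- which(sex == s & yr == a)
      n_str <- length(idx)
      n_pos <- sum(labels[idx] == 1)
      estimable <- n_str >= min_n && n_pos >= 1 && n_pos < n_str
      cutoff <- lo <- hi <- NA_real_
      if (estimable) {
        cutoff <- youden_cutoff(roc_curve(scores[idx], labels[idx]))$cutoff
        pos_i <- idx[labels[idx] == 1]
        neg_i <- idx[labels[idx] == 0]
        bc <- vapply(seq_len(n_boot), function(b) {
          bi <- c(sample(pos_i, length(pos_i), replace = TRUE),
                  sample(neg_i, length(neg_i), replace = TRUE))
          youden_cutoff(roc_curve(scores[bi], labels[bi]))$cutoff
        }, numeric(1))
        qs <- stats::quantile(bc, c(0.025, 0.975), names = FALSE, type = 7)
        lo <- qs[1]
        hi <- qs[2]
        boots[[paste(s, a)]] <- bc
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, age = a, n = n_str, n_pos = n_pos, cutoff = cutoff,
        lo95 = lo, hi95 = hi, estimable = estimable,
        stringsAsFactors = FALSE
      )
    }
  }
  trend <- do.call(rbind, rows)
  diffs <- lapply(all_ages, function(a) {
    bm <- boots[[paste("M", a)]]
    bf <- boots[[paste("F", a)]]
    if (is.null(bm) || is.null(bf)) {
      return(data.frame(age = a, diff = NA_real_, p_value = NA_real_))
    }
    d <- bm - bf
    p <- 2 * min((1 + sum(d <= 0)) / (n_boot + 1),
                 (1 + sum(d >= 0)) / (n_boot + 1))
    data.frame(age = a, diff = mean(d), p_value = min(p, 1))
  })
  attr(trend, "sex_diff") <- do.call(rbind, diffs)
  class(trend) <- c("cutoff_trend", "data.frame")
  trend
}

#' @export
print.cutoff_trend <- function(x, ...) {
  cat("Youden cutoff trend by sex and age\n")
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}
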