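#' Cohort simulation specification
#'
#' Bundles everything the synthetic-cohort generator needs: the cohort size
#' and sex split, the age range, per-sex marginal summaries (median and
#' quartiles, on the measurement scale) for every generated variable, and the
#' latent Gaussian-copula correlation matrix that couples them.
#'
#' Each positive measurement is simulated from a log-normal marginal matched
#' to its `{median, q1, q3}` (location = log median; log-scale spread =
#' log-IQR / (2 * qnorm(0.75))); age is uniform on `age_range`. Dependence
#' comes from a Gaussian copula over the variables in
#' [cohort_variables()] order (age first).
#'
#' @param n_total Number of subjects to generate.
#' @param frac_male Proportion of males in `[0, 1]`.
#' @param age_range Length-2 numeric, years; default `c(10, 17.99)`.
#' @param marginal_params Named list with elements `M` and `F`, each a
#'   data.frame with columns `variable`, `median`, `q1`, `q3` covering every
#'   non-age variable in [cohort_variables()]. Defaults to the frozen
#'   severe-obesity cohort summaries (see [default_marginals()]).
#' @param copula_correlation Symmetric positive semi-definite correlation
#'   matrix with unit diagonal, dimnames = [cohort_variables()]. Defaults to
#'   the frozen calibrated matrix (see [default_copula()]).
#' @param seed Integer seed; the generator is deterministic given the spec.
#'
#' @return An object of class `"cohort_spec"`.
#' @seealso [generate_cohort()], [generate_reference()]
#' @export
cohort_spec <- function(n_total = 1065L,
                        frac_male = 502 / 1065,
                        age_range = c(10, 17.99),
                        marginal_params = default_marginals(),
                        copula_correlation = default_copula(),
                        seed = 1L) {
  spec <- structure(
    list(
      n_total = as.integer(n_total),
      frac_male = frac_male,
      age_range = as.numeric(age_range),
      marginal_params = marginal_params,
      copula_correlation = copula_correlation,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

#' Variables simulated by the cohort generator, in copula order
#' @return Character vector of variable names; `age` is always first.
#' @export
cohort_variables <- function() {
  c("age", "height", "weight", "wc", "sbp", "dbp",
    "glucose", "tg", "hdl", "ldl", "insulin")
}

#' Default per-sex marginal summaries
#'
#' Median and quartiles on the measurement scale for each generated variable,
#' per sex, emulating a hospital cohort of children and adolescents with
#' severe obesity (ages 10-17, BMI-SDS >= 3). Blood-pressure and height
#' summaries are lightly de-heaped: clinical BP is recorded to the nearest
#' 2 mmHg and height charted coarsely, which produces degenerate printed
#' quartiles (q1 = median or q3 = median); the defaults replace those with
#' continuous values whose implied exceedance frequencies match the reported
#' component frequencies.
#'
#' Units: height m, weight kg, wc cm, sbp/dbp mmHg, glucose/tg/hdl/ldl mg/dL,
#' insulin uU/mL.
#' @return Named list with data.frames `M` and `F`.
#' @export
default_marginals <- function() {
  mk <- function(...) {
    df <- as.data.frame(rbind(...), stringsAsFactors = FALSE)
    names(df) <- c("variable", "median", "q1", "q3")
    df$median <- as.numeric(df$median)
    df$q1 <- as.numeric(df$q1)
    df$q3 <- as.numeric(df$q3)
    df
  }
  list(
    M = mk(
      c("height", 1.70, 1.63, 1.77),
      c("weight", 110.5, 93.1, 126.9),
      c("wc", 120, 110, 129),
      c("sbp", 130, 120, 140),
      c("dbp", 77, 70, 83),
      c("glucose", 80, 76, 84),
      c("tg", 93, 71, 125),
      c("hdl", 41, 35, 47),
      c("ldl", 106.5, 87, 126),
      c("insulin", 15.3, 10, 20.1)
    ),
    F = mk(
      c("height", 1.61, 1.56, 1.66),
      c("weight", 101.8, 93, 114),
      c("wc", 115, 106, 124),
      c("sbp", 122, 116, 132),
      c("dbp", 77, 70, 83),
      c("glucose", 79, 73, 83),
      c("tg", 88, 68, 113),
      c("hdl", 44, 37, 50),
      c("ldl", 102, 84, 122),
      c("insulin", 14.5, 10, 19.7)
    )
  )
}

#' Default latent correlation matrix for the Gaussian copula
#'
#' Encodes the dependence structure the analysis assumes: strong positive
#' weight-WC-height coupling, growth with age, moderate BP-adiposity
#' coupling, a negative TG-HDL association, and insulin tracking adiposity
#' and TG. Calibrated once against the target component frequencies of the
#' emulated cohort and frozen.
#'
#' @return Correlation matrix over [cohort_variables()].
#' @export
default_copula <- function() {
  v <- cohort_variables()
  R <- diag(length(v))
  dimnames(R) <- list(v, v)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("age", "height", 0.70)
  set_r("age", "weight", 0.45)
  set_r("age", "wc", 0.25)
  set_r("age", "sbp", 0.20)
  set_r("age", "dbp", 0.15)
  set_r("age", "glucose", 0.05)
  set_r("age", "tg", 0.12)
  set_r("age", "hdl", -0.08)
  set_r("age", "ldl", 0.05)
  set_r("age", "insulin", 0.10)
  set_r("height", "weight", 0.62)
  set_r("height", "wc", 0.40)
  set_r("height", "sbp", 0.20)
  set_r("height", "dbp", 0.10)
  set_r("height", "glucose", 0.03)
  set_r("height", "tg", 0.05)
  set_r("height", "hdl", -0.05)
  set_r("height", "insulin", 0.05)
  set_r("weight", "wc", 0.80)
  set_r("weight", "sbp", 0.30)
  set_r("weight", "dbp", 0.20)
  set_r("weight", "glucose", 0.05)
  set_r("weight", "tg", 0.15)
  set_r("weight", "hdl", -0.12)
  set_r("weight", "ldl", 0.05)
  set_r("weight", "insulin", 0.30)
  set_r("wc", "sbp", 0.30)
  set_r("wc", "dbp", 0.20)
  set_r("wc", "glucose", 0.06)
  set_r("wc", "tg", 0.18)
  set_r("wc", "hdl", -0.15)
  set_r("wc", "ldl", 0.05)
  set_r("wc", "insulin", 0.30)
  set_r("sbp", "dbp", 0.60)
  set_r("sbp", "glucose", 0.05)
  set_r("sbp", "tg", 0.15)
  set_r("sbp", "hdl", -0.15)
  set_r("sbp", "ldl", 0.05)
  set_r("sbp", "insulin", 0.10)
  set_r("dbp", "glucose", 0.03)
  set_r("dbp", "tg", 0.12)
  set_r("dbp", "hdl", -0.12)
  set_r("dbp", "ldl", 0.05)
  set_r("dbp", "insulin", 0.08)
  set_r("glucose", "tg", 0.05)
  set_r("glucose", "hdl", -0.03)
  set_r("glucose", "ldl", 0.02)
  set_r("glucose", "insulin", 0.15)
  set_r("tg", "hdl", -0.40)
  set_r("tg", "ldl", 0.15)
  set_r("tg", "insulin", 0.25)
  set_r("hdl", "ldl", 0.05)
  set_r("hdl", "insulin", -0.15)
  set_r("ldl", "insulin", 0.05)
  R
}

#' Validate a cohort_spec
#'
#' Checks the generator invariants: q1 < median < q3 for every marginal,
#' positive semi-definite copula correlation (the most negative eigenvalue is
#' named in the error when not), frac_male in `[0, 1]`, and a proper age
#' range. Called by [cohort_spec()]; exported so externally assembled specs
#' can be checked.
#'
#' @param spec A `"cohort_spec"`.
#' @return `spec`, invisibly; errors otherwise.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.na(spec$n_total) || spec$n_total < 0) {
    stop("n_total must be a non-negative integer")
  }
  if (spec$frac_male < 0 || spec$frac_male > 1) {
    stop("frac_male must lie in [0, 1]")
  }
  if (length(spec$age_range) != 2 || diff(spec$age_range) <= 0) {
    stop("age_range must be an increasing length-2 numeric")
  }
  vars <- setdiff(cohort_variables(), "age")
  for (sex in c("M", "F")) {
    mp <- spec$marginal_params[[sex]]
    if (is.null(mp)) stop("marginal_params must have elements 'M' and 'F'")
    missing_vars <- setdiff(vars, mp$variable)
    if (length(missing_vars)) {
      stop("marginal_params[['", sex, "']] missing variable(s): ",
           paste(missing_vars, collapse = ", "))
    }
    bad <- mp$variable[!(mp$q1 < mp$median & mp$median < mp$q3)]
    if (length(bad)) {
      stop("marginal_params[['", sex, "']]: need q1 < median < q3 for: ",
           paste(bad, collapse = ", "))
    }
    if (any(mp$q1 <= 0)) {
      stop("marginal_params[['", sex, "']]: quartiles must be positive")
    }
  }
  R <- spec$copula_correlation
  v <- cohort_variables()
  if (!is.matrix(R) || nrow(R) != length(v) || ncol(R) != length(v)) {
    stop("copula_correlation must be a ", length(v), "x", length(v), " matrix")
  }
  if (is.null(dimnames(R)) || !identical(rownames(R), v) ||
      !identical(colnames(R), v)) {
    stop("copula_correlation dimnames must equal cohort_variables()")
  }
  if (max(abs(R - t(R))) > 1e-12) stop("copula_correlation must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-12) {
    stop("copula_correlation must have unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop(sprintf(
      "copula_correlation is not positive semi-definite (smallest eigenvalue %.6g)",
      min(ev)
    ))
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  n_total: %d (frac_male %.3f)\n", x$n_total, x$frac_male))
  cat(sprintf("  age range: [%.2f, %.2f] years\n",
              x$age_range[1], x$age_range[2]))
  cat(sprintf("  variables: %s\n", paste(cohort_variables(), collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# log-normal parameters matched to {median, q1, q3}
lnorm_params <- function(median, q1, q3) {
  list(mu = log(median), sigma = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}
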