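#' Generate a synthetic cohort
#'
#' Draws `spec$n_total` subject records from a Gaussian copula with
#' log-normal marginals matched to the per-sex `{median, q1, q3}` summaries
#' in the spec, and a uniform age marginal on `spec$age_range`. The first
#' `round(n_total * frac_male)` records are male, the rest female. BMI is
#' never generated directly: it is derived downstream from the generated
#' weight and height, so records are internally consistent.
#'
#' The generator is deterministic given the spec (including its seed); the
#' caller's RNG state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with columns `id`, `sex`, `age`, `height_m`,
#'   `weight_kg`, `wc_cm`, `sbp`, `dbp`, `glucose_mgdl`, `tg_mgdl`,
#'   `hdl_mgdl`, `ldl_mgdl`, `insulin`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_total
  cols <- c("id", "sex", "age", "height_m", "weight_kg", "wc_cm", "sbp",
            "dbp", "glucose_mgdl", "tg_mgdl", "hdl_mgdl", "ldl_mgdl",
            "insulin")
  if (n == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 11)), cols
    ))
    return(out)
  }
  n_male <- as.integer(round(n * spec$frac_male))
  sex <- rep(c("M", "F"), times = c(n_male, n - n_male))

  vars <- cohort_variables()
  L <- t(chol_psd(spec$copula_correlation))

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
  set.seed(spec$seed)
  Z <- matrix(stats::rnorm(n * length(vars)), nrow = n) %*% t(L)
  U <- stats::pnorm(Z)
  colnames(U) <- vars

  X <- matrix(NA_real_, nrow = n, ncol = length(vars),
              dimnames = list(NULL, vars))
  X[, "age"] <- spec$age_range[1] + diff(spec$age_range) * U[, "age"]
  for (s in c("M", "F")) {
    idx <- which(sex == s)
    if (!length(idx)) next
    mp <- spec$marginal_params[[s]]
    for (v in setdiff(vars, "age")) {
      row <- mp[mp$variable == v, ]
      p <- lnorm_params(row$median, row$q1, row$q3)
      X[idx, v] <- stats::qlnorm(U[idx, v], meanlog = p$mu, sdlog = p$sigma)
    }
  }

  data.frame(
    id = sprintf("S%05d", seq_len(n)),
    sex = sex,
    age = X[, "age"],
    height_m = X[, "height"],
    weight_kg = X[, "weight"],
    wc_cm = X[, "wc"],
    sbp = X[, "sbp"],
    dbp = X[, "dbp"],
    glucose_mgdl = X[, "glucose"],
    tg_mgdl = X[, "tg"],
    hdl_mgdl = X[, "hdl"],
    ldl_mgdl = X[, "ldl"],
    insulin = X[, "insulin"],
    stringsAsFactors = FALSE
  )
}

# Cholesky of a PSD (possibly rank-deficient) correlation matrix
chol_psd <- function(R) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  ee <- eigen(R, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  t(ee$vectors %*% diag(sqrt(vals), nrow = length(vals)))
}

#' Generate a synthetic growth reference matched to a cohort spec
#'
#' Builds, for every (sex, integer age) cell on the spec's age range, an LMS
#' BMI reference and a 90th-percentile waist-circumference value such that
#' essentially every subject generated from the same spec (i) has
#' BMI-SDS >= 3 — i.e. passes the severe-obesity filter — and (ii) flags
#' abdominal obesity. The BMI reference uses a Box-Cox LMS form with a
#' negative skewness parameter (L = -1.6, S = 0.12) so that the z-scores of
#' the far-right BMI tail are compressed to the 3-4.5 range seen on real
#' pediatric charts; M rises gently with age. The WC 90th percentile rises
#' linearly with age and sits well below the generated WC distribution,
#' mirroring a cohort in which virtually all subjects exceed it.
#'
#' This is a synthetic stand-in for published growth charts, intended for
#' self-contained simulation; real (e.g. WHO) tables are user-supplied via
#' [read_reference()].
#'
#' @param spec A [cohort_spec()].
#' @return A `"growth_reference"` object (see [growth_reference()]).
#' @export
generate_reference <- function(spec) {
  validate_cohort_spec(spec)
  ages <- seq(floor(spec$age_range[1]), floor(spec$age_range[2] - 1e-9))
  L <- -1.6
  S <- 0.12
  rows <- list()
  for (s in c("M", "F")) {
    mp <- spec$marginal_params[[s]]
    wp <- lnorm_params(mp[mp$variable == "weight", "median"],
                       mp[mp$variable == "weight", "q1"],
                       mp[mp$variable == "weight", "q3"])
    hp <- lnorm_params(mp[mp$variable == "height", "median"],
                       mp[mp$variable == "height", "q1"],
                       mp[mp$variable == "height", "q3"])
    rho_wh <- spec$copula_correlation["weight", "height"]
    med_bmi <- exp(wp$mu - 2 * hp$mu)
    sigma_bmi <- sqrt(wp$sigma^2 + 4 * hp$sigma^2 -
                        4 * rho_wh * wp$sigma * hp$sigma)
    # ~0.2nd percentile of the cohort BMI distribution: the BMI at which the
    # LMS z-score equals 3, so <1% of generated subjects fall below z = 3
    bmi_lo <- med_bmi * exp(-2.9 * sigma_bmi)
    # solve ((bmi_lo/M)^L - 1)/(L*S) = 3 for M
    M_base <- bmi_lo / (1 + 3 * L * S)^(1 / L)
    wcq <- mp[mp$variable == "wc", ]
    wcp <- lnorm_params(wcq$median, wcq$q1, wcq$q3)
    # WC 90th centile track: ~0.2nd percentile of cohort WC at the oldest
    # age, decreasing linearly toward younger ages
    wc_top <- wcq$median * exp(-2.9 * wcp$sigma)
    for (a in ages) {
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s,
        age = a,
        mode = "lms",
        mean_or_M = M_base * (1 + 0.004 * (a - max(ages))),
        sd_or_S = S,
        L = L,
        wc_p90 = wc_top - 1.5 * (max(ages) - a),
        stringsAsFactors = FALSE
      )
    }
  }
  growth_reference(do.call(rbind, rows))
}

#' Growth-reference constructor
#'
#' A growth reference is a per-(sex, integer age) lookup of a BMI reference
#' — either `mode = "mean_sd"` (columns `mean_or_M` = mean, `sd_or_S` = SD)
#' or `mode = "lms"` (`mean_or_M` = M, `sd_or_S` = S, `L` = Box-Cox power) —
#' plus the 90th-percentile waist circumference `wc_p90` (cm).
#'
#' @param df Data.frame with columns `sex`, `age`, `mode`, `mean_or_M`,
#'   `sd_or_S`, `L`, `wc_p90`.
#' @return The validated data.frame with class `"growth_reference"`.
#' @export
growth_reference <- function(df) {
  needed <- c("sex", "age", "mode", "mean_or_M", "sd_or_S", "L", "wc_p90")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("growth reference missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(df$mode %in% c("mean_sd", "lms"))) {
    stop("growth reference mode must be 'mean_sd' or 'lms'")
  }
  if (any(df$sd_or_S <= 0)) stop("growth reference needs sd_or_S > 0")
  if (any(df$mode == "lms" & df$mean_or_M <= 0)) {
    stop("growth reference needs M > 0 in lms mode")
  }
  if (any(df$wc_p90 <= 0)) stop("growth reference needs wc_p90 > 0")
  if (anyDuplicated(df[c("sex", "age")])) {
    stop("growth reference has duplicated (sex, age) cells")
  }
  class(df) <- c("growth_reference", "data.frame")
  df
}

#' @export
print.growth_reference <- function(x, ...) {
  cat(sprintf("Growth reference: %d (sex, age) cells, mode %s\n",
              nrow(x), paste(unique(x$mode), collapse = "/")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# single-cell lookup; errors name the missing (sex, age)
reference_cell <- function(reference, sex, age) {
  a <- floor(age)
  i <- which(reference$sex == sex & reference$age == a)
  if (length(i) != 1L) {
    stop(sprintf("growth reference has no cell for (sex=%s, age=%d)", sex, a))
  }
  reference[i, ]
}

#' Filter a cohort to severe obesity (BMI-SDS >= 3.00)
#'
#' Computes each subject's BMI-SDS against the supplied reference and keeps
#' exactly the records with BMI-SDS >= 3.00 (inclusive), preserving order.
#'
#' @param cohort Cohort data.frame (see [generate_cohort()]).
#' @param reference A [growth_reference()] covering every (sex, floor(age))
#'   present; a missing cell is an error naming it.
#' @return The retained subset of `cohort`.
#' @export
apply_severe_obesity_filter <- function(cohort, reference) {
  if (nrow(cohort) == 0L) return(cohort)
  bmi <- compute_bmi(cohort$weight_kg, cohort$height_m)
  sds <- compute_bmi_sds(bmi, cohort$sex, cohort$age, reference)
  cohort[sds >= 3.00, , drop = FALSE]
}

#' Write / read a cohort CSV
#'
#' Plain UTF-8 CSV with header
#' `id,sex,age,height_m,weight_kg,wc_cm,sbp,dbp,glucose_mgdl,tg_mgdl,hdl_mgdl,ldl_mgdl,insulin`
#' (the last two optional on read), sex coded `M`/`F`, decimal point `.`.
#'
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @return `write_cohort`: `path` invisibly. `read_cohort`: the cohort
#'   data.frame; malformed rows raise an error citing the line number.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  needed <- c("id", "sex", "age", "height_m", "weight_kg", "wc_cm", "sbp",
              "dbp", "glucose_mgdl", "tg_mgdl", "hdl_mgdl")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("cohort file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num_cols <- setdiff(needed, c("id", "sex"))
  for (cl in num_cols) {
    bad <- which(!is.finite(df[[cl]]) | df[[cl]] <= 0)
    if (length(bad)) {
      stop(sprintf("cohort file: non-positive or missing '%s' at line %d",
                   cl, bad[1] + 1L))
    }
  }
  bad_sex <- which(!df$sex %in% c("M", "F"))
  if (length(bad_sex)) {
    stop(sprintf("cohort file: sex must be M or F at line %d",
                 bad_sex[1] + 1L))
  }
  bad_bp <- which(df$sbp <= df$dbp)
  if (length(bad_bp)) {
    stop(sprintf("cohort file: sbp <= dbp at line %d", bad_bp[1] + 1L))
  }
  df
}

#' Write / read a growth-reference CSV
#'
#' Header `sex,age,mode,mean_or_M,sd_or_S,L,wc_p90`.
#'
#' @param reference A [growth_reference()].
#' @param path File path.
#' @return `write_reference`: `path` invisibly; `read_reference`: a
#'   validated [growth_reference()].
#' @export
write_reference <- function(reference, path) {
  utils::write.csv(as.data.frame(reference), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  growth_reference(utils::read.csv(path, stringsAsFactors = FALSE,
                                   fileEncoding = "UTF-8"))
}
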