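#' IDF abdominal-obesity flag
#'
#' Under the pediatric IDF criteria, abdominal obesity is waist
#' circumference at or above the sex- and age-specific 90th percentile for
#' ages below `adult_at`, and at or above the adult thresholds of 94 cm
#' (males) / 80 cm (females) from `adult_at` on. The criteria leave exactly
#' age 16 unassigned ("< 16" vs "> 16"); following the usual IDF convention
#' the adult branch applies from 16, switchable via `adult_at`.
#'
#' @param sex,age,wc_cm Vectors of sex (`"M"`/`"F"`), decimal age (years)
#'   and waist circumference (cm).
#' @param reference A [growth_reference()] supplying `wc_p90` for
#'   (sex, floor(age)); needed only for ages below `adult_at`.
#' @param adult_at Age (years) at which the fixed adult thresholds take
#'   over; default 16.
#' @return Logical vector.
#' @export
classify_abdominal_obesity <- function(sex, age, wc_cm, reference,
                                       adult_at = 16) {
  n <- length(wc_cm)
  sex <- rep_len(sex, n)
  age <- rep_len(age, n)
  out <- logical(n)
  for (i in seq_len(n)) {
    if (age[i] >= adult_at) {
      out[i] <- wc_cm[i] >= if (sex[i] == "M") 94 else 80
    } else {
      out[i] <- wc_cm[i] >= reference_cell(reference, sex[i], age[i])$wc_p90
    }
  }
  out
}

#' IDF metabolic-syndrome component flags
#'
#' The four non-abdominal IDF components, with thresholds applied on the
#' mg/dL scale exactly as defined: high triglycerides `tg >= 150` mg/dL
#' (1.7 mmol/L); low HDL `hdl < 40` mg/dL for males at any age and for
#' females under `adult_at`, `< 50` mg/dL (1.29 mmol/L) for females from
#' `adult_at` on; high blood pressure `sbp >= 130` or `dbp >= 80` mmHg;
#' high fasting glucose `glucose >= 100` mg/dL (5.6 mmol/L). Risk
#' thresholds are inclusive (`>=`), the low-HDL comparison strict (`<`).
#'
#' @param cohort Data.frame with columns `sex`, `age`, `tg_mgdl`,
#'   `hdl_mgdl`, `sbp`, `dbp`, `glucose_mgdl`; a missing column is an error
#'   naming it.
#' @param adult_at Age at which the adult female HDL threshold applies.
#' @return Data.frame of logicals `high_tg`, `low_hdl`, `high_bp`,
#'   `high_glucose`.
#' @export
classify_components <- function(cohort, adult_at = 16) {
  needed <- c("sex", "age", "tg_mgdl", "hdl_mgdl", "sbp", "dbp",
              "glucose_mgdl")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("missing field(s): ", paste(missing_cols, collapse = ", "))
  }
  hdl_cut <- ifelse(cohort$sex == "F" & cohort$age >= adult_at, 50, 40)
  data.frame(
    high_tg = cohort$tg_mgdl >= 150,
    low_hdl = cohort$hdl_mgdl < hdl_cut,
    high_bp = cohort$sbp >= 130 | cohort$dbp >= 80,
    high_glucose = cohort$glucose_mgdl >= 100
  )
}

#' IDF metabolic-syndrome classification
#'
#' Metabolic syndrome = abdominal obesity plus two or more of the four
#' components (high TG, low HDL, high BP, high glucose). Returns the cohort
#' with all flags appended.
#'
#' @param cohort Cohort data.frame (see [classify_components()] plus
#'   `wc_cm`).
#' @param reference A [growth_reference()] for the WC 90th percentile.
#' @param adult_at Age at which adult thresholds apply (default 16).
#' @return `cohort` with logical columns `abdominal`, `high_tg`, `low_hdl`,
#'   `high_bp`, `high_glucose`, integer `n_components` (0-4) and logical
#'   `mets`.
#' @export
classify_mets <- function(cohort, reference, adult_at = 16) {
  comp <- classify_components(cohort, adult_at = adult_at)
  cohort$abdominal <- classify_abdominal_obesity(
    cohort$sex, cohort$age, cohort$wc_cm, reference, adult_at = adult_at
  )
  cohort$high_tg <- comp$high_tg
  cohort$low_hdl <- comp$low_hdl
  cohort$high_bp <- comp$high_bp
  cohort$high_glucose <- comp$high_glucose
  cohort$n_components <- comp$high_tg + comp$low_hdl + comp$high_bp +
    comp$high_glucose
  cohort$mets <- cohort$abdominal & cohort$n_components >= 2
  cohort
}

#' Component and syndrome prevalence, overall and by sex
#'
#' Counts and percentages (rounded to one decimal, percentage points) of
#' abdominal obesity, the four components, and metabolic syndrome.
#'
#' @param classified Output of [classify_mets()].
#' @return Data.frame with columns `flag`, `group` (`all`/`M`/`F`), `count`,
#'   `n`, `pct`.
#' @export
component_prevalence <- function(classified) {
  if (nrow(classified) == 0L) stop("empty cohort")
  flags <- c("abdominal", "high_tg", "low_hdl", "high_bp", "high_glucose",
             "mets")
  groups <- list(all = rep(TRUE, nrow(classified)),
                 M = classified$sex == "M",
                 F = classified$sex == "F")
  rows <- list()
  for (f in flags) {
    for (g in names(groups)) {
      sel <- groups[[g]]
      n_g <- sum(sel)
      cnt <- sum(classified[[f]][sel])
      rows[[length(rows) + 1L]] <- data.frame(
        flag = f, group = g, count = cnt, n = n_g,
        pct = if (n_g > 0) percentage(cnt, n_g) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Percentage of a count, rounded to one decimal
#'
#' The print convention used in prevalence reports: `100 * count / n`
#' rounded half away from zero to one decimal place (so 324 of 1065 prints
#' as 30.4).
#'
#' @param count,n Non-negative counts, `n > 0`.
#' @return Numeric percentage with one decimal.
#' @export
percentage <- function(count, n) {
  if (any(n <= 0)) stop("n must be > 0")
  round_half_up(100 * count / n, 1)
}

# round half away from zero (base round() is banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
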