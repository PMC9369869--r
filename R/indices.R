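#' Convert mg/dL to mmol/L
#'
#' Analyte-specific molar conversion: triglycerides divide by 88.57,
#' cholesterol (HDL/LDL/total) by 38.67, glucose by 18.02.
#'
#' @param value Concentration in mg/dL (vectorised, must be >= 0).
#' @param analyte One of `"triglyceride"`, `"cholesterol"`, `"glucose"`.
#' @return Concentration in mmol/L.
#' @export
mgdl_to_mmol <- function(value, analyte) {
  factor <- switch(analyte,
    triglyceride = 88.57,
    cholesterol = 38.67,
    glucose = 18.02,
    stop("unknown analyte: ", analyte)
  )
  if (any(value < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  value / factor
}

#' Body mass index, weight / height^2
#' @param weight_kg Weight in kg (>= 0).
#' @param height_m Height in m (> 0).
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(height_m <= 0)) stop("height must be > 0")
  weight_kg / height_m^2
}

#' Tri-ponderal mass index, weight / height^3
#' @inheritParams compute_bmi
#' @return TMI in kg/m^3.
#' @export
compute_tmi <- function(weight_kg, height_m) {
  if (any(height_m <= 0)) stop("height must be > 0")
  weight_kg / height_m^3
}

#' BMI standard-deviation score against a growth reference
#'
#' In `mean_sd` mode the z-score is `(bmi - mean) / sd`. In `lms` mode it is
#' the Box-Cox LMS z-score `((bmi/M)^L - 1) / (L * S)` for `L != 0`, and
#' `log(bmi/M) / S` when `L = 0`.
#'
#' @param bmi BMI in kg/m^2 (vectorised).
#' @param sex `"M"`/`"F"`, recycled to length of `bmi`.
#' @param age Decimal age in years; the reference is indexed by
#'   `floor(age)` (completed years).
#' @param reference A [growth_reference()]; a missing (sex, age) cell is an
#'   error naming it.
#' @return Numeric vector of BMI-SDS values.
#' @export
compute_bmi_sds <- function(bmi, sex, age, reference) {
  n <- length(bmi)
  sex <- rep_len(sex, n)
  age <- rep_len(age, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    cell <- reference_cell(reference, sex[i], age[i])
    if (cell$mode == "mean_sd") {
      out[i] <- (bmi[i] - cell$mean_or_M) / cell$sd_or_S
    } else {
      L <- cell$L
      M <- cell$mean_or_M
      S <- cell$sd_or_S
      out[i] <- if (abs(L) < 1e-12) {
        log(bmi[i] / M) / S
      } else {
        ((bmi[i] / M)^L - 1) / (L * S)
      }
    }
  }
  out
}

#' Waist-to-height ratio
#' @param wc_cm Waist circumference in cm (> 0).
#' @param height_cm Height in cm (> 0).
#' @return Dimensionless WC / height.
#' @export
compute_wthr <- function(wc_cm, height_cm) {
  if (any(wc_cm <= 0) || any(height_cm <= 0)) {
    stop("waist circumference and height must be > 0")
  }
  wc_cm / height_cm
}

#' Triglyceride to HDL-cholesterol ratio (molar)
#'
#' Both analytes are converted to mmol/L before the ratio, so the result is
#' the molar TG/HDL-C ratio; from mg/dL inputs this equals
#' `(tg/hdl) * 38.67 / 88.57`.
#'
#' @param tg_mgdl Triglycerides in mg/dL (>= 0).
#' @param hdl_mgdl HDL cholesterol in mg/dL (> 0).
#' @return Dimensionless molar ratio.
#' @export
compute_tg_hdl <- function(tg_mgdl, hdl_mgdl) {
  if (any(hdl_mgdl <= 0)) stop("HDL must be > 0")
  mgdl_to_mmol(tg_mgdl, "triglyceride") / mgdl_to_mmol(hdl_mgdl, "cholesterol")
}

#' Cardiometabolic index: WtHR x TG/HDL
#' @param wthr Waist-to-height ratio (> 0).
#' @param tg_hdl Molar TG/HDL ratio (> 0).
#' @return Dimensionless CMI.
#' @export
compute_cmi <- function(wthr, tg_hdl) {
  if (any(wthr <= 0) || any(tg_hdl < 0)) stop("inputs must be positive")
  wthr * tg_hdl
}

#' Visceral adiposity index (Amato), sex-specific
#'
#' \deqn{VAI_{male} = \frac{WC}{39.68 + 1.88\,BMI} \cdot \frac{TG}{1.03}
#'   \cdot \frac{1.31}{HDL}}
#' \deqn{VAI_{female} = \frac{WC}{36.58 + 1.89\,BMI} \cdot \frac{TG}{0.81}
#'   \cdot \frac{1.52}{HDL}}
#' with WC in cm, BMI in kg/m^2 and TG, HDL in mmol/L. Note the first factor
#' is WC divided by the whole linear term `a + b*BMI`: the frequently seen
#' typeset form "(WC/a + (b x BMI))" parsed literally yields values an order
#' of magnitude too large to be a visceral-adiposity score, so this function
#' implements the original formulation.
#'
#' @param sex `"M"` or `"F"` (vectorised, recycled).
#' @param wc_cm Waist circumference, cm.
#' @param bmi BMI, kg/m^2.
#' @param tg_mgdl Triglycerides, mg/dL (converted internally).
#' @param hdl_mgdl HDL cholesterol, mg/dL (converted internally).
#' @return Dimensionless VAI.
#' @export
compute_vai <- function(sex, wc_cm, bmi, tg_mgdl, hdl_mgdl) {
  n <- max(length(sex), length(wc_cm), length(bmi), length(tg_mgdl),
           length(hdl_mgdl))
  sex <- rep_len(sex, n)
  wc_cm <- rep_len(wc_cm, n)
  bmi <- rep_len(bmi, n)
  tg <- mgdl_to_mmol(rep_len(tg_mgdl, n), "triglyceride")
  hdl <- mgdl_to_mmol(rep_len(hdl_mgdl, n), "cholesterol")
  if (any(wc_cm <= 0) || any(bmi <= 0) || any(tg <= 0) || any(hdl <= 0)) {
    stop("all inputs must be > 0")
  }
  if (!all(sex %in% c("M", "F"))) {
    stop("unknown sex: ", paste(unique(sex[!sex %in% c("M", "F")]),
                                collapse = ", "))
  }
  ifelse(sex == "M",
         wc_cm / (39.68 + 1.88 * bmi) * (tg / 1.03) * (1.31 / hdl),
         wc_cm / (36.58 + 1.89 * bmi) * (tg / 0.81) * (1.52 / hdl))
}

#' Compute the full index panel for a cohort
#'
#' Appends the seven candidate indexes — `bmi`, `bmi_sds`, `tmi`, `wthr`,
#' `tg_hdl`, `cmi`, `vai` — to a cohort data.frame, composing the individual
#' index functions.
#'
#' @param cohort Cohort data.frame (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param reference A [growth_reference()] (for `bmi_sds`).
#' @return `cohort` with the seven index columns appended.
#' @export
compute_panel <- function(cohort, reference) {
  cohort$bmi <- compute_bmi(cohort$weight_kg, cohort$height_m)
  cohort$bmi_sds <- compute_bmi_sds(cohort$bmi, cohort$sex, cohort$age,
                                    reference)
  cohort$tmi <- compute_tmi(cohort$weight_kg, cohort$height_m)
  cohort$wthr <- compute_wthr(cohort$wc_cm, 100 * cohort$height_m)
  cohort$tg_hdl <- compute_tg_hdl(cohort$tg_mgdl, cohort$hdl_mgdl)
  cohort$cmi <- compute_cmi(cohort$wthr, cohort$tg_hdl)
  cohort$vai <- compute_vai(cohort$sex, cohort$wc_cm, cohort$bmi,
                            cohort$tg_mgdl, cohort$hdl_mgdl)
  cohort
}
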