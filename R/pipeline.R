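#' Pipeline configuration
#'
#' Exactly one of `input` (a cohort CSV path) or `spec` (a [cohort_spec()]
#' for simulation) must be given. The growth reference is either a CSV path
#' or `"synthetic"`, in which case one matched to the spec is generated.
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate.
#' @param spec A [cohort_spec()], or `NULL` when `input` is given.
#' @param reference Path to a growth-reference CSV, or `"synthetic"`.
#' @param indexes Index columns to evaluate as MetS predictors.
#' @param agestd_degree Polynomial degree for age standardization.
#' @param standardize_biochemical Standardize the purely biochemical TG/HDL
#'   ratio by age as well (default TRUE); when FALSE its raw value is used
#'   as the ROC predictor.
#' @param ci_mode CI convention for [confusion_metrics()].
#' @param n_boot Bootstrap replicates for the cutoff trend.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory (created if absent).
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(input = NULL, spec = NULL,
                            reference = "synthetic",
                            indexes = c("bmi", "bmi_sds", "tmi", "wthr",
                                        "tg_hdl", "cmi", "vai"),
                            agestd_degree = 2,
                            standardize_biochemical = TRUE,
                            ci_mode = c("wilson_subgroup", "wald_total_n"),
                            n_boot = 1000, seed = 1L, out_dir = ".") {
  if (is.null(input) == is.null(spec)) {
    stop("exactly one of 'input' and 'spec' must be set")
  }
  if (!is.null(spec)) validate_cohort_spec(spec)
  structure(
    list(input = input, spec = spec, reference = reference,
         indexes = indexes, agestd_degree = agestd_degree,
         standardize_biochemical = standardize_biochemical,
         ci_mode = match.arg(ci_mode), n_boot = n_boot,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

descriptive_variables <- function(panel) {
  intersect(
    c("age", "weight_kg", "height_m", "wc_cm", "sbp", "dbp", "glucose_mgdl",
      "insulin", "hdl_mgdl", "ldl_mgdl", "tg_mgdl", "bmi", "bmi_sds", "tmi",
      "wthr", "tg_hdl", "cmi", "vai"),
    names(panel)
  )
}

# Descriptive report: per-variable median (q1-q3) in two groups + rank test
describe_by_group <- function(panel, group, label_a, label_b) {
  vars <- descriptive_variables(panel)
  rows <- lapply(vars, function(v) {
    gc <- ranksum_test(panel[[v]][group], panel[[v]][!group], variable = v)
    g <- gc$groups
    data.frame(
      variable = v,
      group_a = label_a, n_a = g$n[1],
      median_a = g$median[1], q1_a = g$q1[1], q3_a = g$q3[1],
      group_b = label_b, n_b = g$n[2],
      median_b = g$median[2], q1_b = g$q1[2], q3_b = g$q3[2],
      p_value = gc$p_value,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run the full screening-evaluation pipeline
#'
#' Orchestrates simulate (or read) -> index panel -> IDF classification ->
#' age standardization -> per-sex ROC/Youden diagnostics -> descriptive and
#' association statistics, writing the complete artifact set to
#' `config$out_dir`:
#'
#' 1. `cohort_panel.csv` — cohort with the seven indexes appended;
#' 2. `mets_classification.csv` — component and MetS flags (0/1);
#' 3. `descriptives.csv` — median (IQR) by sex and by MetS with rank-test p;
#' 4. `roc_M.csv` / `roc_F.csv` + `auc_comparison.csv` — per-sex ROC
#'    coordinates and the DeLong AUC comparison matrix;
#' 5. `youden_metrics.csv` — per sex x index cutoff-level diagnostics;
#' 6. `correlations.csv` — Spearman correlations of TG/HDL with the
#'    metabolic variables, total and by sex;
#' 7. `odds_ratios.csv` — age-adjusted odds ratios of each IDF component
#'    across dichotomized TG/HDL, by sex;
#' 8. `cutoff_trend.csv` — per (sex, age) Youden cutoff of raw TG/HDL with
#'    bootstrap bands (+ `cutoff_trend_sexdiff.csv` p-values);
#'
#' plus `manifest.json` recording the configuration, seed, package version
#' and an MD5 digest of every artifact. Rerunning with an identical
#' configuration reproduces every artifact byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`panel`,
#'   `classified`, `roc` per sex/index, `youden`, `trend`, `manifest`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  cohort <- if (!is.null(config$input)) {
    read_cohort(config$input)
  } else {
    generate_cohort(config$spec)
  }
  reference <- if (identical(config$reference, "synthetic")) {
    if (is.null(config$spec)) {
      stop("reference = 'synthetic' requires a simulation spec")
    }
    generate_reference(config$spec)
  } else {
    read_reference(config$reference)
  }

  panel <- compute_panel(cohort, reference)
  classified <- classify_mets(panel, reference)

  # age standardization, per sex, each evaluated index
  for (idx in config$indexes) {
    z <- rep(NA_real_, nrow(classified))
    for (s in c("M", "F")) {
      sel <- classified$sex == s
      if (idx == "tg_hdl" && !config$standardize_biochemical) {
        z[sel] <- classified$tg_hdl[sel]
      } else {
        z[sel] <- standardize_by_age(classified[[idx]][sel],
                                     classified$age[sel],
                                     degree = config$agestd_degree)$z
      }
    }
    classified[[paste0(idx, "_agestd")]] <- z
  }

  write_cohort(panel, out("cohort_panel.csv"))
  flag_cols <- c("abdominal", "high_tg", "low_hdl", "high_bp",
                 "high_glucose", "mets")
  cls_out <- classified[c("id", "sex", "age", flag_cols, "n_components")]
  for (cl in flag_cols) cls_out[[cl]] <- as.integer(cls_out[[cl]])
  utils::write.csv(cls_out, out("mets_classification.csv"),
                   row.names = FALSE, quote = FALSE)

  desc <- rbind(
    cbind(comparison = "sex",
          describe_by_group(classified, classified$sex == "M", "M", "F")),
    cbind(comparison = "mets",
          describe_by_group(classified, classified$mets, "MetS", "NoMetS"))
  )
  utils::write.csv(desc, out("descriptives.csv"), row.names = FALSE,
                   quote = FALSE)

  rocs <- list()
  youden_rows <- list()
  auc_rows <- list()
  for (s in c("M", "F")) {
    sel <- classified$sex == s
    labels <- as.integer(classified$mets[sel])
    coords <- list()
    for (idx in config$indexes) {
      sc <- classified[[paste0(idx, "_agestd")]][sel]
      rc <- roc_curve(sc, labels)
      rocs[[paste(s, idx)]] <- rc
      coords[[idx]] <- data.frame(
        index = idx, threshold = rc$thresholds, sens = rc$sens,
        spec = 1 - rc$fpr, stringsAsFactors = FALSE
      )
      yc <- youden_cutoff(rc)
      cm <- confusion_metrics(sc, labels, yc$cutoff, ci_mode = config$ci_mode)
      youden_rows[[paste(s, idx)]] <- data.frame(
        sex = s, index = idx, auc = rc$auc,
        auc_lo95 = rc$auc_ci95[1], auc_hi95 = rc$auc_ci95[2],
        cutoff = yc$cutoff, youden_j = yc$J,
        sens = cm$sens$est, sens_lo = cm$sens$ci95[1],
        sens_hi = cm$sens$ci95[2],
        spec = cm$spec$est, spec_lo = cm$spec$ci95[1],
        spec_hi = cm$spec$ci95[2],
        ppv = cm$ppv$est, ppv_lo = cm$ppv$ci95[1], ppv_hi = cm$ppv$ci95[2],
        npv = cm$npv$est, npv_lo = cm$npv$ci95[1], npv_hi = cm$npv$ci95[2],
        plr = cm$plr, nlr = cm$nlr, stringsAsFactors = FALSE
      )
    }
    utils::write.csv(do.call(rbind, coords), out(paste0("roc_", s, ".csv")),
                     row.names = FALSE, quote = FALSE)
    for (a in config$indexes) {
      for (b in config$indexes) {
        if (a >= b) next
        cmp <- delong_compare(classified[[paste0(a, "_agestd")]][sel],
                              classified[[paste0(b, "_agestd")]][sel],
                              labels)
        auc_rows[[paste(s, a, b)]] <- data.frame(
          sex = s, index_a = a, index_b = b, auc_a = cmp$auc_a,
          auc_b = cmp$auc_b, delta = cmp$delta, z = cmp$z, p = cmp$p,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  utils::write.csv(do.call(rbind, auc_rows), out("auc_comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  youden <- do.call(rbind, youden_rows)
  utils::write.csv(youden, out("youden_metrics.csv"), row.names = FALSE,
                   quote = FALSE)

  cor_vars <- setdiff(descriptive_variables(classified),
                      c("tg_hdl", "cmi", "vai", "age"))
  cor_rows <- list()
  for (g in c("all", "M", "F")) {
    sel <- if (g == "all") rep(TRUE, nrow(classified)) else classified$sex == g
    for (v in cor_vars) {
      sp <- spearman_cor(classified$tg_hdl[sel], classified[[v]][sel])
      cor_rows[[paste(g, v)]] <- data.frame(
        group = g, variable = v, rho = sp$rho, p_value = sp$p_value,
        n = sp$n, stringsAsFactors = FALSE
      )
    }
  }
  utils::write.csv(do.call(rbind, cor_rows), out("correlations.csv"),
                   row.names = FALSE, quote = FALSE)

  # TG/HDL dichotomized at the sex-specific Youden cutoff of the raw ratio
  or_rows <- list()
  for (s in c("M", "F")) {
    sel <- classified$sex == s
    labels <- as.integer(classified$mets[sel])
    raw_cut <- youden_cutoff(roc_curve(classified$tg_hdl[sel], labels))$cutoff
    exposure <- as.integer(classified$tg_hdl[sel] >= raw_cut)
    for (oc in c("abdominal", "high_glucose", "low_hdl", "high_tg",
                 "high_bp")) {
      lo <- logistic_or(classified[[oc]][sel], exposure,
                        age = classified$age[sel])
      or_rows[[paste(s, oc)]] <- data.frame(
        sex = s, outcome = oc, exposure_cutoff = raw_cut,
        or = lo$or_point, lo95 = lo$ci95[1], hi95 = lo$ci95[2],
        pseudo_r2 = lo$pseudo_r2, status = lo$status,
        reason = if (is.null(lo$reason)) "" else lo$reason,
        stringsAsFactors = FALSE
      )
    }
  }
  utils::write.csv(do.call(rbind, or_rows), out("odds_ratios.csv"),
                   row.names = FALSE, quote = FALSE)

  trend <- cutoff_trend(classified$tg_hdl, as.integer(classified$mets),
                        classified$age, classified$sex,
                        n_boot = config$n_boot, seed = config$seed)
  utils::write.csv(as.data.frame(trend), out("cutoff_trend.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(attr(trend, "sex_diff"), out("cutoff_trend_sexdiff.csv"),
                   row.names = FALSE, quote = FALSE)

  artifacts <- c("cohort_panel.csv", "mets_classification.csv",
                 "descriptives.csv", "roc_M.csv", "roc_F.csv",
                 "auc_comparison.csv", "youden_metrics.csv",
                 "correlations.csv", "odds_ratios.csv", "cutoff_trend.csv",
                 "cutoff_trend_sexdiff.csv")
  manifest <- list(
    package = "metscreen",
    version = as.character(utils::packageVersion("metscreen")),
    seed = config$seed,
    config = list(
      input = if (is.null(config$input)) NA else config$input,
      simulated = is.null(config$input),
      n_total = if (is.null(config$spec)) NA else config$spec$n_total,
      reference = if (identical(config$reference, "synthetic")) {
        "synthetic"
      } else {
        config$reference
      },
      indexes = config$indexes,
      agestd_degree = config$agestd_degree,
      standardize_biochemical = config$standardize_biochemical,
      ci_mode = config$ci_mode,
      n_boot = config$n_boot
    ),
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$out_dir, artifacts))), artifacts
    ))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(
    panel = panel, classified = classified, descriptives = desc,
    rocs = rocs, youden = youden,
    auc_comparison = do.call(rbind, auc_rows),
    correlations = do.call(rbind, cor_rows),
    odds_ratios = do.call(rbind, or_rows),
    trend = trend, manifest = manifest
  ))
}
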