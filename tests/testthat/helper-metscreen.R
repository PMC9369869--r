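# shared fixtures and independent oracles, all built in code

# flat mean/SD growth reference covering both sexes, ages 10-17
flat_reference <- function(mean = 20, sd = 4, wc_p90 = 90) {
  grid <- expand.grid(sex = c("M", "F"), age = 10:17,
                      stringsAsFactors = FALSE)
  growth_reference(data.frame(
    sex = grid$sex, age = grid$age, mode = "mean_sd",
    mean_or_M = mean, sd_or_S = sd, L = NA_real_, wc_p90 = wc_p90
  ))
}

# hand-assembled subject rows with overridable fields
make_subjects <- function(n, sex = "M", age = 14, height_m = 1.6,
                          weight_kg = 100, wc_cm = 110, sbp = 120, dbp = 70,
                          glucose_mgdl = 80, tg_mgdl = 90, hdl_mgdl = 45) {
  data.frame(
    id = sprintf("T%03d", seq_len(n)),
    sex = rep_len(sex, n), age = rep_len(age, n),
    height_m = rep_len(height_m, n), weight_kg = rep_len(weight_kg, n),
    wc_cm = rep_len(wc_cm, n), sbp = rep_len(sbp, n),
    dbp = rep_len(dbp, n), glucose_mgdl = rep_len(glucose_mgdl, n),
    tg_mgdl = rep_len(tg_mgdl, n), hdl_mgdl = rep_len(hdl_mgdl, n),
    stringsAsFactors = FALSE
  )
}

# brute-force AUC: concordant positive-negative pairs, ties count 1/2
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# brute-force Mann-Whitney U for the first sample
u_brute <- function(x, y) {
  total <- 0
  for (xi in x) total <- total + sum(xi > y) + 0.5 * sum(xi == y)
  total
}

# exhaustive Youden maximization over all candidate thresholds
youden_brute <- function(scores, labels) {
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
  }, numeric(1))
  list(cutoff = min(thr[j >= max(j) - 1e-12]), J = max(j))
}

default_spec_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(n_total, seed) {
    key <- paste(n_total, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- cohort_spec(n_total = n_total, seed = seed)
    }
    cache[[key]]
  }
})
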