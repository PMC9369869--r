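test_that("abdominal obesity branches on age 16 with inclusive thresholds", {
  ref <- flat_reference(wc_p90 = 90)
  expect_true(classify_abdominal_obesity("M", 16.5, 94, ref))
  expect_false(classify_abdominal_obesity("M", 16.5, 93.9, ref))
  expect_false(classify_abdominal_obesity("F", 17, 79.9, ref))
  expect_true(classify_abdominal_obesity("F", 17, 80, ref))
  expect_true(classify_abdominal_obesity("F", 12, 91, ref))
  expect_false(classify_abdominal_obesity("F", 12, 89.9, ref))
  # exactly 16 uses the adult branch by default; switchable
  expect_true(classify_abdominal_obesity("F", 16, 80, ref))
  expect_false(classify_abdominal_obesity("F", 16, 80, ref, adult_at = 17))
  expect_error(classify_abdominal_obesity("M", 9, 95, ref), "age=9")
})

test_that("component flags apply the IDF thresholds exactly as printed", {
  # adult female HDL branch switches at 16
  f16 <- make_subjects(1, sex = "F", age = 16.2, hdl_mgdl = 45)
  f15 <- make_subjects(1, sex = "F", age = 15.8, hdl_mgdl = 45)
  expect_true(classify_components(f16)$low_hdl)
  expect_false(classify_components(f15)$low_hdl)
  # males keep the 40 threshold at any age
  m17 <- make_subjects(1, sex = "M", age = 17.5, hdl_mgdl = 45)
  expect_false(classify_components(m17)$low_hdl)
  expect_true(classify_components(
    make_subjects(1, sex = "M", age = 17.5, hdl_mgdl = 39.9))$low_hdl)

  bp <- classify_components(make_subjects(1, sbp = 130, dbp = 70))
  expect_true(bp$high_bp)
  expect_true(classify_components(make_subjects(1, sbp = 115,
                                                dbp = 80))$high_bp)
  expect_false(classify_components(make_subjects(1, sbp = 129.9,
                                                 dbp = 79.9))$high_bp)

  strict <- classify_components(make_subjects(1, tg_mgdl = 149.9,
                                              glucose_mgdl = 99.9))
  expect_false(strict$high_tg)
  expect_false(strict$high_glucose)
  incl <- classify_components(make_subjects(1, tg_mgdl = 150,
                                            glucose_mgdl = 100))
  expect_true(incl$high_tg)
  expect_true(incl$high_glucose)

  no_sbp <- make_subjects(1)
  no_sbp$sbp <- NULL
  expect_error(classify_components(no_sbp), "missing field.*sbp")
})

test_that("MetS requires abdominal obesity plus two or more components", {
  ref <- flat_reference(wc_p90 = 90)
  # abdominal + exactly two components (high TG, low HDL)
  s <- make_subjects(1, wc_cm = 95, tg_mgdl = 160, hdl_mgdl = 35,
                     sbp = 110, dbp = 60, glucose_mgdl = 80)
  r <- classify_mets(s, ref)
  expect_true(r$mets)
  expect_equal(r$n_components, 2)
  # no abdominal obesity: all four components cannot make MetS
  s2 <- make_subjects(1, wc_cm = 80, tg_mgdl = 160, hdl_mgdl = 35,
                      sbp = 135, dbp = 85, glucose_mgdl = 110)
  r2 <- classify_mets(s2, ref)
  expect_equal(r2$n_components, 4)
  expect_false(r2$mets)
  # abdominal + one component only
  s3 <- make_subjects(1, wc_cm = 95, tg_mgdl = 160)
  expect_false(classify_mets(s3, ref)$mets)
  # invariant: n_components is the sum of the four flags
  spec <- cohort_spec(n_total = 300, seed = 11)
  cls <- classify_mets(compute_panel(generate_cohort(spec),
                                     generate_reference(spec)),
                       generate_reference(spec))
  expect_equal(cls$n_components,
               cls$high_tg + cls$low_hdl + cls$high_bp + cls$high_glucose)
  expect_equal(cls$mets, cls$abdominal & cls$n_components >= 2)
})

test_that("classification is monotone under risk-increasing perturbations", {
  ref <- flat_reference(wc_p90 = 90)
  set.seed(4)
  for (i in 1:30) {
    s <- make_subjects(
      1, sex = sample(c("M", "F"), 1), age = runif(1, 10, 17.9),
      wc_cm = runif(1, 70, 130), sbp = runif(1, 100, 150),
      dbp = runif(1, 55, 95), glucose_mgdl = runif(1, 70, 110),
      tg_mgdl = runif(1, 50, 250), hdl_mgdl = runif(1, 25, 70)
    )
    before <- classify_mets(s, ref)$mets
    bump <- s
    up_var <- sample(c("tg_mgdl", "wc_cm", "sbp", "dbp", "glucose_mgdl",
                       "hdl_down"), 1)
    if (up_var == "hdl_down") {
      bump$hdl_mgdl <- bump$hdl_mgdl - runif(1, 0, 20)
    } else {
      bump[[up_var]] <- bump[[up_var]] + runif(1, 0, 40)
    }
    after <- classify_mets(bump, ref)$mets
    expect_true(after >= before)  # can only turn false -> true
  }
})

test_that("prevalence report counts exactly and rounds to one decimal", {
  ref <- flat_reference(wc_p90 = 90)
  coh <- make_subjects(
    10,
    sex = c("M", "M", "M", "M", "M", "F", "F", "F", "F", "F"),
    age = 14,
    wc_cm = c(95, 95, 95, 70, 95, 95, 95, 70, 95, 95),
    tg_mgdl = c(160, 160, 90, 160, 90, 90, 160, 90, 90, 90),
    hdl_mgdl = c(35, 45, 35, 35, 45, 39, 45, 45, 45, 45),
    sbp = c(135, 110, 110, 135, 110, 110, 135, 110, 110, 110),
    glucose_mgdl = c(80, 80, 80, 105, 80, 80, 80, 80, 80, 80)
  )
  cls <- classify_mets(coh, ref)
  prev <- component_prevalence(cls)
  # hand enumeration
  expect_equal(prev$count[prev$flag == "abdominal" & prev$group == "all"], 8)
  expect_equal(prev$count[prev$flag == "high_tg" & prev$group == "all"], 4)
  expect_equal(prev$count[prev$flag == "high_tg" & prev$group == "M"], 3)
  # row 1 (abd + TG + HDL + BP) and row 7 (abd + TG + BP) are the MetS cases
  expect_equal(prev$count[prev$flag == "mets" & prev$group == "all"], 2)
  expect_equal(prev$pct[prev$flag == "mets" & prev$group == "all"], 20.0)
  expect_equal(prev$count[prev$flag == "mets" & prev$group == "F"], 1)

  quiet <- classify_mets(make_subjects(4, wc_cm = 70), ref)
  pq <- component_prevalence(quiet)
  expect_true(all(pq$count[pq$flag != "abdominal"] == 0))

  expect_error(component_prevalence(cls[0, ]), "empty")
  expect_equal(percentage(324, 1065), 30.4)
})
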