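test_that("ROC curve endpoints, monotonicity and AUC match the pair count", {
  rc <- roc_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0))
  expect_equal(rc$auc, 1)
  expect_equal(rc$sens[1], 0)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$sens[length(rc$sens)], 1)
  expect_equal(rc$fpr[length(rc$fpr)], 1)

  # oracle-derived small instance: 3 of 4 concordant pairs
  rc2 <- roc_curve(c(0.9, 0.7, 0.8, 0.6), c(1, 1, 0, 0))
  expect_equal(rc2$auc, 0.75)
  expect_equal(rc2$auc, auc_brute(c(0.9, 0.7, 0.8, 0.6), c(1, 1, 0, 0)))

  set.seed(20)
  scores <- rnorm(2000)
  labels <- rbinom(2000, 1, 0.4)  # independent of scores
  expect_lt(abs(roc_curve(scores, labels)$auc - 0.5), 0.03)

  expect_error(roc_curve(1:5, rep(1, 5)), "single class")
})

test_that("AUC equals the Mann-Whitney statistic on tied and untied data", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_curve(scores, labels)$auc, auc_brute(scores, labels))
  }
})

test_that("DeLong AUC inference agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  n <- 300
  labels <- rbinom(n, 1, 0.4)
  a <- rnorm(n) + labels
  b <- rnorm(n) + 0.5 * labels
  rc <- roc_curve(a, labels)
  pr <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
  expect_equal(rc$auc, as.numeric(pROC::auc(pr)))
  expect_equal(as.numeric(sqrt(pROC::var(pr, method = "delong"))), rc$auc_se,
               tolerance = 1e-8)
  cmp <- delong_compare(a, b, labels)
  pt <- pROC::roc.test(pr, pROC::roc(labels, b, quiet = TRUE,
                                     direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(cmp$p, pt$p.value, tolerance = 1e-8)
  expect_equal(cmp$auc_b, as.numeric(pt$estimate[2]))
})

test_that("DeLong comparison is null on identical or rank-equivalent scores", {
  set.seed(23)
  labels <- rbinom(200, 1, 0.5)
  a <- rnorm(200) + labels
  same <- delong_compare(a, a, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  mono <- delong_compare(a, exp(a) + 3, labels)  # monotone transform
  expect_equal(mono$auc_a, mono$auc_b)
  expect_equal(mono$z, 0)
  # antisymmetry
  b <- rnorm(200) + 0.5 * labels
  ab <- delong_compare(a, b, labels)
  ba <- delong_compare(b, a, labels)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
})

test_that("DeLong test has power against a real AUC difference", {
  set.seed(24)
  rejections <- 0
  for (i in 1:200) {
    labels <- rep(c(1, 0), each = 500)
    # binormal predictors with true AUCs ~0.76 vs ~0.66 (delta 0.10)
    a <- rnorm(1000) + labels * 1.0
    b <- rnorm(1000) + labels * 0.58
    if (delong_compare(a, b, labels)$p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / 200, 0.5)
})

test_that("Youden cutoff equals the exhaustive sweep with smallest-threshold ties", {
  rc <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  yc <- youden_cutoff(rc)
  expect_equal(yc$cutoff, 3)
  expect_equal(yc$J, 1)
  set.seed(25)
  for (i in 1:20) {
    n <- sample(15:80, 1)
    scores <- sample(seq(1, 6, 0.5), n, replace = TRUE)
    labels <- rbinom(n, 1, plogis(scores - 3))
    if (length(unique(labels)) < 2) next
    yc <- youden_cutoff(roc_curve(scores, labels))
    oracle <- youden_brute(scores, labels)
    expect_equal(yc$cutoff, oracle$cutoff)
    expect_equal(yc$J, oracle$J)
  }
})

test_that("confusion metrics reproduce the PLR/NLR identities and CIs", {
  lr <- likelihood_ratios(0.713, 0.854)
  expect_equal(round(lr$plr, 1), 4.9)
  expect_equal(round(likelihood_ratios(0.65, 0.872)$plr, 1), 5.1)
  expect_equal(likelihood_ratios(0.5, 0.5)$plr, 1)
  expect_equal(likelihood_ratios(0.5, 0.5)$nlr, 1)

  set.seed(26)
  scores <- rnorm(400)
  labels <- rbinom(400, 1, plogis(2 * scores))
  cm <- confusion_metrics(scores, labels, cutoff = 0)
  tab <- cm$table
  expect_equal(cm$sens$est, tab["tp"] / (tab["tp"] + tab["fn"]),
               ignore_attr = TRUE)
  expect_equal(cm$plr, cm$sens$est / (1 - cm$spec$est))
  expect_equal(cm$nlr, (1 - cm$sens$est) / cm$spec$est)
  # PPV consistency with prevalence on the same 2x2 table
  pi_hat <- (tab["tp"] + tab["fn"]) / sum(tab)
  expect_equal(cm$ppv$est,
               unname(cm$sens$est * pi_hat /
                        (cm$sens$est * pi_hat +
                           (1 - cm$spec$est) * (1 - pi_hat))))
  # wilson CI matches prop.test-style score interval
  w <- confusion_metrics(scores, labels, 0, ci_mode = "wilson_subgroup")
  pt <- prop.test(tab["tp"], tab["tp"] + tab["fn"], correct = FALSE)
  expect_equal(w$sens$ci95, as.numeric(pt$conf.int), tolerance = 1e-10)
})

test_that("wald_total_n replicates the full-sample-N interval convention", {
  # p = 0.752 with N = 563 gives half-width ~0.036
  labels <- rep(c(1, 0), c(250, 313))
  scores <- numeric(563)
  scores[labels == 1][1:188] <- 1   # sens = 188/250 = 0.752
  cm <- confusion_metrics(scores, labels, cutoff = 0.5,
                          ci_mode = "wald_total_n")
  expect_equal(cm$sens$est, 0.752)
  half <- diff(cm$sens$ci95) / 2
  expect_lt(abs(half - (0.787 - 0.716) / 2), 0.002)
})

test_that("empty 2x2 cells are flagged not-calculable instead of estimated", {
  labels <- rep(c(1, 0), each = 20)
  scores <- c(rep(2, 20), rep(1, 20))
  cm <- confusion_metrics(scores, labels, cutoff = 0.5)  # nobody negative
  expect_true("npv" %in% cm$not_calculable)
  expect_true(is.na(cm$npv$est))
  expect_true("nlr" %in% cm$not_calculable)  # spec = 0
})

test_that("cutoff trend recovers an age shift and respects stratum floors", {
  set.seed(27)
  n <- 3200
  ages <- runif(n, 10, 18)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  labels <- rbinom(n, 1, 0.35)
  # both classes shift up linearly with age; separation fixed
  scores <- 0.3 * ages + rnorm(n, sd = 0.6) + 1.5 * labels
  tr <- cutoff_trend(scores, labels, ages, sex, n_boot = 100, seed = 5)
  est <- as.data.frame(tr)
  est <- est[est$estimable, ]
  for (s in c("M", "F")) {
    cuts <- est$cutoff[est$sex == s][order(est$age[est$sex == s])]
    expect_gt(cor(seq_along(cuts), cuts, method = "spearman"), 0.8)
  }
  # a small stratum is flagged, not estimated
  small <- cutoff_trend(scores[1:100], labels[1:100], rep(12.5, 100),
                        rep(c("M", "F"), 50), min_n = 200, n_boot = 50)
  expect_true(all(!small$estimable))
  expect_true(all(is.na(small$cutoff)))
  # determinism
  tr2 <- cutoff_trend(scores, labels, ages, sex, n_boot = 100, seed = 5)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
})

test_that("per-age sex comparison holds its size under the null", {
  set.seed(28)
  rejections <- 0
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    n <- 240  # one age stratum, same generator for both sexes
    sex <- rep(c("M", "F"), each = n / 2)
    labels <- rbinom(n, 1, 0.4)
    scores <- rnorm(n) + 1.2 * labels
    tr <- cutoff_trend(scores, labels, rep(13.5, n), sex, n_boot = 199,
                       seed = i, min_n = 30)
    p <- attr(tr, "sex_diff")$p_value[1]
    if (!is.na(p) && p < 0.05) rejections <- rejections + 1
  }
  expect_lt(rejections / n_rep, 0.12)
})

test_that("a single stratum with perfect separation pins the cutoff", {
  scores <- c(rep(1, 25), rep(3, 25))
  labels <- c(rep(0, 25), rep(1, 25))
  tr <- cutoff_trend(scores, labels, rep(14.2, 50), rep("M", 50),
                     n_boot = 50, min_n = 30)
  est <- as.data.frame(tr)
  expect_equal(est$cutoff[est$sex == "M" & est$age == 14], 3)
})
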