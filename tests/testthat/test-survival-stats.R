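test_that("Cox regression recovers known hazard ratios and the null", {
  ch <- generate_cohort(cohort_spec(2000, clinical_beta = c(sex_male = log(2)),
                                    censoring_rate = 0, seed = 21))
  tb <- cox_fit(ch, "sex", mode = "univariate")$table
  expect_gt(tb$hr, 1.8); expect_lt(tb$hr, 2.2)
  expect_true(tb$ci_low <= 2 && 2 <= tb$ci_high)

  # covariate independent of survival: CI covers 1
  tb0 <- cox_fit(ch, "tnm", mode = "univariate")$table
  expect_true(tb0$ci_low <= 1 && 1 <= tb0$ci_high)

  # duplicated covariate: singular design
  ch$sex2 <- ch$sex
  expect_error(cox_fit(ch, c("sex", "sex2"), mode = "multivariate"),
               "singular|aliased")

  # time rescaling leaves the HR unchanged
  chd <- ch; chd$os_months <- chd$os_months * 30.44
  expect_equal(cox_fit(chd, "sex", mode = "univariate")$table$hr, tb$hr,
               tolerance = 1e-8)
})

test_that("Kaplan-Meier estimates equal empirical survival without censoring", {
  d <- data.frame(os_months = c(1, 2, 3, 4), event = 1)
  expect_equal(km_at(d$os_months, d$event, 2.5), 0.5)

  ch <- generate_cohort(cohort_spec(500, censoring_rate = 0, seed = 3))
  ts <- sort(ch$os_months)[c(50, 250, 450)]
  for (t in ts) {
    expect_equal(km_at(ch$os_months, ch$event, t),
                 mean(ch$os_months > t), tolerance = 1e-12)
  }

  g <- rep(c("a", "b"), 250)
  expect_error(km_logrank(data.frame(os_months = 1:500, event = 0), g),
               "events")
  expect_error(km_logrank(ch, rep("a", 500)), "two groups")
})

test_that("the log-rank test is calibrated under the null", {
  ch <- generate_cohort(cohort_spec(2000, censoring_rate = 0.2, seed = 8))
  ps <- vapply(1:100, function(sd) {
    g <- withr::with_seed(sd, sample(rep(c("g1", "g2"), 1000)))
    km_logrank(ch, g)$logrank_p
  }, numeric(1))
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("ROC analysis, AUC and the Youden cutoff behave as defined", {
  r <- roc_youden(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_gt(r$cutoff, 2); expect_lt(r$cutoff, 3)

  # perfectly separating score on a larger sample
  y <- rep(0:1, each = 100)
  r2 <- roc_youden(c(rnorm(100), rnorm(100) + 50), y)
  expect_equal(r2$auc, 1)
  expect_equal(r2$youden_j, 1)

  # outcome-independent score concentrates near AUC 1/2
  set.seed(7)
  r3 <- roc_youden(rnorm(2000), rbinom(2000, 1, 0.5))
  expect_gte(r3$auc, 0.45); expect_lte(r3$auc, 0.55)

  # AUC(score) = 1 - AUC(-score)
  set.seed(8)
  s <- rnorm(300); yy <- rbinom(300, 1, stats::plogis(s))
  expect_equal(roc_youden(s, yy)$auc, 1 - roc_youden(-s, yy)$auc,
               tolerance = 1e-12)

  expect_error(roc_youden(rnorm(10), rep(1, 10)), "classes")
})

test_that("a Youden cutoff transfers across splits of one distribution", {
  sim <- function(sd) {
    withr::with_seed(sd, {
      s <- rnorm(1000)
      y <- rbinom(1000, 1, stats::plogis(1.5 * s))
      list(s = s, y = y)
    })
  }
  tr <- sim(31); va <- sim(32)
  r <- roc_youden(tr$s, tr$y)
  cls <- as.integer(va$s > r$cutoff)
  sens <- mean(cls[va$y == 1]); spec <- mean(1 - cls[va$y == 0])
  j_va <- sens + spec - 1
  expect_lt(abs(j_va - r$youden_j), 0.15)
})

test_that("nomogram point scales are normalized and map back to survival", {
  ch <- generate_cohort(cohort_spec(600,
                                    clinical_beta = c(lvi_yes = 0.8),
                                    censoring_rate = 0.25, seed = 5))
  cm <- cox_fit(ch, "lvi", mode = "multivariate")
  nm <- build_nomogram(cm, ch)
  pts <- nm$point_tables
  expect_equal(sort(pts$points), c(0, 100))  # single binary covariate

  # all patients at reference level score 0 points; others 100
  tp <- nomogram_points(nm, ch)
  expect_true(all(tp[ch$lvi == "No"] == 0))
  expect_true(all(abs(tp[ch$lvi == "Yes"] - 100) < 1e-8))

  # patient at reference level: predicted survival equals the baseline
  ref <- ch[ch$lvi == "No", ][1, ]
  bh <- nm$baseline_cumhaz
  h0 <- stats::approx(bh$time, bh$hazard, xout = 12, method = "constant",
                      rule = 2)$y
  expect_equal(predict_survival(nm, ref, 12), exp(-h0), tolerance = 1e-12)

  # total points increase strictly with the linear predictor
  cm2 <- cox_fit(ch, c("lvi", "tnm", "fea1"), mode = "multivariate")
  nm2 <- build_nomogram(cm2, ch)
  lp <- collascore:::predict_lp(cm2$fit, ch)
  tp2 <- nomogram_points(nm2, ch)
  ord <- order(lp)
  expect_true(all(diff(tp2[ord]) >= -1e-9))

  expect_error(predict_survival(nm, ch, 1e6), "horizon")
})

test_that("calibration of a correctly specified model is close to ideal", {
  ch <- generate_cohort(cohort_spec(2000, clinical_beta = c(tnm_high = 0.7),
                                    censoring_rate = 0.2, seed = 12))
  cm <- cox_fit(ch, "tnm", mode = "multivariate")
  nm <- build_nomogram(cm, ch)
  pred <- predict_survival(nm, ch, 12)
  cal <- calibration_curve(pred, ch, 12, n_bins = 4)
  expect_lte(mean(abs(cal$predicted - cal$observed)), 0.05)

  # constant predictor: single populated bin equals the overall KM
  cal1 <- calibration_curve(rep(0.5, nrow(ch)), ch, 12, n_bins = 4)
  expect_equal(nrow(cal1), 1)
  expect_equal(cal1$observed, km_at(ch$os_months, ch$event, 12))

  # one bin: overall mean prediction vs overall KM
  calb <- calibration_curve(pred, ch, 12, n_bins = 1)
  expect_equal(calb$predicted, mean(pred))
})

test_that("feature-OS correlations hit the exact and null limits", {
  ch <- generate_cohort(cohort_spec(200, seed = 2))
  ch$fx <- ch$os_months
  ch$fy <- -ch$os_months
  fc <- feature_os_correlation(ch, columns = c("fx", "fy"),
                               method = "spearman")
  expect_equal(fc$estimate, c(1, -1))

  ch$fz <- 1
  expect_error(feature_os_correlation(ch, columns = "fz"), "variance")

  # independent feature: |rho| <= 0.06 in at least 95% of 100 replicates
  ch2 <- generate_cohort(cohort_spec(2000, seed = 3))
  hits <- vapply(1:100, function(sd) {
    x <- withr::with_seed(sd, rnorm(2000))
    abs(stats::cor(x, ch2$os_months, method = "spearman")) <= 0.06
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
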