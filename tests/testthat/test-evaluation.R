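test_that("thresholds are inclusive empirical quantiles of noncase scores", {
  th <- derive_thresholds(1:100, levels = 0.90)
  expect_equal(unname(th), 90)
  expect_identical(sum(1:100 > th), 10L)      # exactly 10 exceed it
  # degenerate: all scores equal -> threshold that value, nothing alerts
  th <- derive_thresholds(rep(2.5, 50), levels = c(0.90, 0.99))
  expect_equal(unname(th), c(2.5, 2.5))
  expect_identical(sum(rep(2.5, 50) > th[1]), 0L)
  # thresholds nondecreasing in the level
  set.seed(71)
  x <- rnorm(1000)
  th <- derive_thresholds(x, levels = c(0.5, 0.9, 0.99))
  expect_true(all(diff(th) >= 0))
  # quantile oracle: fraction strictly above the 0.99 threshold <= 0.01
  x <- rnorm(10000)
  th <- derive_thresholds(x, levels = 0.99)
  expect_lte(mean(x > th), 0.01)
  expect_error(derive_thresholds(numeric(0)), "at least one")
  expect_error(derive_thresholds(1:10, levels = 1.5), "levels")
})

test_that("confusion metrics match a brute-force 2x2 tabulation", {
  # perfectly separated scores
  sc <- c(rep(10, 5), rep(0, 20)); lb <- rep(c("case", "noncase"), c(5, 20))
  cm <- confusion_at_threshold(sc, lb, 5)
  expect_equal(cm$sensitivity, 1); expect_equal(cm$ppv, 1)
  expect_equal(cm$specificity, 1)
  # threshold above all scores -> sensitivity 0, NPV = noncase fraction
  cm <- confusion_at_threshold(sc, lb, 100)
  expect_equal(cm$sensitivity, 0)
  expect_equal(cm$npv, 20 / 25)
  expect_true(is.na(cm$ppv))
  # random instance vs direct enumeration oracle
  set.seed(73)
  sc <- rnorm(500); lb <- sample(c("case", "noncase"), 500, TRUE)
  th <- 0.3
  cm <- confusion_at_threshold(sc, lb, th)
  tp <- sum(sc > th & lb == "case"); fp <- sum(sc > th & lb == "noncase")
  fn <- sum(sc <= th & lb == "case"); tn <- sum(sc <= th & lb == "noncase")
  expect_equal(cm$sensitivity, tp / (tp + fn))
  expect_equal(cm$specificity, tn / (tn + fp))
  expect_equal(cm$ppv, tp / (tp + fp))
  expect_equal(cm$npv, tn / (tn + fn))
  expect_error(confusion_at_threshold(1:5, rep("case", 5), 2), "both classes")
})

test_that("the AUC is the Mann-Whitney probability with tie correction", {
  # identical distributions -> 0.5
  x <- c(1, 2, 3, 4)
  expect_equal(auc_mw(x, x)$auc, 0.5)
  # complete separation -> 1
  expect_equal(auc_mw(c(5, 6), c(1, 2))$auc, 1)
  # brute-force pairwise oracle with ties
  set.seed(79)
  for (i in 1:20) {
    cs <- sample(1:8, 30, TRUE); ns <- sample(1:8, 30, TRUE)
    a <- auc_mw(cs, ns)$auc
    oracle <- mean(outer(cs, ns, ">") + 0.5 * outer(cs, ns, "=="))
    expect_equal(a, oracle, tolerance = 1e-12)
  }
  expect_error(auc_mw(numeric(0), 1:3), "non-empty")
})

test_that("the AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  for (i in 1:25) {
    n1 <- sample(10:60, 1); n0 <- sample(10:60, 1)
    cs <- round(rnorm(n1), 2); ns <- round(rnorm(n0, -0.3), 2)
    a <- auc_mw(cs, ns)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = rep(c(1, 0), c(n1, n0)), predictor = c(cs, ns),
      quiet = TRUE, direction = "<")))
    expect_equal(a, ref, tolerance = 1e-9)
  }
})

test_that("Hanley-McNeil standard errors match the closed form", {
  cs <- c(3, 5, 7, 9); ns <- c(1, 2, 4, 6)
  a <- auc_mw(cs, ns)
  A <- a$auc
  q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + 3 * (q1 - A^2) + 3 * (q2 - A^2)) / 16)
  expect_equal(a$se, se, tolerance = 1e-12)
  expect_equal(a$ci_high, min(1, A + 1.96 * se))
})

test_that("timeliness summaries average detected cases with a normal CI", {
  s <- timeliness_summary(c(1, 3))
  expect_equal(s$mean, 2); expect_identical(s$n_detected, 2L)
  # single detection: mean defined, CI absent
  s <- timeliness_summary(2.5)
  expect_equal(s$mean, 2.5)
  expect_true(is.na(s$ci_low))
  # none detected: absent mean, not an error
  s <- timeliness_summary(numeric(0))
  expect_identical(s$n_detected, 0L)
  expect_true(is.na(s$mean))
  # closed-form normal-approximation oracle on simulated lead times
  set.seed(89)
  lt <- rexp(100, rate = 0.5)
  s <- timeliness_summary(lt)
  expect_equal(s$mean, mean(lt))
  expect_equal(s$ci_low, mean(lt) - 1.96 * sd(lt) / 10, tolerance = 1e-12)
  expect_error(timeliness_summary(c(1, -0.2)), ">= 0")
})

test_that("decile tables apportion by noncase score quantiles", {
  # noncase-only input with distinct scores: 10% per decile (+-1 patient)
  sc <- 1:200; lb <- rep("noncase", 200)
  dt <- decile_table(sc, lb)
  expect_identical(nrow(dt), 10L)
  expect_true(all(abs(dt$n_noncase - 20L) <= 1L))
  expect_equal(sum(dt$noncase_pct), 100)
  # strong signal: all case scores in the top decile
  sc <- c(1:100, rep(1000, 10))
  lb <- rep(c("noncase", "case"), c(100, 10))
  dt <- decile_table(sc, lb)
  expect_equal(dt[decile == 10, case_pct], 100)
  expect_equal(sum(dt$case_pct), 100)
  expect_true(dt[decile == 10, case_pct] == max(dt$case_pct))
  expect_error(decile_table(1:5, rep("noncase", 5)), "10 noncases")
})

test_that("site evaluation is internally consistent across levels", {
  spec <- site_spec("ev", 6000, 0.05, 5, 2, seed = 97,
                    concept_catalog = lean_catalog(list(
                      concept_effect("DX", "30183", 0.008, 2.2),
                      concept_effect("DX", "V6284", 0.006, 2.4))))
  res <- run_generated_site(spec, seed_split = 5)$result
  ev <- res$evaluation
  m <- ev$metrics
  expect_identical(nrow(m), 2L)
  # sensitivity nonincreasing, PPV nondecreasing in specificity level
  expect_lte(m[level == 0.99, sensitivity], m[level == 0.90, sensitivity])
  expect_gte(m[level == 0.99, ppv], m[level == 0.90, ppv])
  # realized specificity at least near nominal
  expect_gt(m[level == 0.90, specificity], 0.88)
  expect_gt(m[level == 0.99, specificity], 0.985)
  # later alerts at stricter thresholds
  expect_lte(m[level == 0.99, mean_lead_time_years],
             m[level == 0.90, mean_lead_time_years])
  expect_lte(m[level == 0.99, n_detected], m[level == 0.90, n_detected])
  # detected counts bounded by validation cases
  expect_lte(max(m$n_detected), ev$n_validation_cases)
  # decile percentages sum to 100 per class
  expect_equal(sum(ev$decile_table$case_pct), 100, tolerance = 1e-9)
  expect_equal(sum(ev$decile_table$noncase_pct), 100, tolerance = 1e-9)
  # planted signal shows up as discrimination
  expect_gt(ev$auc, 0.6)
})
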