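test_that("the train/validation split is disjoint, exhaustive and seeded", {
  ids <- sprintf("p%03d", 1:100)
  sp <- split_cohort(ids, fraction = 0.5, seed = 4)
  expect_length(sp$train, 50L)
  expect_length(sp$validation, 50L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_identical(sp, split_cohort(ids, fraction = 0.5, seed = 4))
  expect_false(identical(sp$train, split_cohort(ids, 0.5, seed = 5)$train))
  expect_error(split_cohort(ids, fraction = 0), "fraction")
  expect_error(split_cohort(ids, fraction = 1.2), "fraction")
})

test_that("unstratified splitting preserves the case fraction on average", {
  # binomial/hypergeometric sampling oracle: mean training-case fraction over
  # 200 reseeded splits of a 10%-case cohort is 0.10 within 3 SE, where
  # var(frac) = p(1-p)/n * (N-n)/(N-1) for sampling without replacement
  ids <- sprintf("p%03d", 1:200)
  is_case <- ids %in% ids[1:20]
  names(is_case) <- ids
  fracs <- vapply(1:200, function(s)
    mean(is_case[split_cohort(ids, 0.5, seed = s)$train]), numeric(1))
  se_mean <- sqrt(0.1 * 0.9 / 100 * (100 / 199)) / sqrt(200)
  expect_lt(abs(mean(fracs) - 0.10), 3 * se_mean)
})

test_that("partial scores follow the smoothed log prevalence ratio", {
  # equal prevalence with equal margins -> exactly 0 for any k
  expect_equal(partial_score(10, 90, 10, 90, k = 1), 0)
  expect_equal(partial_score(10, 90, 10, 90, k = 7), 0)
  # equal prevalence with unequal margins: the smoothing pseudocount pulls
  # both classes toward 1/2 at different strengths, so the score is only
  # asymptotically zero (and vanishes as counts grow at fixed prevalence)
  expect_equal(partial_score(100, 900, 1000, 9000, k = 1), 0, tolerance = 0.01)
  expect_lt(abs(partial_score(100, 900, 1000, 9000, k = 1)),
            abs(partial_score(10, 90, 100, 900, k = 1)))
  # hand-computed from the formula: log((51/1002)/(11/1002)) = log(51/11)
  expect_equal(partial_score(50, 950, 10, 990, k = 1), log(51 / 11),
               tolerance = 1e-12)
  # smoothing keeps an all-absent-in-cases concept finite and protective
  s <- partial_score(0, 100, 50, 50, k = 1)
  expect_true(is.finite(s) && s < 0)
  expect_error(partial_score(-1, 1, 1, 1), "nonnegative")
  expect_error(partial_score(0, 0, 1, 1), "margins")
  expect_error(partial_score(1, 1, 1, 1, k = 0), "k")
})

test_that("partial scores obey the sign law and monotonicity in a", {
  set.seed(31)
  for (i in 1:200) {
    n1 <- sample(5:500, 1); n0 <- sample(5:500, 1)
    a <- sample(0:n1, 1); cc <- sample(0:n0, 1)
    k <- runif(1, 0.1, 5)
    s <- partial_score(a, n1 - a, cc, n0 - cc, k = k)
    p1 <- (a + k) / (n1 + 2 * k)
    p0 <- (cc + k) / (n0 + 2 * k)
    expect_identical(s > 0, p1 > p0)
  }
  a_seq <- 0:50
  s_seq <- partial_score(a_seq, 30, 10, 90, k = 1)
  expect_true(all(diff(s_seq) > 0))
})

test_that("odds ratios use the cross-product with zero-cell correction", {
  o <- compute_or(30, 70, 10, 90)
  expect_equal(o$or, (30 * 90) / (70 * 10), tolerance = 1e-12)  # 3.857
  # symmetric table: OR 1, CI straddles 1
  o <- compute_or(10, 10, 10, 10)
  expect_equal(o$or, 1)
  expect_lt(o$ci_low, 1); expect_gt(o$ci_high, 1)
  # zero cell: Haldane-Anscombe keeps everything finite
  o <- compute_or(5, 0, 10, 90)
  expect_true(is.finite(o$or) && is.finite(o$ci_high))
  expect_equal(o$or, (5.5 * 90.5) / (0.5 * 10.5), tolerance = 1e-12)
  expect_error(compute_or(-1, 1, 1, 1), "nonnegative")
})

test_that("site models score every training concept and reject single classes", {
  spec <- site_spec("tm", 2500, 0.06, 4, 2, seed = 37,
                    concept_catalog = lean_catalog(
                      list(concept_effect("DX", "30183", 0.006, 2))))
  site <- generate_site(spec)
  cohort <- build_cohort(site$patients, site$events)
  tl <- extract_timelines(cohort)
  model <- train_site_model(tl, k = 1, site_id = "tm")
  uni <- concept_universe(tl)
  expect_setequal(names(model$scores), uni$concept)
  expect_true(all(is.finite(model$scores)))
  # sign law across all trained concepts
  st <- model$stats
  p1 <- (st$a + 1) / (model$n_cases + 2)
  p0 <- (st$c + 1) / (model$n_noncases + 2)
  expect_identical(st$partial_score > 0, p1 > p0)
  # the planted adverse concept gets a positive score
  expect_gt(model$scores[["DX:30183"]], 0)

  # single-class training set errors
  nc_only <- subset_timelines(tl, tl$patients[label == "noncase", patient_id])
  expect_error(train_site_model(nc_only), "both cases and noncases")
})

test_that("a concept present in every patient scores approximately zero", {
  tl <- structure(list(
    features = data.table::data.table(
      patient_id = sprintf("p%02d", 1:40),
      date = as.Date("2010-01-01"),
      concept = "PX:everyone"),
    patients = data.table::data.table(
      patient_id = sprintf("p%02d", 1:40),
      label = rep(c("case", "noncase"), each = 20),
      index_date = as.Date(NA))), class = "feature_timelines")
  model <- train_site_model(tl, k = 1)
  expect_equal(unname(model$scores[["PX:everyone"]]), 0, tolerance = 0.01)
})

test_that("scores and ORs converge to the planted values as sites grow", {
  # scaled sequence of sites with one planted concept; estimates approach
  # the prevalence-ratio log score and the planted OR
  errs <- vapply(c(2000, 16000), function(n) {
    spec <- site_spec("gr", n, 0.05, 4, 2, seed = 41,
                      concept_catalog = lean_catalog(
                        list(concept_effect("DX", "29650", 0.01, 1.5))))
    site <- generate_site(spec)
    res <- run_site(site$patients, site$events, pipeline_config(seed = 2), "gr")
    abs(log(res$model$stats[concept == "DX:29650", or]) - 1.5)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.35)
})

test_that("sites with different planted effects learn different models", {
  mk <- function(code, lor, seed) {
    spec <- site_spec(paste0("s", seed), 3000, 0.06, 4, 2, seed = seed,
                      concept_catalog = lean_catalog(list(
                        concept_effect("DX", "30183", 0.008, lor),
                        concept_effect("DX", "29650", 0.008, 2.2 - lor))))
    site <- generate_site(spec)
    run_site(site$patients, site$events, pipeline_config(seed = 1))$model
  }
  m1 <- mk("a", 2.2, 51); m2 <- mk("b", 0, 52)
  expect_gt(m1$scores[["DX:30183"]], m2$scores[["DX:30183"]] + 0.5)
  expect_gt(m2$scores[["DX:29650"]], m1$scores[["DX:29650"]] + 0.5)
})

test_that("the reporting filter mirrors the published table rules", {
  stats <- data.table::data.table(
    concept = c("DX:rare", "DX:fewcases", "DX:common"),
    a = c(3L, 5L, 50L), b = c(97L, 95L, 50L),
    c = c(50L, 200L, 400L), d = c(850L, 700L, 500L))
  stats[, partial_score := partial_score(a, b, c, d)]
  stats <- cbind(stats, compute_or(stats$a, stats$b, stats$c, stats$d))
  rep <- concept_report(stats, min_patients = 100L, min_case_patients = 10L)
  # DX:rare has 53 carriers -> dropped entirely
  expect_false("DX:rare" %in% rep$concept)
  # DX:fewcases has 205 carriers but < 10 case carriers -> OR suppressed
  expect_true(is.na(rep[concept == "DX:fewcases", or]))
  expect_false(is.na(rep[concept == "DX:fewcases", partial_score]))
  # DX:common fully reported, ordered first by case share
  expect_identical(rep$concept[1], "DX:common")
  expect_equal(rep[concept == "DX:common", case_pct],
               round(100 * 50 / 450, 1))
})
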