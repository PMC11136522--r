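# Threshold derivation and site-level performance metrics.
#
# Alert thresholds are specificity quantiles of the TRAINING split's noncase
# maximal scores (the leak-free reading); metrics are computed on the
# validation split: sensitivity/specificity/PPV/NPV at each level, AUC with a
# Hanley-McNeil standard error, mean prediction lead time with a normal 95%
# CI over detected cases, and the decile enrichment table whose boundaries
# come from the validation noncase score distribution.

#' Derive alert thresholds at target specificity levels
#'
#' Threshold for level q is the inclusive (type-1) empirical q-quantile of
#' the noncase maximal scores: the smallest observed score with at least a
#' fraction q of scores less than or equal to it.  Because an alert requires
#' strictly exceeding the threshold, the realised specificity on the defining
#' set is always >= q.
#'
#' @param noncase_max_scores Maximal scores of (training) noncases.
#' @param levels Specificity levels in (0, 1), default `c(0.90, 0.99)`.
#' @return Named numeric vector of thresholds (names are the levels),
#'   nondecreasing in the level.
#' @export
derive_thresholds <- function(noncase_max_scores, levels = c(0.90, 0.99)) {
  if (!length(noncase_max_scores))
    stop("derive_thresholds: need at least one noncase score")
  if (any(levels <= 0 | levels >= 1))
    stop("derive_thresholds: levels must lie in (0, 1)")
  levels <- sort(levels)
  th <- quantile(noncase_max_scores, probs = levels, type = 1, names = FALSE)
  stats::setNames(th, format(levels, trim = TRUE))
}

#' Confusion metrics at a threshold
#'
#' Alert = maximal score strictly greater than the threshold; standard 2x2
#' definitions at the set's natural prevalence.
#'
#' @param scores Maximal scores.
#' @param labels `"case"`/`"noncase"` per score.
#' @param threshold Alert threshold.
#' @return List (sensitivity, specificity, ppv, npv, tp, fp, fn, tn); PPV is
#'   `NA` when nothing alerts.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  is_case <- labels == "case"
  if (!any(is_case) || all(is_case))
    stop("confusion_at_threshold: both classes must be present")
  alert <- scores > threshold
  tp <- sum(alert & is_case); fp <- sum(alert & !is_case)
  fn <- sum(!alert & is_case); tn <- sum(!alert & !is_case)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Mann-Whitney AUC with Hanley-McNeil standard error
#'
#' AUC is the probability that a random case scores above a random noncase,
#' counting ties as one half (midrank estimator).  The standard error follows
#' Hanley & McNeil's formula; the 95% CI is `auc +/- 1.96 se`, clipped to
#' `[0, 1]`.
#'
#' @param case_scores,noncase_scores Non-empty numeric vectors.
#' @return List (auc, se, ci_low, ci_high).
#' @export
auc_mw <- function(case_scores, noncase_scores) {
  n1 <- length(case_scores); n0 <- length(noncase_scores)
  if (!n1 || !n0) stop("auc_mw: both classes must be non-empty")
  r <- rank(c(case_scores, noncase_scores))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  list(auc = auc, se = se,
       ci_low = max(0, auc - 1.96 * se),
       ci_high = min(1, auc + 1.96 * se))
}

#' Mean prediction lead time over detected cases
#'
#' Arithmetic mean of the lead times of cases whose trajectory crossed the
#' threshold, with a normal-approximation 95% CI (`mean +/- 1.96 sd/sqrt(n)`).
#' With one detection the CI is undefined; with none, the mean too.
#'
#' @param lead_times Nonnegative lead times in years (detected cases only).
#' @return List (n_detected, mean, ci_low, ci_high).
#' @export
timeliness_summary <- function(lead_times) {
  lead_times <- lead_times[!is.na(lead_times)]
  if (any(lead_times < 0)) stop("timeliness_summary: lead times must be >= 0")
  n <- length(lead_times)
  if (n == 0L)
    return(list(n_detected = 0L, mean = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_))
  m <- mean(lead_times)
  if (n == 1L)
    return(list(n_detected = 1L, mean = m,
                ci_low = NA_real_, ci_high = NA_real_))
  half <- 1.96 * sd(lead_times) / sqrt(n)
  list(n_detected = n, mean = m, ci_low = m - half, ci_high = m + half)
}

#' Decile enrichment table
#'
#' Decile boundaries are the 10%,...,90% (type-1) quantiles of the noncase
#' maximal scores; patients of both classes are apportioned into the
#' resulting ten bins and each class is expressed as a percentage of its own
#' total, so each class column sums to 100 (up to rounding).
#'
#' @param scores Maximal scores.
#' @param labels `"case"`/`"noncase"` per score.
#' @return data.table (decile, n_case, n_noncase, case_pct, noncase_pct).
#' @export
decile_table <- function(scores, labels) {
  nc_scores <- scores[labels == "noncase"]
  if (length(nc_scores) < 10L)
    stop("decile_table: need at least 10 noncases")
  b <- quantile(nc_scores, probs = seq(0.1, 0.9, by = 0.1), type = 1,
                names = FALSE)
  dec <- findInterval(scores, b, left.open = TRUE) + 1L
  out <- data.table(decile = 1:10)
  counts <- data.table(decile = dec, label = labels)[
    , .(n_case = sum(label == "case"), n_noncase = sum(label == "noncase")),
    by = decile]
  out <- merge(out, counts, by = "decile", all.x = TRUE)
  out[is.na(n_case), n_case := 0L]
  out[is.na(n_noncase), n_noncase := 0L]
  tot_case <- sum(out$n_case); tot_nc <- sum(out$n_noncase)
  out[, case_pct := if (tot_case > 0) 100 * n_case / tot_case else NA_real_]
  out[, noncase_pct := 100 * n_noncase / tot_nc]
  out[]
}

#' Evaluate one site's validation split
#'
#' Derives thresholds from the training noncases' maximal scores, then
#' computes on the validation split: confusion metrics and timeliness at each
#' specificity level, AUC with SE, and the decile table.
#'
#' @param traj_train Training-split `risk_trajectories` (threshold source).
#' @param traj_validation Validation-split `risk_trajectories`.
#' @param levels Specificity levels, default `c(0.90, 0.99)`.
#' @param site_id Site label.
#' @return Object of class `site_evaluation` with `metrics` (one row per
#'   level), `auc`, `auc_se`, `auc_ci`, `decile_table`, `thresholds` and
#'   validation counts.  Aggregate-only: no patient-level fields.
#' @export
evaluate_site <- function(traj_train, traj_validation,
                          levels = c(0.90, 0.99), site_id = "site") {
  stopifnot(inherits(traj_train, "risk_trajectories"),
            inherits(traj_validation, "risk_trajectories"))
  thr <- derive_thresholds(
    traj_train$summary[label == "noncase", max_score], levels)
  val <- traj_validation$summary
  if (!nrow(val[label == "case"]) || !nrow(val[label == "noncase"]))
    stop("evaluate_site: validation split must contain both classes")
  rows <- vector("list", length(thr))
  for (i in seq_along(thr)) {
    lev <- as.numeric(names(thr)[i])
    cm <- confusion_at_threshold(val$max_score, val$label, thr[i])
    cr <- crossing_times(traj_validation, thr[i])
    tl <- timeliness_summary(cr[label == "case" & !is.na(first_crossing_date),
                                lead_time_years])
    rows[[i]] <- data.table(
      level = lev, threshold = unname(thr[i]),
      sensitivity = cm$sensitivity, specificity = cm$specificity,
      ppv = cm$ppv, npv = cm$npv,
      n_detected = tl$n_detected, mean_lead_time_years = tl$mean,
      lead_ci_low = tl$ci_low, lead_ci_high = tl$ci_high)
  }
  a <- auc_mw(val[label == "case", max_score],
              val[label == "noncase", max_score])
  structure(list(
    site_id = site_id,
    n_validation_cases = val[, sum(label == "case")],
    n_validation_noncases = val[, sum(label == "noncase")],
    thresholds = thr,
    metrics = rbindlist(rows),
    auc = a$auc, auc_se = a$se, auc_ci = c(a$ci_low, a$ci_high),
    decile_table = decile_table(val$max_score, val$label)),
    class = "site_evaluation")
}

#' @export
print.site_evaluation <- function(x, ...) {
  cat(sprintf(
    "<site_evaluation> site '%s': %d validation cases / %d noncases, AUC %.3f (SE %.3f)\n",
    x$site_id, x$n_validation_cases, x$n_validation_noncases, x$auc, x$auc_se))
  print(x$metrics[, .(level, sensitivity = round(sensitivity, 3),
                      specificity = round(specificity, 3),
                      ppv = round(ppv, 3), npv = round(npv, 3),
                      n_detected,
                      mean_lead_time_years = round(mean_lead_time_years, 2))])
  invisible(x)
}
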