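# Site-specific naive Bayes trainer.
#
# Each concept gets a partial risk score: the natural log of the ratio of its
# smoothed prevalence among cases to its smoothed prevalence among noncases
# in the training split.  Positive scores are adverse, negative protective.
# Additive smoothing with pseudocount k (denominator +2k) keeps every score
# finite; absent concepts contribute nothing when scoring (the
# absence-likelihood term of a full naive Bayes is deliberately not used --
# patients accumulate only the scores of features actually recorded).

#' Split a cohort into training and validation sets
#'
#' Patient-level simple random split (unstratified), reproducible from the
#' seed; the two sets are disjoint and exhaustive.
#'
#' @param x An `ehr_cohort`, a `feature_timelines`, or a character vector of
#'   patient ids.
#' @param fraction Training fraction in (0, 1); default 0.5.
#' @param seed Integer seed for the split.
#' @return List with character vectors `train` and `validation`.
#' @export
split_cohort <- function(x, fraction = 0.5, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("split_cohort: fraction must lie in (0, 1)")
  ids <- if (inherits(x, "ehr_cohort")) x$patients$patient_id
         else if (inherits(x, "feature_timelines")) x$patients$patient_id
         else as.character(x)
  if (!length(ids)) stop("split_cohort: empty cohort")
  set.seed(seed)
  n_train <- round(fraction * length(ids))
  train <- sort(sample(ids, n_train))
  list(train = train, validation = sort(setdiff(ids, train)))
}

#' Smoothed log prevalence-ratio partial risk score
#'
#' `log(((a+k)/(a+b+2k)) / ((c+k)/(c+d+2k)))` with `a`/`b` the cases with and
#' without the concept and `c`/`d` the noncases with and without it.  Natural
#' logarithm; always finite for `k > 0`.
#'
#' @param a,b,c,d Nonnegative 2x2 counts (vectorised); `a+b > 0`, `c+d > 0`.
#' @param k Smoothing pseudocount (> 0), default 1.
#' @return Numeric vector of partial scores.
#' @export
partial_score <- function(a, b, c, d, k = 1) {
  if (any(c(a, b, c, d) < 0)) stop("partial_score: counts must be nonnegative")
  if (any(a + b <= 0) || any(c + d <= 0))
    stop("partial_score: class margins must be positive")
  if (!is.numeric(k) || k <= 0) stop("partial_score: k must be > 0")
  log(((a + k) / (a + b + 2 * k)) / ((c + k) / (c + d + 2 * k)))
}

#' Odds ratio with 95% confidence interval
#'
#' Cross-product odds ratio `(a*d)/(b*c)`.  If any cell is zero, 0.5 is added
#' to all four cells (Haldane-Anscombe) before both the OR and its CI; the
#' Woolf interval `exp(log OR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))` is computed on
#' the (possibly corrected) cells.
#'
#' @param a,b,c,d Nonnegative 2x2 counts (vectorised); `a+b > 0`, `c+d > 0`.
#' @return data.table (or, ci_low, ci_high).
#' @export
compute_or <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("compute_or: counts must be nonnegative")
  if (any(a + b <= 0) || any(c + d <= 0))
    stop("compute_or: class margins must be positive")
  zero <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  corr <- fifelse(zero, 0.5, 0)
  aa <- a + corr; bb <- b + corr; cc <- c + corr; dd <- d + corr
  or <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  data.table(or = or,
             ci_low = exp(log(or) - 1.96 * se),
             ci_high = exp(log(or) + 1.96 * se))
}

#' Train a site-specific naive Bayes scorer
#'
#' One partial score, odds ratio and 95% CI per concept in the training
#' universe; deterministic given its inputs.
#'
#' @param timelines Training-split `feature_timelines`.
#' @param k Smoothing pseudocount, default 1.
#' @param site_id Site label carried into the model.
#' @return Object of class `site_nbc`: list with `site_id`, `scores` (named
#'   numeric, concept to partial score), `stats` (per-concept 2x2 counts,
#'   partial_score, or, ci), `k`, `n_cases`, `n_noncases`.
#' @export
train_site_model <- function(timelines, k = 1, site_id = "site") {
  stopifnot(inherits(timelines, "feature_timelines"))
  n_cases <- timelines$patients[, sum(label == "case")]
  n_noncases <- timelines$patients[, sum(label == "noncase")]
  if (n_cases == 0L || n_noncases == 0L)
    stop("train_site_model: training set must contain both cases and noncases")
  uni <- concept_universe(timelines)
  stats <- data.table(
    concept = uni$concept,
    a = uni$n_case, b = n_cases - uni$n_case,
    c = uni$n_noncase, d = n_noncases - uni$n_noncase)
  stats[, partial_score := partial_score(a, b, c, d, k = k)]
  stats <- cbind(stats, compute_or(stats$a, stats$b, stats$c, stats$d))
  if (any(!is.finite(stats$partial_score)))
    stop("train_site_model: non-finite partial score (invariant violated)")
  structure(list(site_id = site_id,
                 scores = stats[, stats::setNames(partial_score, concept)],
                 stats = stats[], k = k,
                 n_cases = n_cases, n_noncases = n_noncases),
            class = "site_nbc")
}

#' Reporting filter for per-concept statistics
#'
#' Keeps concepts carried by at least `min_patients` patients (cases and
#' noncases combined) and suppresses the OR and CI of concepts with fewer
#' than `min_case_patients` case carriers; rows are ordered by descending
#' case share (share of carriers who are cases, as a percentage).
#'
#' @param stats Per-concept stats table (from a `site_nbc` or pooled).
#' @param min_patients Minimum carriers to report a concept, default 100.
#' @param min_case_patients Minimum case carriers to report an OR, default 10.
#' @return Filtered data.table with `n_carriers` and `case_pct` columns.
#' @export
concept_report <- function(stats, min_patients = 100L, min_case_patients = 10L) {
  rep <- as.data.table(stats)[ (a + c) >= min_patients ]
  rep[, n_carriers := a + c]
  rep[, case_pct := round(100 * a / (a + c), 1)]
  rep[a < min_case_patients, `:=`(or = NA_real_, ci_low = NA_real_,
                                  ci_high = NA_real_)]
  setorder(rep, -case_pct, concept)
  rep[]
}

#' @export
print.site_nbc <- function(x, ...) {
  cat(sprintf(
    "<site_nbc> site '%s': %d concepts scored (k = %g) from %d cases / %d noncases\n",
    x$site_id, length(x$scores), x$k, x$n_cases, x$n_noncases))
  invisible(x)
}
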