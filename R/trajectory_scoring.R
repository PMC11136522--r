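# Cumulative risk-score trajectories.
#
# A patient's trajectory is the running sum of partial risk scores over their
# first-occurrence features in chronological order.  Same-date features are
# summed together and only date-level cumulative values are meaningful (a
# trajectory has one step per distinct feature date).  The maximal cumulative
# score is the patient's summary score; "surpassing" a threshold is a strict
# inequality, and 365.25 days make a year when converting lead times.

#' Score all timelines against a site model
#'
#' Features absent from the model contribute a score of 0 (they still occupy
#' their date); patients with no features at all get a maximal score of 0.
#'
#' @param timelines A `feature_timelines` object.
#' @param model A `site_nbc` from [train_site_model()].
#' @return Object of class `risk_trajectories`: list with `steps` (patient_id,
#'   date, cum_score; one row per patient per distinct feature date) and
#'   `summary` (patient_id, label, index_date, max_score, n_steps).
#' @export
score_trajectories <- function(timelines, model) {
  stopifnot(inherits(timelines, "feature_timelines"),
            inherits(model, "site_nbc"))
  f <- copy(timelines$features)
  f[, score := model$scores[concept]]
  f[is.na(score), score := 0]
  day <- f[, .(day_score = sum(score)), by = .(patient_id, date)]
  setorder(day, patient_id, date)
  day[, cum_score := cumsum(day_score), by = patient_id]
  summ <- day[, .(max_score = max(cum_score), n_steps = .N), by = patient_id]
  summ <- merge(timelines$patients, summ, by = "patient_id", all.x = TRUE)
  summ[is.na(max_score), `:=`(max_score = 0, n_steps = 0L)]
  setorder(summ, patient_id)
  structure(list(steps = day[, .(patient_id, date, cum_score)],
                 summary = summ[]),
            class = "risk_trajectories")
}

#' Score a single timeline
#'
#' @param timeline data.table (date, concept) as from [extract_timeline()].
#' @param model A `site_nbc`.
#' @return List with `steps` (date, cum_score) and `max_score`.
#' @export
score_trajectory <- function(timeline, model) {
  tl <- as.data.table(timeline)
  if (!nrow(tl)) return(list(steps = data.table(date = as.Date(character()),
                                                cum_score = numeric()),
                             max_score = 0))
  tl[, score := model$scores[concept]]
  tl[is.na(score), score := 0]
  day <- tl[, .(day_score = sum(score)), by = date]
  setorder(day, date)
  day[, cum_score := cumsum(day_score)]
  list(steps = day[, .(date, cum_score)], max_score = max(day$cum_score))
}

#' First threshold crossing of one trajectory
#'
#' Earliest step date at which the cumulative score strictly exceeds the
#' threshold.  For cases (an `index_date` is supplied) the lead time is the
#' interval from the crossing to the index date in years of 365.25 days.
#' Later dips below the threshold do not move the crossing.
#'
#' @param steps data.table (date, cum_score), ordered by date.
#' @param threshold Alert threshold.
#' @param index_date Optional index date (cases).
#' @return List (threshold, first_crossing_date, lead_time_years); the date
#'   and lead time are `NA` when the trajectory never surpasses the threshold
#'   (or, for the lead time, when no index date is given).
#' @export
first_crossing <- function(steps, threshold, index_date = NULL) {
  st <- as.data.table(steps)
  i <- which(st$cum_score > threshold)
  if (!length(i))
    return(list(threshold = threshold, first_crossing_date = as.Date(NA),
                lead_time_years = NA_real_))
  d <- as.Date(st$date[min(i)])
  lead <- if (!is.null(index_date) && !is.na(index_date))
    as.numeric(as.Date(index_date) - d) / DAYS_PER_YEAR else NA_real_
  list(threshold = threshold, first_crossing_date = d,
       lead_time_years = lead)
}

#' First crossings for every patient at one threshold
#'
#' @param trajectories A `risk_trajectories` object.
#' @param threshold Alert threshold.
#' @return data.table (patient_id, label, index_date, max_score,
#'   first_crossing_date, lead_time_years); lead times only for cases that
#'   cross.
#' @export
crossing_times <- function(trajectories, threshold) {
  stopifnot(inherits(trajectories, "risk_trajectories"))
  cr <- trajectories$steps[cum_score > threshold,
                           .(first_crossing_date = date[1L]), by = patient_id]
  out <- merge(trajectories$summary, cr, by = "patient_id", all.x = TRUE)
  out[, lead_time_years := fifelse(
    !is.na(index_date) & !is.na(first_crossing_date),
    as.numeric(index_date - first_crossing_date) / DAYS_PER_YEAR,
    NA_real_)]
  out[]
}
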