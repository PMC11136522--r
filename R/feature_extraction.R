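# First-occurrence binary concept features.
#
# Every predictor enters the model once, at its earliest date, as a yes/no
# variable.  Laboratory results are split by value flag (test X flagged H is
# a different predictor from X flagged N; a missing flag reads as N).
# Demographic attributes (sex, race/ethnicity, age decade at first contact)
# become DEM concepts dated at the patient's first post-censoring event so
# they occupy a defined place in the chronological cumulative score.

# feature identity string: "DX:30183", "LAB:acetaminophen:H", "DEM:sex:F"
make_concept_id <- function(domain, code, flag = NULL) {
  code <- gsub("[ :]", "_", code)
  if (is.null(flag)) paste(domain, code, sep = ":")
  else paste(domain, code, flag, sep = ":")
}

# vectorised concept ids for an event table (LAB gets its flag, others not)
event_concept_ids <- function(ev) {
  flag <- fifelse(is.na(ev$value_flag) | ev$value_flag == "", "N", ev$value_flag)
  fifelse(ev$domain == "LAB",
          paste(ev$domain, gsub("[ :]", "_", ev$code), flag, sep = ":"),
          paste(ev$domain, gsub("[ :]", "_", ev$code), sep = ":"))
}

demographic_concepts <- function(pats, anchor_dates) {
  age <- as.numeric(anchor_dates - pats$birth_date) / DAYS_PER_YEAR
  age_dec <- pmax(0, floor(age / 10) * 10)
  rbindlist(list(
    data.table(patient_id = pats$patient_id, date = anchor_dates,
               concept = make_concept_id("DEM", paste0("sex_", pats$sex))),
    data.table(patient_id = pats$patient_id, date = anchor_dates,
               concept = make_concept_id("DEM", paste0("race_", pats$race_ethnicity))),
    data.table(patient_id = pats$patient_id, date = anchor_dates,
               concept = make_concept_id("DEM", paste0("age_decade_", age_dec)))
  ))
}

#' Extract first-occurrence feature timelines for a cohort
#'
#' @param cohort An `ehr_cohort` from [build_cohort()].
#' @return Object of class `feature_timelines`: list with `features`
#'   (patient_id, date, concept; one row per patient-concept at its earliest
#'   date) and `patients` (patient_id, label, index_date).
#' @export
extract_timelines <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  ev <- cohort$events
  pats <- cohort$patients
  if (nrow(ev)) {
    evc <- data.table(patient_id = ev$patient_id, date = as.Date(ev$date),
                      concept = event_concept_ids(ev))
    feats <- evc[, .(date = min(date)), by = .(patient_id, concept)]
    anchors <- evc[, .(anchor = min(date)), by = patient_id]
  } else {
    feats <- data.table(patient_id = character(), concept = character(),
                        date = as.Date(character()))
    anchors <- data.table(patient_id = character(),
                          anchor = as.Date(character()))
  }
  dem_pats <- merge(pats, anchors, by = "patient_id", all.x = TRUE)
  # cohort members always have >= 1 censored event; fall back to birth date
  # for completeness on degenerate inputs
  dem_pats[is.na(anchor), anchor := birth_date]
  dem <- demographic_concepts(dem_pats, dem_pats$anchor)
  out <- rbind(feats[, .(patient_id, date, concept)], dem)
  setorder(out, patient_id, date, concept)
  structure(list(features = out,
                 patients = pats[, .(patient_id, label, index_date)]),
            class = "feature_timelines")
}

#' Extract the timeline of a single patient
#'
#' Single-patient counterpart of [extract_timelines()]; input events must be
#' censored and sorted by date (unsorted input is a contract violation).
#'
#' @param events The patient's censored events (date, domain, code,
#'   value_flag), sorted ascending by date; may have zero rows.
#' @param sex,race_ethnicity,birth_date Demographic attributes; demographic
#'   concepts are dated at the first event (or `birth_date` when there are no
#'   events).
#' @return data.table (date, concept), unique by concept, dates ascending.
#' @export
extract_timeline <- function(events, sex, race_ethnicity, birth_date) {
  ev <- as.data.table(events)
  if (nrow(ev) && is.unsorted(as.Date(ev$date)))
    stop("extract_timeline: events must be sorted ascending by date")
  pid <- "patient"
  if (nrow(ev)) {
    evc <- data.table(patient_id = pid, date = as.Date(ev$date),
                      concept = event_concept_ids(ev))
    feats <- evc[, .(date = min(date)), by = .(patient_id, concept)]
    anchor <- min(evc$date)
  } else {
    feats <- data.table(patient_id = character(), concept = character(),
                        date = as.Date(character()))
    anchor <- as.Date(birth_date)
  }
  dem <- demographic_concepts(
    data.table(patient_id = pid, sex = sex, race_ethnicity = race_ethnicity,
               birth_date = as.Date(birth_date)), anchor)
  out <- rbind(feats[, .(patient_id, date, concept)], dem)
  setorder(out, date, concept)
  out[, .(date, concept)]
}

#' Concept universe with per-label patient counts
#'
#' Every concept observed in at least one timeline, with the number of case
#' and noncase patients carrying it.  All concepts are kept regardless of
#' frequency.
#'
#' @param timelines A `feature_timelines` object.
#' @return data.table (concept, n_case, n_noncase).
#' @export
concept_universe <- function(timelines) {
  stopifnot(inherits(timelines, "feature_timelines"))
  f <- merge(timelines$features, timelines$patients[, .(patient_id, label)],
             by = "patient_id")
  out <- f[, .(n_case = sum(label == "case"),
               n_noncase = sum(label == "noncase")), by = concept]
  setorder(out, concept)
  out[]
}

#' Restrict timelines to a set of patients
#'
#' @param timelines A `feature_timelines` object.
#' @param ids Patient ids to keep.
#' @return A `feature_timelines` object.
#' @export
subset_timelines <- function(timelines, ids) {
  stopifnot(inherits(timelines, "feature_timelines"))
  structure(list(features = timelines$features[patient_id %in% ids],
                 patients = timelines$patients[patient_id %in% ids]),
            class = "feature_timelines")
}
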