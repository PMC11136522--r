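# Case definition, inclusion criteria and pre-index censoring.
#
# Cases are patients whose diagnosis stream contains at least one ICD-9 code
# matching the validated wildcard families (E95*, 965*, 967*, 969*, 881*);
# the index date is the first such code and all case data on/after it are
# censored.  Inclusion asks for >= 3 visits (distinct event dates), >= 30
# days between first and last visit, and records after age 10 and before
# age 90.  Inclusion is evaluated on the full record; exclusion of cases with
# no pre-index data is a separate, later step with its own ledger entry.

DAYS_PER_YEAR <- 365.25

#' ICD-9 wildcard case definition
#'
#' @param code_patterns Character vector of exact codes or `"stem*"` wildcard
#'   prefixes; defaults to the validated suicide-attempt families.
#' @return Object of class `case_definition`.
#' @export
case_definition <- function(code_patterns = c("E95*", "965*", "967*",
                                              "969*", "881*")) {
  if (!length(code_patterns) || any(!nzchar(sub("\\*$", "", code_patterns))))
    stop("case_definition: each pattern must be a non-empty code or prefix")
  structure(list(code_patterns = code_patterns, domain = "DX"),
            class = "case_definition")
}

#' Cohort inclusion rules
#'
#' @param min_visits Minimum number of visits (distinct event dates).
#' @param min_span_days Minimum days between first and last visit.
#' @param min_age_years,max_age_years The record must contain at least one
#'   event after `min_age_years` and at least one before `max_age_years`.
#' @return Object of class `inclusion_rules`.
#' @export
inclusion_rules <- function(min_visits = 3L, min_span_days = 30L,
                            min_age_years = 10, max_age_years = 90) {
  if (min_visits < 1) stop("inclusion_rules: invariant violated: min_visits >= 1")
  if (min_span_days < 0) stop("inclusion_rules: invariant violated: min_span_days >= 0")
  if (!(min_age_years < max_age_years))
    stop("inclusion_rules: invariant violated: min_age < max_age")
  structure(list(min_visits = as.integer(min_visits),
                 min_span_days = as.integer(min_span_days),
                 min_age_years = min_age_years,
                 max_age_years = max_age_years),
            class = "inclusion_rules")
}

#' Match ICD-9 codes against a case definition
#'
#' A code matches a wildcard pattern `"stem*"` when it starts with the stem
#' (the bare stem itself matches), and a non-wildcard pattern only on exact
#' equality.
#'
#' @param code Character vector of ICD-9 codes.
#' @param definition A [case_definition()].
#' @return Logical vector.
#' @export
match_case_code <- function(code, definition = case_definition()) {
  if (!length(code) || any(is.na(code)) || any(!nzchar(code)))
    stop("match_case_code: codes must be non-empty")
  out <- logical(length(code))
  for (pat in definition$code_patterns) {
    if (endsWith(pat, "*")) {
      stem <- substr(pat, 1L, nchar(pat) - 1L)
      out <- out | startsWith(code, stem)
    } else {
      out <- out | (code == pat)
    }
  }
  out
}

#' Find a patient's index date
#'
#' Earliest date of any case-defining diagnosis event, or `NA` if none.
#'
#' @param events data.frame/data.table with columns `date`, `domain`, `code`.
#' @param definition A [case_definition()].
#' @return A `Date` (possibly `NA`).
#' @export
find_index_date <- function(events, definition = case_definition()) {
  ev <- as.data.table(events)
  if (!nrow(ev)) return(as.Date(NA))
  hit <- ev$domain == definition$domain & match_case_code_safe(ev$code, definition)
  if (!any(hit)) return(as.Date(NA))
  min(as.Date(ev$date)[hit])
}

# internal: like match_case_code but treats empty codes as non-matching
match_case_code_safe <- function(code, definition) {
  ok <- !is.na(code) & nzchar(code)
  out <- logical(length(code))
  if (any(ok)) out[ok] <- match_case_code(code[ok], definition)
  out
}

#' Apply inclusion rules to one patient record
#'
#' Visits are counted as distinct calendar dates with at least one event.
#' The rules are checked in order min_visits, min_span, age_window and the
#' first failure is reported.
#'
#' @param events The patient's full (uncensored) events.
#' @param birth_date The patient's birth date (required).
#' @param rules An [inclusion_rules()].
#' @return List with `keep` (logical) and `reason` (`NA` or one of
#'   `"min_visits"`, `"min_span"`, `"age_window"`).
#' @export
apply_inclusion <- function(events, birth_date, rules = inclusion_rules()) {
  if (is.null(birth_date) || is.na(birth_date))
    stop("apply_inclusion: birth_date is required")
  ev <- as.data.table(events)
  dts <- if (nrow(ev)) unique(as.Date(ev$date)) else as.Date(character())
  if (length(dts) < rules$min_visits)
    return(list(keep = FALSE, reason = "min_visits"))
  if (as.numeric(max(dts) - min(dts)) < rules$min_span_days)
    return(list(keep = FALSE, reason = "min_span"))
  age <- as.numeric(dts - as.Date(birth_date)) / DAYS_PER_YEAR
  if (!any(age > rules$min_age_years) || !any(age < rules$max_age_years))
    return(list(keep = FALSE, reason = "age_window"))
  list(keep = TRUE, reason = NA_character_)
}

#' Build a labeled, censored cohort from a raw extract
#'
#' Applies inclusion rules on full records, labels cases by the case
#' definition, censors case event streams strictly before the index date and
#' moves cases without any pre-index event into the exclusion ledger.
#'
#' @param patients Patient table (patient_id, birth_date, sex, race_ethnicity).
#' @param events Event table (patient_id, date, domain, code, value_flag).
#' @param definition A [case_definition()].
#' @param rules An [inclusion_rules()].
#' @return Object of class `ehr_cohort`: list with `patients` (patient_id,
#'   label, index_date, birth_date, sex, race_ethnicity), `events` (censored),
#'   and `exclusions` (per-reason counts plus totals).
#' @export
build_cohort <- function(patients, events, definition = case_definition(),
                         rules = inclusion_rules()) {
  pats <- as.data.table(patients)
  ev <- as.data.table(events)
  ev[, date := as.Date(date)]
  pats[, birth_date := as.Date(birth_date)]

  unknown <- setdiff(unique(ev$patient_id), pats$patient_id)
  if (length(unknown))
    stop("build_cohort: events reference unknown patient ids: ",
         paste(head(unknown, 5L), collapse = ", "),
         if (length(unknown) > 5L) sprintf(" (and %d more)", length(unknown) - 5L))
  if (anyNA(pats$birth_date))
    stop("build_cohort: missing birth_date for ",
         sum(is.na(pats$birth_date)), " patients")

  # inclusion on the full record
  evb <- merge(ev[, .(patient_id, date)],
               pats[, .(patient_id, birth_date)], by = "patient_id")
  per <- evb[, {
    dts <- unique(date)
    age <- as.numeric(dts - birth_date[1L]) / DAYS_PER_YEAR
    .(n_dates = length(dts),
      span = as.numeric(max(dts) - min(dts)),
      ok_young = any(age > rules$min_age_years),
      ok_old = any(age < rules$max_age_years))
  }, by = patient_id]
  per <- merge(pats[, .(patient_id)], per, by = "patient_id", all.x = TRUE)
  per[is.na(n_dates), `:=`(n_dates = 0L, span = 0, ok_young = FALSE, ok_old = FALSE)]
  per[, reason := fcase(
    n_dates < rules$min_visits, "min_visits",
    span < rules$min_span_days, "min_span",
    !(ok_young & ok_old), "age_window",
    default = NA_character_)]

  included_ids <- per[is.na(reason), patient_id]
  ev_inc <- ev[patient_id %in% included_ids]

  # index dates over full (uncensored) records of included patients
  hit <- ev_inc[domain == definition$domain &
                  match_case_code_safe(code, definition),
                .(index_date = min(date)), by = patient_id]

  cohort_pats <- merge(pats[patient_id %in% included_ids], hit,
                       by = "patient_id", all.x = TRUE)
  cohort_pats[, label := fifelse(is.na(index_date), "noncase", "case")]

  # censor cases strictly before the index date; noncases keep everything
  ev_c <- merge(ev_inc, cohort_pats[, .(patient_id, index_date)],
                by = "patient_id")
  ev_c <- ev_c[is.na(index_date) | date < index_date]
  ev_c[, index_date := NULL]

  # cases with no pre-index data are excluded, with their own ledger reason
  with_data <- unique(ev_c$patient_id)
  no_pre <- cohort_pats[label == "case" & !(patient_id %in% with_data),
                        patient_id]
  cohort_pats <- cohort_pats[!(patient_id %in% no_pre)]
  ev_c <- ev_c[patient_id %in% cohort_pats$patient_id]
  setorder(ev_c, patient_id, date, domain, code)
  setorder(cohort_pats, patient_id)

  reasons <- table(per$reason)
  exclusions <- list(
    n_input = nrow(pats),
    min_visits = as.integer(reasons["min_visits"] %val% 0L),
    min_span = as.integer(reasons["min_span"] %val% 0L),
    age_window = as.integer(reasons["age_window"] %val% 0L),
    no_pre_index_data = length(no_pre),
    n_passed_inclusion = length(included_ids),
    n_cases = cohort_pats[, sum(label == "case")],
    n_noncases = cohort_pats[, sum(label == "noncase")])

  structure(list(
    patients = cohort_pats[, .(patient_id, label, index_date, birth_date,
                               sex, race_ethnicity)],
    events = ev_c,
    exclusions = exclusions,
    definition = definition,
    rules = rules), class = "ehr_cohort")
}

# value-or-default for possibly-NA table lookups
`%val%` <- function(x, default) if (length(x) == 0L || is.na(x)) default else x

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf(
    "<ehr_cohort> %d patients (%d cases, %d noncases), %d censored events\n",
    nrow(x$patients), x$exclusions$n_cases, x$exclusions$n_noncases,
    nrow(x$events)))
  cat(sprintf(
    "  excluded: %d min_visits, %d min_span, %d age_window, %d no_pre_index_data\n",
    x$exclusions$min_visits, x$exclusions$min_span, x$exclusions$age_window,
    x$exclusions$no_pre_index_data))
  invisible(x)
}
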