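# Synthetic multi-site EHR generator.
#
# Emits i2b2-style flat extracts (a patient table and a timestamped coded
# event table) with a planted risk structure: each catalog concept carries a
# per-visit baseline emission probability among noncases and a log odds ratio
# that tilts, on the odds scale, a case patient's probability of ever carrying
# the concept before their index suicide-attempt code.  Complete histories are
# emitted (including post-index events for cases); censoring is deliberately
# left to the cohort builder so that censoring is testable downstream.

CASE_CODE_FAMILIES <- c("E95", "965", "967", "969", "881")

#' Define a planted concept effect
#'
#' A concept the generator can emit, with its per-visit emission probability
#' among noncases (`baseline_rate`) and a planted log odds ratio applied to a
#' case patient's odds of carrying the concept in the observable (pre-index)
#' part of their record.  Laboratory concepts additionally carry a
#' (normal, low, high) flag probability triple.
#'
#' @param domain One of `"DX"`, `"RX"`, `"PX"`, `"LAB"`.
#' @param code Concept code (ICD-9 style for DX, free string otherwise).
#' @param baseline_rate Per-visit emission probability among noncases, in (0,1).
#' @param log_or Planted log odds ratio (0 = no association with case status).
#' @param lab_flag_probs For LAB concepts, probabilities of the N/L/H value
#'   flags (must sum to 1); defaults to `c(N = .7, L = .15, H = .15)`.
#' @return An object of class `concept_effect`.
#' @export
concept_effect <- function(domain, code, baseline_rate, log_or = 0,
                           lab_flag_probs = NULL) {
  domain <- match.arg(domain, c("DX", "RX", "PX", "LAB"))
  if (!is.character(code) || length(code) != 1L || !nzchar(code))
    stop("concept_effect: 'code' must be a non-empty string")
  if (!is.numeric(baseline_rate) || baseline_rate <= 0 || baseline_rate >= 1)
    stop("concept_effect: invariant violated: baseline_rate must lie in (0, 1)")
  if (!is.numeric(log_or) || !is.finite(log_or))
    stop("concept_effect: 'log_or' must be a finite number")
  # case-side carriage probability plogis(qlogis(p) + log_or) is automatically
  # in (0,1) for finite log_or; finiteness is the invariant enforced above
  if (domain == "LAB") {
    if (is.null(lab_flag_probs)) lab_flag_probs <- c(N = 0.7, L = 0.15, H = 0.15)
    if (length(lab_flag_probs) != 3L || any(lab_flag_probs < 0) ||
        abs(sum(lab_flag_probs) - 1) > 1e-9)
      stop("concept_effect: invariant violated: lab_flag_probs must sum to 1")
    names(lab_flag_probs) <- c("N", "L", "H")
  } else if (!is.null(lab_flag_probs)) {
    stop("concept_effect: lab_flag_probs are only meaningful for LAB concepts")
  }
  structure(list(domain = domain, code = code, baseline_rate = baseline_rate,
                 log_or = log_or, lab_flag_probs = lab_flag_probs),
            class = "concept_effect")
}

#' Default planted concept catalog
#'
#' A compact catalog mixing (i) high-risk concepts patterned on the magnitudes
#' reported for suicidal ideation, substance-use and mood-disorder codes,
#' toxicology laboratory tests and psychotropic medications (odds ratios
#' roughly 2.5 to 11), and (ii) common routine-care concepts with null or
#' mildly protective effects that give patients realistic visit density.
#'
#' @return List of [concept_effect()] objects.
#' @export
default_concept_catalog <- function() {
  list(
    # adverse, rare-ish (per-visit baselines; ORs on the patient carriage scale)
    concept_effect("DX", "V6284", 0.0020, log(11)),    # suicidal ideation
    concept_effect("DX", "2920",  0.0015, log(10)),    # drug withdrawal
    concept_effect("DX", "30183", 0.0015, log(9.9)),   # borderline personality
    concept_effect("DX", "29650", 0.0020, log(6)),     # bipolar, depressed
    concept_effect("DX", "30590", 0.0030, log(8)),     # mixed drug abuse
    concept_effect("DX", "3030",  0.0020, log(9)),     # acute alcohol intox.
    concept_effect("DX", "311",   0.0100, log(4)),     # depressive disorder
    concept_effect("DX", "30000", 0.0120, log(3)),     # anxiety state
    concept_effect("RX", "lithium", 0.0020, log(5)),
    concept_effect("RX", "nicotine_replacement", 0.0040, log(2.5)),
    concept_effect("LAB", "acetaminophen", 0.0030, log(7),
                   lab_flag_probs = c(0.6, 0.1, 0.3)),
    concept_effect("LAB", "salicylate", 0.0020, log(7),
                   lab_flag_probs = c(0.7, 0.1, 0.2)),
    # common, null-to-protective (visit-density backbone)
    concept_effect("DX", "4011", 0.08, log(0.8)),      # hypertension
    concept_effect("DX", "V700", 0.15, log(0.9)),      # routine exam
    concept_effect("DX", "4659", 0.10, 0),             # acute URI
    concept_effect("PX", "99213", 0.45, 0),            # office visit
    concept_effect("PX", "90658", 0.05, log(0.85)),    # influenza vaccine
    concept_effect("RX", "amoxicillin", 0.05, 0),
    concept_effect("RX", "lisinopril", 0.05, log(0.8)),
    concept_effect("LAB", "cbc", 0.20, log(1.1),
                   lab_flag_probs = c(0.8, 0.1, 0.1)),
    concept_effect("LAB", "glucose", 0.15, log(1.2),
                   lab_flag_probs = c(0.75, 0.10, 0.15))
  )
}

#' Default demographic category mixes
#' @return Named list with `sex` and `race_ethnicity` probability vectors.
#' @export
default_demographics_mix <- function() {
  list(
    sex = c(F = 0.57, M = 0.43),
    race_ethnicity = c(White = 0.60, African_American = 0.15,
                       Hispanic_or_Latino = 0.08, Asian = 0.03,
                       Other_or_unknown = 0.14)
  )
}

#' Specify one synthetic site
#'
#' @param site_id Short site identifier.
#' @param n_patients Number of patients to generate (>= 1).
#' @param case_fraction Fraction of patients carrying a case-defining
#'   suicide-attempt code, in (0,1).
#' @param years_of_data Calendar span of generated events in years.
#' @param visit_rate Mean visits per patient-year (homogeneous Poisson over
#'   the site span).
#' @param concept_catalog List of [concept_effect()] objects.
#' @param demographics_mix Named list with `sex` and `race_ethnicity`
#'   probability vectors, each summing to 1.
#' @param seed Integer seed; generation is a pure function of the spec
#'   including this seed.
#' @param no_history_frac Fraction of cases whose index date coincides with
#'   their first visit, so they have no pre-index record (these exercise the
#'   cohort builder's exclusion rule).
#' @param age_tail_frac Fraction of patients whose age at first contact falls
#'   outside the 10-90 year window (exercises the age inclusion rule).
#' @param end_date Last calendar day of the site span.
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(site_id, n_patients, case_fraction, years_of_data,
                      visit_rate, concept_catalog = default_concept_catalog(),
                      demographics_mix = default_demographics_mix(),
                      seed = 1L, no_history_frac = 0.2, age_tail_frac = 0.02,
                      end_date = as.Date("2015-12-31")) {
  spec <- structure(
    list(site_id = site_id, n_patients = n_patients,
         case_fraction = case_fraction, years_of_data = years_of_data,
         visit_rate = visit_rate, concept_catalog = concept_catalog,
         demographics_mix = demographics_mix, seed = as.integer(seed),
         no_history_frac = no_history_frac, age_tail_frac = age_tail_frac,
         end_date = as.Date(end_date)),
    class = "site_spec")
  validate_site_spec(spec)
}

#' @rdname site_spec
#' @param spec A `site_spec` to validate.
#' @export
validate_site_spec <- function(spec) {
  if (!inherits(spec, "site_spec")) stop("validate_site_spec: not a site_spec")
  with(spec, {
    if (!is.character(site_id) || !nzchar(site_id))
      stop("site_spec: invariant violated: site_id must be a non-empty string")
    if (!is.numeric(n_patients) || n_patients < 1)
      stop("site_spec: invariant violated: n_patients >= 1")
    if (!is.numeric(case_fraction) || case_fraction <= 0 || case_fraction >= 1)
      stop("site_spec: invariant violated: case_fraction in (0, 1)")
    if (!is.numeric(years_of_data) || years_of_data <= 0)
      stop("site_spec: invariant violated: years_of_data > 0")
    if (!is.numeric(visit_rate) || visit_rate <= 0)
      stop("site_spec: invariant violated: visit_rate > 0")
    for (nm in c("sex", "race_ethnicity")) {
      pr <- demographics_mix[[nm]]
      if (is.null(pr) || is.null(names(pr)) || any(pr < 0) ||
          abs(sum(pr) - 1) > 1e-9)
        stop(sprintf(
          "site_spec: invariant violated: demographics_mix$%s must be a named vector summing to 1",
          nm))
    }
    if (!length(concept_catalog) ||
        !all(vapply(concept_catalog, inherits, TRUE, "concept_effect")))
      stop("site_spec: concept_catalog must be a non-empty list of concept_effect")
    if (no_history_frac < 0 || no_history_frac >= 1)
      stop("site_spec: invariant violated: no_history_frac in [0, 1)")
    if (age_tail_frac < 0 || age_tail_frac >= 1)
      stop("site_spec: invariant violated: age_tail_frac in [0, 1)")
  })
  spec
}

# draw ICD-9 style case-defining codes (two trailing digits on a family stem)
sample_case_codes <- function(n) {
  fam <- sample(CASE_CODE_FAMILIES, n, replace = TRUE,
                prob = c(0.45, 0.25, 0.10, 0.10, 0.10))
  paste0(fam, sample(0:9, n, TRUE), sample(0:9, n, TRUE))
}

#' Generate one synthetic site extract
#'
#' Visit dates follow a homogeneous Poisson process over the site calendar
#' span.  Whether a patient carries a concept is a Bernoulli draw with
#' probability `plogis(qlogis(1-(1-b)^v) + log_or * case)` where `b` is the
#' concept's per-visit baseline rate and `v` the patient's total visit count;
#' the first occurrence is placed at a truncated-geometric position among the
#' observable visits (whole record for noncases, strictly pre-index for
#' cases) and later observable visits re-emit with probability `b`.  For
#' noncases, and for everyone when `log_or = 0`, this reproduces independent
#' per-visit Bernoulli emission; because carriage odds are computed from the
#' same total-visit exposure in both classes, the patient-level
#' first-occurrence odds ratio the downstream trainer estimates (censored
#' case record vs full noncase record) equals `exp(log_or)` by construction,
#' up to the noncollapsibility of marginalising over visit counts.  Cases
#' whose index date precedes any visit express no carriage (they have no
#' observable record).  Cases receive a case-defining
#' ICD-9 code at an index date drawn uniformly in the last 60% of their visit
#' span (or at their first visit for the configured no-history fraction), and
#' their post-index visits keep emitting at baseline so the extract contains
#' complete histories.
#'
#' @param spec A [site_spec()].
#' @return List of class `ehr_site` with elements `patients` (patient_id,
#'   birth_date, sex, race_ethnicity), `events` (patient_id, date, domain,
#'   code, value_flag), and `truth` (per-patient generated case status and
#'   index date, for simulation studies only -- the pipeline never reads it).
#' @export
generate_site <- function(spec) {
  spec <- validate_site_spec(spec)
  set.seed(spec$seed)
  n <- as.integer(spec$n_patients)
  span_days <- max(1L, as.integer(round(spec$years_of_data * 365.25)))
  start_date <- spec$end_date - span_days
  patient_id <- sprintf("%s-%06d", spec$site_id, seq_len(n))

  sex <- sample(names(spec$demographics_mix$sex), n, TRUE,
                prob = spec$demographics_mix$sex)
  race <- sample(names(spec$demographics_mix$race_ethnicity), n, TRUE,
                 prob = spec$demographics_mix$race_ethnicity)
  is_case <- runif(n) < spec$case_fraction

  n_visits <- rpois(n, spec$visit_rate * spec$years_of_data)
  n_visits[is_case & n_visits == 0L] <- 1L  # a case needs a date to attach to

  visits <- data.table(p = rep.int(seq_len(n), n_visits))
  visits[, date := start_date + (sample.int(span_days + 1L, .N, replace = TRUE) - 1L)]
  setorder(visits, p, date)
  vrange <- visits[, .(first_visit = date[1L], last_visit = date[.N]), by = p]

  pat <- data.table(p = seq_len(n), patient_id = patient_id, sex = sex,
                    race_ethnicity = race, is_case = is_case,
                    n_visits = n_visits)
  pat <- merge(pat, vrange, by = "p", all.x = TRUE)
  setorder(pat, p)

  # ages at first contact: bulk inside the 10-90 window, configurable tail out
  anchor <- fifelse(is.na(pat$first_visit), start_date, pat$first_visit)
  age <- runif(n, 12, 85)
  in_tail <- runif(n) < spec$age_tail_frac
  tail_young <- in_tail & runif(n) < 0.5
  tail_old <- in_tail & !tail_young
  age[tail_young] <- runif(sum(tail_young), 1, 9.5)
  age[tail_old] <- runif(sum(tail_old), 90.5, 99)
  pat[, birth_date := anchor - as.integer(round(age * 365.25))]

  # case index dates: uniform over the last 60% of the patient's visit span;
  # the no-history fraction indexes at the first visit (no pre-index record)
  no_hist_draw <- runif(n) < spec$no_history_frac
  pat[, index_date := as.Date(NA)]
  ci <- which(pat$is_case)
  if (length(ci)) {
    fs <- as.integer(pat$first_visit[ci])
    ls <- as.integer(pat$last_visit[ci])
    lo <- fs + as.integer(ceiling(0.4 * (ls - fs)))
    idx <- lo + as.integer(floor(runif(length(ci)) * (ls - lo + 1L)))
    idx[no_hist_draw[ci]] <- fs[no_hist_draw[ci]]
    pat$index_date[ci] <- as.Date(idx, origin = "1970-01-01")
  }

  # observable visits: full record for noncases, strictly pre-index for cases
  visits <- merge(visits, pat[, .(p, is_case, index_date)], by = "p")
  setorder(visits, p, date)
  visits[, observable := !is_case | (date < index_date)]
  obs <- visits[observable == TRUE, .(p, date)]
  obs[, ord := seq_len(.N), by = p]
  v_eff <- integer(n)
  nv_obs <- obs[, .N, by = p]
  v_eff[nv_obs$p] <- nv_obs$N
  post <- visits[is_case & observable == FALSE, .(p, date)]

  ev_parts <- vector("list", length(spec$concept_catalog) + 1L)
  for (j in seq_along(spec$concept_catalog)) {
    cc <- spec$concept_catalog[[j]]
    bb <- cc$baseline_rate
    pbase <- -expm1(pat$n_visits * log1p(-bb))   # 1 - (1-b)^v_total
    pcarry <- plogis(qlogis(pbase) + cc$log_or * pat$is_case)
    pcarry[pbase == 0] <- 0
    carry <- which(runif(n) < pcarry & v_eff > 0L)
    dates <- NULL
    pids <- NULL
    if (length(carry)) {
      v <- v_eff[carry]
      u <- runif(length(carry))
      # truncated geometric: first success among v Bernoulli(b) trials
      f <- as.integer(ceiling(log1p(u * expm1(v * log1p(-bb))) / log1p(-bb)))
      f <- pmin(pmax(f, 1L), v)
      first_hit <- obs[data.table(p = carry, ord = f), on = c("p", "ord")]
      # re-emissions at later observable visits, per-visit Bernoulli(b)
      m <- v - f
      has_m <- which(m > 0L)
      rep_hit <- NULL
      if (length(has_m)) {
        grid <- data.table(
          p = rep.int(carry[has_m], m[has_m]),
          ord = as.integer(rep.int(f[has_m], m[has_m]) + sequence(m[has_m])))
        grid <- grid[runif(nrow(grid)) < bb]
        if (nrow(grid)) rep_hit <- obs[grid, on = c("p", "ord")]
      }
      pids <- c(first_hit$p, if (!is.null(rep_hit)) rep_hit$p)
      dates <- c(first_hit$date, if (!is.null(rep_hit)) rep_hit$date)
    }
    # post-index emissions for cases: plain per-visit Bernoulli(b)
    if (nrow(post)) {
      hit <- post[runif(nrow(post)) < bb]
      if (nrow(hit)) {
        pids <- c(pids, hit$p)
        dates <- c(dates, hit$date)
      }
    }
    if (length(pids)) {
      part <- data.table(p = pids, date = as.Date(dates, origin = "1970-01-01"),
                         domain = cc$domain, code = cc$code)
      part[, value_flag := if (cc$domain == "LAB")
        sample(c("N", "L", "H"), .N, TRUE, prob = cc$lab_flag_probs) else ""]
      ev_parts[[j]] <- part
    }
  }

  # case-defining diagnosis at the index date
  if (length(ci)) {
    ev_parts[[length(ev_parts)]] <- data.table(
      p = ci, date = pat$index_date[ci], domain = "DX",
      code = sample_case_codes(length(ci)), value_flag = "")
  }

  events <- rbindlist(ev_parts[!vapply(ev_parts, is.null, TRUE)])
  if (!nrow(events))
    events <- data.table(p = integer(), date = as.Date(character()),
                         domain = character(), code = character(),
                         value_flag = character())
  events[, patient_id := patient_id[p]]
  setorder(events, p, date, domain, code, value_flag)
  events <- events[, .(patient_id, date, domain, code, value_flag)]

  patients <- pat[, .(patient_id, birth_date, sex, race_ethnicity)]
  truth <- pat[, .(patient_id, is_case, index_date, n_visits)]
  structure(list(patients = patients, events = events, truth = truth,
                 site_id = spec$site_id),
            class = "ehr_site")
}

#' Generate a multi-site network of extracts
#'
#' Writes one patient/event CSV pair per site plus a JSON manifest listing
#' sites and seeds.
#'
#' @param specs List of [site_spec()] objects with unique `site_id`s.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
generate_network <- function(specs, dir) {
  if (!length(specs)) stop("generate_network: at least one site spec required")
  ids <- vapply(specs, function(s) s$site_id, character(1))
  if (anyDuplicated(ids))
    stop("generate_network: duplicate site_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    site <- generate_site(s)
    pf <- paste0(s$site_id, "_patients.csv")
    ef <- paste0(s$site_id, "_events.csv")
    fwrite(site$patients, file.path(dir, pf))
    fwrite(site$events, file.path(dir, ef))
    entries[[i]] <- list(site_id = s$site_id, n_patients = s$n_patients,
                         case_fraction = s$case_fraction, seed = s$seed,
                         years_of_data = s$years_of_data,
                         patient_file = pf, event_file = ef)
  }
  manifest <- list(format = "ehrnbc-extract-v1", sites = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a site extract written by [generate_network()]
#'
#' @param dir Directory holding the extract pair.
#' @param site_id Site identifier.
#' @return List with `patients` and `events` data.tables (dates parsed).
#' @export
read_site_extract <- function(dir, site_id) {
  pf <- file.path(dir, paste0(site_id, "_patients.csv"))
  ef <- file.path(dir, paste0(site_id, "_events.csv"))
  if (!file.exists(pf) || !file.exists(ef))
    stop("read_site_extract: no extract for site '", site_id, "' in ", dir)
  patients <- fread(pf, colClasses = list(character = "patient_id"))
  patients[, birth_date := as.Date(birth_date)]
  events <- fread(ef, colClasses = list(character = c("patient_id", "code",
                                                      "value_flag")),
                  na.strings = NULL)
  events[, date := as.Date(date)]
  events[is.na(value_flag), value_flag := ""]
  list(patients = patients[], events = events[])
}

#' Site specifications patterned on a five-system reference network
#'
#' Five heterogeneous sites whose relative sizes, pre-exclusion case
#' prevalences (1.30/2.00/1.70/0.89/0.40%), data spans (17/17/10/13/8 years),
#' no-pre-index-history fractions and demographic mixes follow the published
#' description of five US health systems; `scale` shrinks the patient counts
#' to desk size while preserving the ratios.
#'
#' @param scale Multiplier on the reference patient counts (default 0.01,
#'   about 37,000 patients in total).
#' @param seed Base seed; site i uses `seed * 100 + i`.
#' @param concept_catalog Shared planted-concept catalog.
#' @return Named list of [site_spec()] objects.
#' @export
reference_network_specs <- function(scale = 0.01, seed = 1L,
                                    concept_catalog = default_concept_catalog()) {
  ids <- c("siteA", "siteB", "siteC", "siteD", "siteE")
  n_ref <- c(1931672, 477447, 528110, 501486, 286078)
  case_prev <- c(0.0130, 0.0200, 0.0170, 0.0089, 0.0040)
  years <- c(17, 17, 10, 13, 8)
  no_hist <- c(0.205, 0.160, 0.228, 0.377, 0.152)
  visit_rate <- c(2.0, 2.0, 2.2, 1.8, 2.4)
  sex_f <- c(0.581, 0.535, 0.565, 0.597, 0.543)
  race <- list(
    c(African_American = 6.4, Asian = 3.7, White = 72.7,
      Hispanic_or_Latino = 6.9, Other_or_unknown = 10.3),
    c(African_American = 30.8, American_Indian = 0.4, Asian = 4.4,
      White = 36.4, Hispanic_or_Latino = 9.8, Other_or_unknown = 18.2),
    c(African_American = 17.5, American_Indian = 0.3, Asian = 1.0,
      White = 74.7, Hispanic_or_Latino = 0.1, Other_or_unknown = 6.5),
    c(African_American = 19.9, American_Indian = 0.3, White = 42.4,
      Hispanic_or_Latino = 8.1, Other_or_unknown = 29.2),
    c(African_American = 7.6, American_Indian = 0.2, Asian = 2.6,
      White = 57.7, Hispanic_or_Latino = 10.6, Other_or_unknown = 32.0))
  out <- vector("list", 5L)
  for (i in 1:5) {
    mix <- list(sex = c(F = sex_f[i], M = 1 - sex_f[i]),
                race_ethnicity = race[[i]] / sum(race[[i]]))
    out[[i]] <- site_spec(
      site_id = ids[i], n_patients = max(50L, as.integer(round(n_ref[i] * scale))),
      case_fraction = case_prev[i], years_of_data = years[i],
      visit_rate = visit_rate[i], concept_catalog = concept_catalog,
      demographics_mix = mix, seed = as.integer(seed * 100 + i),
      no_history_frac = no_hist[i])
  }
  names(out) <- ids
  out
}
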