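# Shared fixtures, built in code at test time.

library(data.table)

# a lean catalog: visit-density backbone + planted effects, cheap to simulate
lean_catalog <- function(extra = list()) {
  c(list(
    concept_effect("PX", "99213", 0.45, 0),
    concept_effect("LAB", "cbc", 0.25, 0, lab_flag_probs = c(0.8, 0.1, 0.1)),
    concept_effect("DX", "4659", 0.12, 0),
    concept_effect("RX", "amoxicillin", 0.06, 0)
  ), extra)
}

# hand-built toy extract: three patients, known structure
toy_extract <- function() {
  patients <- data.table(
    patient_id = c("p1", "p2", "p3"),
    birth_date = as.Date(c("1980-01-01", "1990-06-15", "1975-03-10")),
    sex = c("F", "M", "F"),
    race_ethnicity = c("White", "Asian", "White"))
  events <- data.table(rbind(
    # p1: case with pre-index history; index = 2010-06-01
    list("p1", "2010-01-10", "DX", "4659", ""),
    list("p1", "2010-02-20", "RX", "amoxicillin", ""),
    list("p1", "2010-03-15", "LAB", "cbc", "H"),
    list("p1", "2010-06-01", "DX", "E9503", ""),
    list("p1", "2010-07-01", "DX", "30183", ""),     # post-index, must censor
    # p2: noncase, three spaced visits
    list("p2", "2011-01-01", "DX", "4011", ""),
    list("p2", "2011-03-01", "PX", "99213", ""),
    list("p2", "2011-06-01", "LAB", "cbc", ""),
    # p3: case whose index code is their earliest event -> no pre-index data
    list("p3", "2012-01-01", "DX", "96500", ""),
    list("p3", "2012-02-15", "PX", "99213", ""),
    list("p3", "2012-03-20", "DX", "311", "")))
  setnames(events, c("patient_id", "date", "domain", "code", "value_flag"))
  events[, patient_id := as.character(patient_id)]
  events[, date := as.Date(unlist(date))]
  events[, domain := as.character(domain)]
  events[, code := as.character(code)]
  events[, value_flag := as.character(value_flag)]
  list(patients = patients, events = events)
}

# run the full pipeline on a freshly generated site, returning everything
run_generated_site <- function(spec, seed_split = 11L, config = NULL) {
  site <- generate_site(spec)
  if (is.null(config)) config <- pipeline_config(seed = seed_split)
  list(site = site,
       result = run_site(site$patients, site$events, config, spec$site_id))
}
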