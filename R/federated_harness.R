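# Federated multi-site orchestration.
#
# Each site runs the full local pipeline (cohort -> features -> split ->
# train -> score -> evaluate) independently; with privacy mode on (the
# default) only aggregate summaries -- per-concept statistics and site
# evaluation metrics -- leave the site.  Aggregation computes unweighted
# cross-site means and min-max ranges and pools per-concept carrier counts.

#' Pipeline configuration
#'
#' @param k Smoothing pseudocount for partial scores.
#' @param split_fraction Training fraction for the patient-level split.
#' @param specificity_levels Specificity levels for alert thresholds.
#' @param seed Seed for the train/validation split.
#' @param privacy_mode When `TRUE` (default) site results contain only
#'   aggregate summaries, never patient-level rows.
#' @param case_definition A [case_definition()].
#' @param inclusion_rules An [inclusion_rules()].
#' @param min_patients,min_case_patients Reporting filter for the concept
#'   table (see [concept_report()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 1, split_fraction = 0.5,
                            specificity_levels = c(0.90, 0.99), seed = 1L,
                            privacy_mode = TRUE,
                            case_definition = ehrnbc::case_definition(),
                            inclusion_rules = ehrnbc::inclusion_rules(),
                            min_patients = 100L, min_case_patients = 10L) {
  structure(list(k = k, split_fraction = split_fraction,
                 specificity_levels = specificity_levels,
                 seed = as.integer(seed), privacy_mode = privacy_mode,
                 case_definition = case_definition,
                 inclusion_rules = inclusion_rules,
                 min_patients = min_patients,
                 min_case_patients = min_case_patients),
            class = "pipeline_config")
}

#' Run the full pipeline at one site
#'
#' @param patients,events The site's flat extract tables.
#' @param config A [pipeline_config()].
#' @param site_id Site label.
#' @return Object of class `site_result`: list with `site_id`, `evaluation`
#'   (a `site_evaluation`), `model` (a `site_nbc`), `concept_stats` (filtered
#'   reporting table), `exclusions`, and cohort/split counts.  When
#'   `privacy_mode` is off, patient-level `cohort` and `trajectories` are
#'   attached as well.
#' @export
run_site <- function(patients, events, config = pipeline_config(),
                     site_id = "site") {
  res <- try({
    cohort <- build_cohort(patients, events, config$case_definition,
                           config$inclusion_rules)
    timelines <- extract_timelines(cohort)
    split <- split_cohort(timelines, fraction = config$split_fraction,
                          seed = config$seed)
    tl_train <- subset_timelines(timelines, split$train)
    tl_val <- subset_timelines(timelines, split$validation)
    model <- train_site_model(tl_train, k = config$k, site_id = site_id)
    traj_train <- score_trajectories(tl_train, model)
    traj_val <- score_trajectories(tl_val, model)
    evaluation <- evaluate_site(traj_train, traj_val,
                                levels = config$specificity_levels,
                                site_id = site_id)
    out <- list(site_id = site_id, evaluation = evaluation, model = model,
                concept_stats = concept_report(model$stats,
                                               config$min_patients,
                                               config$min_case_patients),
                exclusions = cohort$exclusions,
                n_train = length(split$train),
                n_validation = length(split$validation))
    if (!config$privacy_mode) {
      out$cohort <- cohort
      out$trajectories <- list(train = traj_train, validation = traj_val)
    }
    structure(out, class = "site_result")
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("run_site[", site_id, "]: ", attr(res, "condition")$message)
  res
}

#' Run every site of a generated network
#'
#' @param dir Directory holding extracts and `manifest.json` (from
#'   [generate_network()]).
#' @param config A [pipeline_config()].
#' @return Named list of `site_result` objects.
#' @export
run_network <- function(dir, config = pipeline_config()) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  results <- list()
  for (entry in manifest$sites) {
    message(sprintf("run_network: site %s", entry$site_id))
    ex <- read_site_extract(dir, entry$site_id)
    results[[entry$site_id]] <- run_site(ex$patients, ex$events, config,
                                         site_id = entry$site_id)
  }
  results
}

#' Unweighted cross-site summary of one metric
#'
#' @param values Per-site metric values (`NA`s are dropped).
#' @return List (mean, min, max, n_sites).
#' @export
site_metric_summary <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) return(list(mean = NA_real_, min = NA_real_,
                              max = NA_real_, n_sites = 0L))
  list(mean = mean(v), min = min(v), max = max(v), n_sites = length(v))
}

#' Case share among pooled concept carriers
#'
#' Percentage of the patients carrying a concept (summed over sites) who are
#' cases, rounded to one decimal for reporting.
#'
#' @param cases,noncases Pooled carrier counts (vectorised).
#' @return Numeric percentage(s).
#' @export
concept_case_share <- function(cases, noncases) {
  if (any(cases < 0) || any(noncases < 0))
    stop("concept_case_share: counts must be nonnegative")
  if (any(cases + noncases == 0))
    stop("concept_case_share: no carriers")
  round(100 * cases / (cases + noncases), 1)
}

#' Aggregate per-site results into a network summary
#'
#' Unweighted arithmetic means and min-max ranges across sites for AUC and
#' the per-level metrics, plus a cross-site concept table joining per-site
#' ORs with pooled carrier counts and the pooled case share.  Aggregation is
#' permutation-invariant in the site order.
#'
#' @param site_results List of `site_result` (or `site_evaluation`) objects.
#' @return Object of class `network_summary`: list with `sites`, `auc`,
#'   `metrics` (per-level cross-site mean/range of sensitivity, ppv, npv and
#'   mean lead time), `site_metrics` (per-site rows) and `concepts`.
#' @export
aggregate_network <- function(site_results) {
  if (!length(site_results)) stop("aggregate_network: no site results")
  evs <- lapply(site_results, function(r)
    if (inherits(r, "site_result")) r$evaluation else r)
  ids <- vapply(evs, `[[`, character(1), "site_id")

  site_metrics <- rbindlist(lapply(evs, function(e)
    cbind(data.table(site_id = e$site_id, auc = e$auc, auc_se = e$auc_se,
                     n_validation_cases = e$n_validation_cases,
                     n_validation_noncases = e$n_validation_noncases),
          e$metrics)))

  agg <- site_metrics[, {
    s <- site_metric_summary(sensitivity)
    p <- site_metric_summary(ppv)
    np <- site_metric_summary(npv)
    lt <- site_metric_summary(mean_lead_time_years)
    .(mean_sensitivity = s$mean, min_sensitivity = s$min,
      max_sensitivity = s$max,
      mean_ppv = p$mean, min_ppv = p$min, max_ppv = p$max,
      mean_npv = np$mean, min_npv = np$min, max_npv = np$max,
      mean_lead_time_years = lt$mean, min_lead_time_years = lt$min,
      max_lead_time_years = lt$max, n_sites = .N)
  }, by = level]

  concepts <- NULL
  stats_list <- lapply(site_results, function(r)
    if (inherits(r, "site_result"))
      cbind(site_id = r$site_id, r$model$stats) else NULL)
  stats_list <- stats_list[!vapply(stats_list, is.null, TRUE)]
  if (length(stats_list)) {
    all_stats <- rbindlist(stats_list)
    pooled <- all_stats[, .(pooled_cases = sum(a), pooled_noncases = sum(c)),
                        by = concept]
    pooled[, case_pct := concept_case_share(pooled_cases, pooled_noncases)]
    ors <- dcast(all_stats, concept ~ site_id, value.var = "or")
    setnames(ors, setdiff(names(ors), "concept"),
             paste0("or_", setdiff(names(ors), "concept")))
    concepts <- merge(pooled, ors, by = "concept")
    setorder(concepts, -case_pct, concept)
  }

  structure(list(
    sites = ids,
    auc = site_metric_summary(vapply(evs, `[[`, numeric(1), "auc")),
    metrics = agg,
    site_metrics = site_metrics,
    concepts = concepts), class = "network_summary")
}

#' Write a network summary to disk
#'
#' Emits `network_summary.json` (aggregates only), a per-site metrics CSV in
#' the shape of a specificity-by-site performance table, and the cross-site
#' concept CSV (per-site ORs plus pooled counts and case share).
#'
#' @param summary A `network_summary`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_network_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "network_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- file.path(dir, "network_summary.json")
  jsonlite::write_json(list(sites = summary$sites, auc = summary$auc,
                            metrics = summary$metrics),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  mcsv <- file.path(dir, "site_metrics.csv")
  fwrite(summary$site_metrics, mcsv)
  paths <- c(js, mcsv)
  if (!is.null(summary$concepts)) {
    ccsv <- file.path(dir, "concept_table.csv")
    fwrite(summary$concepts, ccsv)
    paths <- c(paths, ccsv)
  }
  invisible(paths)
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary> %d sites: %s\n", length(x$sites),
              paste(x$sites, collapse = ", ")))
  cat(sprintf("  AUC mean %.3f (range %.3f-%.3f)\n",
              x$auc$mean, x$auc$min, x$auc$max))
  print(x$metrics[, .(level, mean_sensitivity = round(mean_sensitivity, 3),
                      mean_ppv = round(mean_ppv, 3),
                      mean_npv = round(mean_npv, 3),
                      mean_lead_time_years = round(mean_lead_time_years, 2))])
  invisible(x)
}
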