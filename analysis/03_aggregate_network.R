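#!/usr/bin/env Rscript
# Step 3: federated aggregation.
#
# Pools the per-site summaries into the cross-site network report:
# unweighted means and ranges of AUC, sensitivity, PPV, NPV and prediction
# lead time per specificity level, and the cross-site concept table (per-site
# ORs joined with pooled carrier counts and case share).  Writes
# results/network/{network_summary.json, site_metrics.csv, concept_table.csv}.

suppressPackageStartupMessages({
  library(ehrnbc)
  library(data.table)
})

rds <- "results/site_results.rds"
results <- if (file.exists(rds)) readRDS(rds) else
  run_network("results/extracts", pipeline_config(seed = 8L))
ns <- aggregate_network(results)
print(ns)

message(sprintf("AUC across sites: mean %.3f, range %.3f-%.3f",
                ns$auc$mean, ns$auc$min, ns$auc$max))
m90 <- ns$metrics[level == 0.90]
message(sprintf(
  "at 90%% specificity: mean sensitivity %.0f%%, mean lead time %.1f y",
  100 * m90$mean_sensitivity, m90$mean_lead_time_years))

top <- ns$concepts[pooled_cases >= 10][1:10]
message("top pooled concepts by case share:")
print(top[, .(concept, pooled_cases, pooled_noncases, case_pct)])

paths <- write_network_summary(ns, "results/network")
message("wrote: ", paste(paths, collapse = ", "))
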