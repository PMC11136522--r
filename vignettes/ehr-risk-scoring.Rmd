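---
title: "Cumulative naive Bayes risk scoring for suicide-attempt prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative naive Bayes risk scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`ehrnbc` implements a risk prediction workflow for incident suicide attempts
from routinely collected, structured electronic-health-record (EHR) data:
ICD-9 diagnoses, medications, procedures, laboratory results (as
normal/low/high flags) and demographics. The design premise is federated
validation: several health systems each hold their own extract, retrain the
model locally, and share only aggregate summaries — per-concept odds ratios
and performance metrics — with a coordinating center.

The classifier is a naive Bayes scorer over binary first-occurrence
features. For concept $j$, with $a_j$ training cases carrying it out of
$n_1$ and $c_j$ noncases out of $n_0$, the partial risk score is the
smoothed log prevalence ratio

$$ s_j \;=\; \log\frac{(a_j + k)/(n_1 + 2k)}{(c_j + k)/(n_0 + 2k)}, $$

with pseudocount $k$ (default 1). Positive scores are adverse, negative
protective. A patient's cumulative risk trajectory is the running sum of
the $s_j$ of their features in chronological order of first occurrence;
the trajectory's maximum is the patient's summary score. Alert thresholds
are specificity quantiles of the *training* noncases' maximal scores, and a
patient alerts when their cumulative score strictly exceeds the threshold.
For cases, the lead time is the interval from the first crossing to the
index date (the first case-defining code), in years of 365.25 days.

Three modelling conventions deserve emphasis:

* **Recorded features only.** Scoring sums the partial scores of features a
  patient actually has; the absence-likelihood term of a full naive Bayes is
  deliberately omitted. This keeps the trajectory interpretable as an
  accumulating record and matches the cumulative-sum formulation.
* **First occurrence only.** Each concept contributes once, at its earliest
  date, as a binary variable. Repeat codes neither add nor decay.
* **Strict thresholds.** "Surpassing" a threshold is a strict inequality,
  consistent with the inclusive (type-1) quantile used to derive it: the
  realized specificity on the defining set is always at least the nominal
  level.

## Cohorts

Cases are patients with at least one diagnosis matching the wildcard
families `E95*`, `965*`, `967*`, `969*`, `881*` (a case definition with
chart-review PPV > 0.70, taken as given here); the index date is the first
such code, and case records are censored strictly before it — events on the
index date itself are discarded. Inclusion requires at least 3 visits, at
least 30 days between first and last visit, and records after age 10 and
before age 90. Since flat extracts carry no encounter table, a *visit* is
operationalised as a distinct calendar date with at least one event. The
age rule is read as: at least one event strictly after age 10 *and* at
least one strictly before age 90. Inclusion is evaluated on the full
record; the exclusion of cases with no pre-index data is a separate,
subsequent step with its own ledger entry, so cohort totals are exactly
conserved (`included cases + noncases + no-pre-index exclusions = patients
passing inclusion`).

Demographics enter as DEM concepts (sex, race/ethnicity, age decade at
first contact) dated at the patient's first post-censoring event. Placing
them at "time zero" gives them a defined slot in the chronological sum;
where the demographic encoding is not dictated by the data model (age in
particular), decade bins at first contact are used because the
binary-feature framework needs categorical age.

## The synthetic network generator

No real extracts can be shipped, so the `synthetic_ehr` module generates
them. Per site: visit dates follow a homogeneous Poisson process over the
site's calendar span (`visit_rate` visits/patient-year); each catalog
concept has a per-visit baseline emission probability $b$ among noncases
and a planted log odds ratio $\lambda$. Concept carriage is decided at the
patient level with probability
$\mathrm{logit}^{-1}\!\big(\mathrm{logit}(1-(1-b)^{v}) + \lambda\,
\mathbb{1}[\text{case}]\big)$ where $v$ is the patient's **total** visit
count; the first occurrence lands at a truncated-geometric position among
the *observable* visits (the whole record for noncases, the pre-index
visits for cases), and later observable visits re-emit with probability
$b$. This construction has two properties that matter for validation:

* With $\lambda = 0$ it reduces exactly to independent per-visit Bernoulli
  emission, identical across classes, so a zero-signal network is a true
  null (pipeline AUC converges to 0.5).
* Because carriage odds use the same total-visit exposure in both classes,
  the marginal first-occurrence odds ratio estimated downstream — censored
  case record versus full noncase record — equals $e^{\lambda}$ up to the
  noncollapsibility of marginalising over heterogeneous visit counts. For
  dense concepts (carriage near 0.5) this noncollapsibility attenuates the
  marginal OR by roughly 10–20%, which is an inherent property of odds
  ratios, not a pipeline bias; sign and ranking are preserved.

Cases receive a case-defining ICD-9 code at an index date drawn uniformly
over the last 60% of their visit span, so most have usable pre-index
history; a configurable fraction (site-specific, 15–38% in the reference
network) index at their first visit and therefore exercise the
no-pre-index exclusion rule. A small tail (2%) of patients falls outside
the 10–90 age window to exercise the age filter. Post-index case visits
keep emitting at baseline: the generator always writes *complete*
histories, and censoring is left entirely to the cohort builder so that
censoring soundness is a testable property rather than a construction
artifact.

The reference network (`reference_network_specs()`) fixes five sites whose
relative sizes, pre-exclusion case prevalences (1.30/2.00/1.70/0.89/0.40%),
data spans (17/17/10/13/8 years), no-history fractions and sex and
race/ethnicity mixes follow the published description of five US health
systems, scaled to desk size (default 1%, ~37,000 patients). The default
concept catalog mixes high-risk concepts patterned on the reported
magnitudes (suicidal ideation, drug withdrawal, borderline personality,
toxicology labs, lithium; ORs ~2.5–11) with common routine-care concepts
(office visits, CBC, URI; ORs 0.8–1.2) that provide visit density. Visit
rates (1.8–2.4/year) were chosen once as plausible ambulatory contact
rates; the original sites' visit-frequency distributions are not published,
so the Poisson process is a stand-in, not a claim about the source data.

What the generator does **not** emulate: disease co-occurrence and coding
correlation (concepts are conditionally independent given case status —
exactly the naive Bayes assumption), care-seeking intensity that differs
between cases and noncases, secular coding trends, and ICD-10. Because the
generated data satisfy the classifier's independence assumption, synthetic
discrimination (AUC ≈ 0.80–0.97 at desk scale) is substantially better
than what the method achieves on real EHR data (AUC ≈ 0.71–0.76); passing
tests demonstrate the pipeline's correctness and calibration, not
real-world effect sizes.

## Evaluation choices

* **Threshold source.** Thresholds come from the *training* split's noncase
  maximal scores and are then applied to the validation split. Deriving
  them from validation noncases would leak the evaluation set into the
  alert rule; the training-derived reading is the only leak-free one.
* **AUC.** Rank-based Mann–Whitney estimator with tie correction (ties
  count one half), standard error by the Hanley–McNeil formula; the 95% CI
  is a normal interval clipped to [0, 1]. An $O(n^2)$ pairwise oracle and
  an independent library implementation back it in the tests.
* **Odds ratios.** Cross-product OR with Haldane–Anscombe correction (0.5
  added to all four cells when any cell is zero) and a Woolf CI on the
  corrected cells. Reporting mirrors the published table rules: concepts
  carried by fewer than 100 patients are dropped from reports and ORs with
  fewer than 10 case carriers are suppressed; the model itself keeps every
  concept regardless of frequency.
* **Timeliness.** Arithmetic mean of lead times over detected cases with a
  normal 95% CI; a single detection reports a mean without a CI, zero
  detections report `n = 0` with an absent mean.
* **Decile table.** Bin boundaries are the 10%–90% type-1 quantiles of the
  *noncase* maximal-score distribution, so by construction each decile
  holds ~10% of noncases and case concentration in the top decile measures
  discrimination.
* **Aggregation.** Cross-site means are unweighted (the published mean AUC
  equals the unweighted mean of the five printed AUCs) with min–max ranges;
  concept counts are pooled by summation and the case share is
  `100 * cases / (cases + noncases)` among pooled carriers.
* **Smoothing and log base.** The original smoothing scheme and log base
  are unpublished; additive $k = 1$ and the natural log are used, both
  configurable. The base rescales all scores by a constant and therefore
  cannot change quantile thresholds, alerts, ranks or AUC.
* **Split.** Unstratified patient-level simple random 50/50 split, seeded.
  With very small sites a split can lack training cases; this is raised as
  an explicit error rather than silently degraded.

## Numerical and degenerate-input conventions

Strict `>` everywhere an alert is decided; ties at the threshold never
alert. Patients with no scored features have a flat trajectory with
maximal score 0 — the score scale is shift-sensitive only through
thresholds learned under the same convention, so this is internally
consistent. Same-date features are summed in stable input order and only
date-level cumulative values are treated as meaningful (the maximum is
taken over date-level sums; whether the original implementation used
event-level or date-level partial sums is unstated). Lead times use
365.25 days/year. Concepts unseen in training contribute 0 but still
produce a trajectory step. All randomness flows through explicit integer
seeds; generation and the pipeline are pure functions of (spec, seed).

## Problem sizes used in the test suite

The packaged tests run the property suites at sizes chosen to make the
statistical assertions sharp on a single CPU: specificity calibration on
~20,000 validation noncases against exact binomial 95% bounds; sign
recovery of planted log-ORs (|log OR| ≥ 1, baseline ≥ 0.005) over 20
replicates of 50,000-patient sites; OR magnitude recovery within ±25% of
$e^2$ for a dense planted concept across the same replicates; AUC oracle
agreement to 1e-9 on 100 random instances; and null-network behavior
(AUC within 3 SE of 0.5, top-decile case share within binomial error
of 10%) on a 20,000-patient site. The analysis scripts run the reference
network at 1% scale; `reference_network_specs(scale = ...)` scales it up.

## Known limitations

The method predicts the *first* documented suicidal event only; repeat
attempts are out of scope by design. The visit proxy (distinct event
dates) may differ from true encounter counts. The synthetic generator's
independence and homogeneous-Poisson assumptions make it a correctness
harness, not a realism benchmark. PPV on any realistically rare outcome is
low at useful specificity levels — an inherent property of base rates, not
of the scoring rule.
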