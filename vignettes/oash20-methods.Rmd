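---
title: "Measuring chronic conditions and multimorbidity with the OASH 20-condition scheme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chronic conditions and multimorbidity with the OASH 20-condition scheme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oash20)
```

## The measurement problem

Estimates of how many people live with chronic conditions — and how many
live with several at once (multiple chronic conditions, MCC) — vary widely
across studies, largely for instrumental rather than epidemiological
reasons: published definitions of "chronic condition" disagree on duration,
functional limitation and need for ongoing care; classification schemes
disagree on how many conditions to track (from 20 to 185); and the national
data systems that supply the estimates measure conditions differently
(self-report interviews, chart-abstraction checkboxes, CCS-grouped
diagnoses, raw ICD-9-CM claims) on different units of analysis (persons,
outpatient visits, hospitalizations).

`oash20` operationalizes a two-dimensional conceptual model for this
problem. Dimension one is a classification scheme: the 20-condition list
developed by the HHS Office of the Assistant Secretary for Health (OASH),
shipped here as a machine-readable registry with per-condition code sets.
Dimension two is a model of the data system ("dialect") the scheme is
applied to: its unit of analysis, its condition-data kind, and which of the
20 conditions it can measure at all. The intersection of the two — applying
the coding rules to a system's records — yields per-unit condition
profiles, from which the package computes the model's output indicators:
per-condition prevalence, MCC prevalence, the condition-count distribution
and dyad co-occurrence.

## The registry and its encoding decisions

The packaged registry (`inst/extdata/oash20_registry.json`, loaded by
`load_registry()`) encodes the published 20 x 5 mapping table verbatim:
each cell is kept as printed and parsed at load time into normalized code
sets (ICD-9-CM compact form with the decimal removed; CCS categories as
integers; inclusive integer ranges such as `105–106` expanded). Where the
source is internally inconsistent the registry records both readings and a
single operational choice:

* **NAMCS availability.** The transcribed table prints "Not applicable" for
  seven NAMCS cells, while the accompanying narrative counts NAMCS as
  measuring 19 of 20 conditions with only chronic kidney disease
  unavailable. The narrative is the operative encoding (it carries the
  scheme's own headline totals); the table reading is retained in per-cell
  provenance notes.
* **The NHIS kidney proxy.** NHIS has no chronic kidney disease question but
  asks about weak or failing kidneys. The cell is encoded as a
  `related_proxy` item that reports under chronic kidney disease by default
  (`coding_config(count_proxies = FALSE)` disables this), and it counts
  toward the NHIS total of 10.
* **Transcription artifacts.** The depression claims cell contains a stray
  token `2`, which is not a valid diagnosis code; it is dropped at parse
  time with a logged validation note. The autism MEPS/NIS cells print
  5-digit ICD-9-CM-style values (`29900, 29901`) in an otherwise-CCS
  column; they are stored verbatim under the declared system with a
  cross-system anomaly note. CCS 108 is printed for both congestive heart
  failure and chronic kidney disease; it is encoded as printed, with a
  duplicate-code note.

Availability totals derived from this encoding are NHIS 10, NAMCS 19,
MEPS 20, NIS 20, CMS 15:

```{r coverage}
reg <- load_registry()
coverage_report(reg)
```

## Coding semantics

Matching is **exact on normalized codes** by default. The scheme enumerates
codes at mixed specificity (a list can carry both `585` and `585.1`), so
prefix expansion would silently widen some definitions; an optional
prefix-matching mode (`coding_config(prefix_matching = TRUE)`) is available
for data known to carry more specific codes than the lists. E-codes are
rejected outright — none appear in the scheme, so one in the input signals
a data-quality problem.

The default flagging rule is *any single qualifying record*. Warehouse
claim-count/reference-period algorithms are intentionally not reproduced
(they are external to the scheme itself); `min_records_per_condition`
generalizes the rule to "seen on at least k distinct records". One code may
set several flags: the printed lists overlap (for example `402.01` appears
under both hypertension and congestive heart failure), and the coder
preserves that property rather than resolving it. Records whose codes do
not parse, or whose declared code system contradicts the dialect, are
quarantined under a configurable policy (`warn`/`ignore`/`error`).

Units of analysis follow the data systems' designs: persons for NHIS, MEPS
and CMS, outpatient visits for NAMCS, hospitalizations for NIS.
Cross-encounter aggregation to persons for the visit/hospitalization
systems is out of scope, matching what those systems support.

## The synthetic world

The generator exists so every pipeline stage is testable without access to
restricted data. Its stated world:

* **Truth.** Condition indicators are drawn by a Gaussian copula: a latent
  multivariate standard normal with a configurable correlation matrix is
  thresholded at the quantile matching each marginal prevalence. The copula
  was chosen because no dependence structure is prescribed for the scheme;
  it gives exact marginals with a single well-understood association
  parameter per pair. A convenience converter `latent_corr_from_or()` maps
  a target pairwise odds ratio to a latent correlation via the classical
  tetrachoric approximation `cos(pi / (1 + OR^0.75))`, documented as an
  approximation only.
* **Default prevalences** (`default_prevalence()`) are plausible US-adult
  orders of magnitude — hypertension 0.30, hyperlipidemia 0.25, arthritis
  0.23, diabetes 0.10, down to HIV 0.005 — chosen once as a realistic
  stated world, not fitted to anything, and not revisited.
* **Claims emission.** Every true condition the dialect measures yields one
  guaranteed claim; `Poisson(claims_per_unit = 4)` additional claims per
  unit draw codes from the unit's true conditions, each replaced with
  probability `extraneous_code_rate = 0.1` by a decoy — a valid-format code
  belonging to none of the 20 code sets (ICD-9-CM decoys also avoid every
  listed three-digit root, so they stay inert even under prefix matching).
  Codes are drawn preferring members that identify exactly one condition in
  the dialect: because the printed lists overlap, emitting a shared code
  would flag a condition the unit does not have and make exact parameter
  recovery impossible by construction. Under CMS every measured condition
  retains unambiguous codes, so the zero-noise pipeline recovers true
  prevalence *exactly*; in MEPS/NIS congestive heart failure and chronic
  kidney disease share their entire (single-code) sets and are irreducibly
  confounded — the tests assert exact recovery everywhere else and
  union-behavior for that pair.
* **Survey emission.** Items answer "yes" with probability `sensitivity`
  (0.85 by default) given the condition and `1 - specificity` (specificity
  0.97) otherwise, independently per item, so observed prevalence follows
  the closed form `p*s + (1 - p)(1 - c)`; tests check it within 3 binomial
  standard errors.
* **Randomness.** One master seed; each stage (truth, claims, survey) and
  each dialect derives a fixed sub-seed from it, so outputs are
  reproducible bit-for-bit and independent of call order.

What a green test does **not** establish: the generator has no age/sex
structure, no visit-frequency correlation with morbidity, no longitudinal
claims history, and survey misclassification is independent across items —
real self-report errors are correlated within respondents. Green tests
certify the measurement machinery (parsing, mapping, coding, aggregation),
not realism of the simulated epidemiology.

## Indicators and numerical choices

`compute_indicators()` returns weighted or unweighted per-condition
prevalence, MCC prevalence at a threshold (default 2, the conventional
definition of "multiple"), the condition-count distribution top-coded at
`4+` (the common reporting convention; bin edges are configurable), and
dyad co-occurrence counts via a cross-product of the flag matrix. Weights
are plain per-unit analysis weights; design-based variance estimation is
deliberately out of scope. Equal weights reduce algebraically to the
unweighted estimator, and `mcc_prevalence` equals the count-distribution
mass at or above the threshold by construction — both are also tested.

`compare_dialects()` reports prevalence differences between reports and
flags conditions measurable in one dialect but not another as structurally
incomparable: a difference there is an instrument effect, not an
epidemiological one. Degenerate inputs error early: empty populations,
negative or all-zero weights, single-report comparisons, descending code
ranges, non-positive-semidefinite association matrices (the offending
eigenvalue is named).

## Known limitations

* ICD-9-CM only, as published; no ICD-10 translation.
* The CMS cancer mapping covers four cancer sites only (female breast,
  colorectal, prostate, lung), narrower than the condition's "all except
  nonmelanoma skin" scope; it is encoded as printed with a scope note.
* The MEPS/NIS congestive heart failure / chronic kidney disease confound
  (shared CCS 108) is inherent to the printed scheme.
* No reference-period or claim-count logic; dates are accepted but unused.
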