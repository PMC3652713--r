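# oash20

Standardized measurement of chronic conditions and multimorbidity (MCC)
with the 20-condition classification scheme developed by the HHS Office of
the Assistant Secretary for Health (OASH).

Prevalence estimates for chronic conditions — and for *multiple* chronic
conditions, conventionally 2 or more concurrent conditions in one person —
are hard to compare across studies because the instruments differ: the
National Health Interview Survey (NHIS) asks people, NAMCS abstracts chart
checkboxes per outpatient visit, MEPS and the Nationwide Inpatient Sample
(NIS) carry CCS-grouped diagnoses, and Medicare (CMS) claims carry raw
ICD-9-CM codes — and not every system can measure every condition. This
package encodes the OASH scheme and those five data-system "dialects" in a
machine-readable registry, applies the scheme to claims-like and
survey-like records, and computes the resulting indicators. A synthetic
population generator with known multimorbidity structure makes the whole
pipeline testable end to end without restricted data.

For unit \(i\) with condition flags \(y_{ic} \in \{0,1\}\) over the 20
conditions \(c\), the package computes condition counts
\(k_i = \sum_c y_{ic}\), per-condition prevalence
\(\hat p_c = \sum_i w_i y_{ic} / \sum_i w_i\), MCC prevalence
\(\Pr(k_i \ge t)\) at threshold \(t = 2\) by default, the distribution of
\(k_i\) top-coded at 4+, and dyad co-occurrence counts
\(\sum_i w_i\, y_{ic}\, y_{ic'}\). The synthetic truth is a Gaussian
copula: \(y_{ic} = \mathbf 1\{z_{ic} > \Phi^{-1}(1 - p_c)\}\) with
\(z_i \sim N(0, R)\); survey measurement follows the classical
misclassification form \(\Pr(\text{yes}) = p\,s + (1-p)(1-c)\) for
sensitivity \(s\) and specificity \(c\).

## Worked example

```r
library(oash20)
reg <- load_registry()
reg
#> <mcc_registry> OASH list of selected chronic conditions (version 2011)
#>    20 conditions x 5 data-system dialects
#>   measured per dialect: NHIS=10 NAMCS=19 MEPS=20 NIS=20 CMS=15
#>    6 validation note(s); see $validation

claims <- data.frame(
  unit_id   = c("A", "A", "A", "B", "B", "C"),
  record_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
  code      = c("402.01", "250.00", "493.90", "272.0", "00188", "585.3"))
prof <- code_population(claims, reg, "CMS")
prof
#> <mcc_profiles> 3 unit(s) under CMS | 6 record(s), 0 quarantined
#>   unit_id hypertension congestive_heart_failure ... n_conditions
#> 1       A         TRUE                     TRUE ...            4
#> 2       B        FALSE                    FALSE ...            1
#> 3       C        FALSE                    FALSE ...            1

compute_indicators(prof)
#> <mcc_indicators> 3 unit(s) under CMS
#>   MCC prevalence (>= 2 conditions): 0.333
#>   condition count distribution:
#>     0     1     2     3    4+
#> 0.000 0.667 0.000 0.000 0.333
#>   top prevalences: hypertension=0.333  congestive_heart_failure=0.333  ...
```

What the numbers mean: unit A's single claim `402.01` (hypertensive heart
disease with heart failure) sets **both** hypertension and congestive heart
failure — the scheme's code lists overlap and the coder preserves that —
plus diabetes (`250.00`) and asthma (`493.90`), so A has 4 conditions and
is the one MCC case (1 of 3 units, prevalence 0.333). Unit B's `00188` is a
valid-format code outside all 20 lists and flags nothing; C's `585.3`
(chronic kidney disease stage III) flags chronic kidney disease.

Availability across systems, including the three mapping patterns
(measured / related proxy / unavailable):

```r
coverage_report(reg)          # 20 x 5 table; totals 10 / 19 / 20 / 20 / 15
availability(reg)["chronic_kidney_disease", ]  # NHIS: related_proxy
conditions_for_code(reg, "402.01", "CMS")      # both owning conditions
```

Synthetic end-to-end loop (also available from the command line via
`inst/cli/oash20.R`):

```r
cfg   <- synthetic_config(n_units = 10000, seed = 1,
                          extraneous_code_rate = 0, registry = reg)
truth <- simulate_truth(cfg)
prof  <- code_population(emit_claims(truth, reg, "CMS"), reg, "CMS",
                         units = truth$unit_id)
ind   <- compute_indicators(prof)
# at zero coding noise, recovered prevalence == true prevalence exactly
```

## Command line

```sh
Rscript inst/cli/oash20.R coverage
Rscript inst/cli/oash20.R simulate --out-dir sim --n 10000 --seed 1 --dialects CMS,NHIS
Rscript inst/cli/oash20.R code --input sim/claims_CMS.csv --dialect CMS \
    --out sim/profiles.csv --units sim/truth.csv
Rscript inst/cli/oash20.R indicators --profiles sim/profiles.csv --out sim/report.json
```

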