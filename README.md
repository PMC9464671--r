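# valsim

Monte-Carlo comparison of **internal vs external validation** of a
fixed-form clinical prediction model, in the setting of PET-based risk
prediction for diffuse large B-cell lymphoma (DLBCL).

Prognostic models built on PET radiomics are typically developed on small
cohorts, and the question of *how* to validate them — repeated
cross-validation, a holdout split, an optimism-corrected bootstrap, or a
dedicated external test set — matters more than it seems: a single small
test set carries large uncertainty, and an external set with a different
case mix measures something different from sampling variation. valsim makes
these trade-offs measurable by simulating cohorts whose data-generating
mechanism is fully known, so every validation approach can be scored
against the same ground truth.

## What is simulated

Each synthetic patient has an Ann Arbor stage (2/3/4, allocated
deterministically at 16/21/63%), three stage-specific log-normal PET
metrics (SUVpeak, metabolic tumor volume MTV, dissemination distance
Dmax), and two binary flags (age > 60 at 30%, WHO performance status > 1
at 23/16/6% per stage). Risk comes from a fixed published logistic model

```
p = 1 / (1 + exp(-LP))
LP = -6.532 + 0.533·log MTV − 1.395·log SUVpeak + 0.257·log Dmax
     + 0.773·IPIage + 0.787·WHO
```

and outcome labels are generated by **threshold + misclassification**:
patients with `p ≥ 0.375` are provisional events, then exactly 45% of the
high-risk and 15% of the low-risk patients are relabeled (uniformly,
without replacement). Validators score every approach by ROC AUC
(Mann–Whitney concordance) and calibration slope (ML slope of
`outcome ~ a + b·lp` on test data).

Scenario runners rebuild the study's full 17-row battery: three internal
approaches, external test sets of 100/200/500 patients, EARL2-style PET
reconstruction shifts, case-mix shifts (equal or single-stage external
populations), positivity cutoffs 0.10/0.66/0.90, and label-noise levels
12/25/45%.

## Worked example

```r
library(valsim)

# a labeled 500-patient cohort under the default study conditions
cohort <- simulate_labeled_cohort(500, seed = 42)
cohort
#> # A tibble: 500 × 9
#>   patient_id stage log_suvpeak log_mtv log_dmax age_gt60 who_gt1 true_p outcome
#> 1          1     2        3.47    14.3     4.63        0       0 0.0711       0
#> 2          2     2        2.50    12.4     4.10        0       0 0.0862       0
#> ...

# stratified five-fold CV, twice repeated: 10 fold-level AUCs
folds <- cross_validate(cohort, k = 5, repeats = 2, seed = 1)
summarize_metric(folds$auc)
#> # A tibble: 1 × 6
#>       n  mean     sd ci_low ci_high n_dropped
#> 1    10 0.603 0.0917  0.494   0.760         0

# an external-validation scenario: train on 400 default patients,
# test on 500 stage-2-only patients, 25 independent replications
res <- run_scenario(
  scenario_spec("ext_stage2_only", "external", n = 400,
                test_profiles = single_stage_profiles(2),
                outer_repeats = 25),
  master_seed = 42
)
res
#> <scenario_result ext_stage2_only> 25 records (0 failed)
#>   AUC   0.581 +/- 0.021 (0.542-0.613)
#>   slope 0.598 +/- 0.201 (0.298-0.976)

# the discrimination ceiling the label noise leaves to any model
expected_auc_oracle(n_large = 1e5, seed = 42)
#> [1] 0.6207252
```

Reading the numbers: the CV mean AUC (0.60) sits just under the noise
ceiling (0.62) — the refit model recovers essentially all recoverable
signal. The stage-2-only external set discriminates worse (0.58) and its
calibration slope of 0.60 < 1 shows the trained coefficients are too
extreme for a low-stage population: the case-mix shift, not sampling
noise, is what the external set detects. `autoplot()` on a scenario
result draws the per-repeat AUC scatter;
`run_all(default_scenarios(), master_seed = 1)` produces the whole
battery with a summary table, and `tidy()`/`glance()` give tibble views
of any result.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/valsim.R simulate --n 500 --out cohort.csv --seed 7
Rscript inst/scripts/valsim.R run-all --out results/ --seed 42 --fast
```

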