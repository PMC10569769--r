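# navfair

Fair, prediction-informed distribution of newly diagnosed cancer
patients among cancer patient navigators (CPNs).

## The problem

Specialized CPNs guide patients through screening, diagnosis,
treatment, and follow-up. New patients are typically handed to a
specialty's navigators in rotation — effectively at random — and, to
preserve the patient–navigator relationship, patients are essentially
never transferred afterwards. Workloads therefore drift far apart, and
sustained overload is a recognized driver of navigator burnout. The
only lever available is the placement of *new* patients.

`navfair` is for health-services researchers and clinical-operations
analysts who want to study (and stress-test) the algorithmic
alternative: predict the work each active patient will generate next
week, then place the week's new patients so the specialty's total
predicted workload is as even as possible.

## The model

**Unfairness metric.** For a specialty with `m` navigators carrying
weekly workloads `L_1..L_m`, the fair share is `F = (Σ L_j)/m` and the
weekly unfairness is the mean absolute deviation

```
U = (1/m) Σ_j | L_j − F |
```

Weekly series are summarized as `mean ± 1.98·SD/√n`. Workload is
measured by the `enct` proxy: EHR encounters per day, counting at most
one encounter per patient per day.

**Two-stage predictor.** Patient-weeks are clustered with k-prototypes
(mixed numeric/categorical dissimilarity, k = 7 by default, elbow
selection available); the cluster id joins a gradient-boosted-tree
regressor (xgboost) tuned by a 15-combination random search under
3-fold patient-level cross-validation.

**Distribution model.** Each week's new patients are assigned to
navigators to minimize the unfairness of predicted loads (existing
panel + new patients) — solved exactly by enumeration for up to 12 new
patients (a greedy longest-processing-time fallback beyond), under the
consistency constraint that no patient is ever reassigned.

**Evaluation.** A weekly simulation on a held-out patient partition
compares three policies on identical realized encounter streams:
prediction-informed assignment, a random baseline (each week's random
distribution repeated 10,000 times, mean unfairness recorded), and a
future-informed oracle fed realized workloads. Because no suitable
EHR data set is public, a calibrated synthetic cohort generator stands
in for the data: Poisson weekly arrivals (13.4/week in two-navigator
specialties, 20.1/week in three-navigator ones), 90-day activity
tails, and zero-inflated daily encounters whose 30-day totals match
the reference workload distribution (median 0, mean ≈ 0.5, SD ≈ 1.1,
CV ≈ 220%, range 0–15).

See `vignettes/workload-distribution.Rmd` for the full methods
account.

## Worked example

```r
library(navfair)

cfg <- cohort_config(n_weeks = 30, seed = 11, interaction_log = FALSE)
coh <- generate_cohort(cfg)
coh
#> <cpn_cohort> 2533 patients, 5 specialties, 30 weeks, 5968 encounter-days
#>   train/test patients: 2026/507; seed 11

unlist(monthly_workload_stats(coh)[c("mean", "sd", "median",
                                     "cv_percent", "skew", "max")])
#>        mean          sd      median  cv_percent        skew         max
#>   0.5202685   1.0954864   0.0000000 210.5617381   1.4247603  13.0000000

m <- workload_model(build_model_table(coh, "train"), seed = 12)
m
#> <workload_model> family gbt, k = 7 clusters, best CV MSE 0.0850
#>   trained on 2026 patients; baseline mean 0.1662

cmp <- simulate_policies(coh, m, n_reps = 10000, seed = 13)
summary(cmp)
#> Pooled weekly unfairness by policy:
#>               policy      mean        sd    ci_low   ci_high
#>  prediction_informed 0.6370370 0.5488660 0.5483039 0.7257702
#>               random 1.0879780 0.4788264 1.0105679 1.1653881
#>      future_informed 0.3592593 0.3625447 0.3006480 0.4178705
#>  pct_reduction_vs_random
#>                 41.44762
#>                  0.00000
#>                 66.97918
```

Reading the output: per-patient monthly encounter counts from the
generator match the calibrated workload distribution (zero-inflated,
mean ≈ 0.5, SD ≈ 1.1); the fitted predictor beats the training-mean
baseline (CV MSE 0.085 vs. a target variance well above it); and over
30 simulated weeks the prediction-informed policy cuts pooled mean
weekly unfairness by ~41% relative to the repeated-random baseline,
sitting between the random policy and the future-informed oracle
(~67%), with non-overlapping 95% CIs.

`plot(cmp)` draws the by-specialty bar chart, and
`run_pipeline(cfg, out_dir = "out")` writes the weekly series CSV,
summary JSON, and config snapshot in one call. A thin command-line
wrapper lives at `inst/cli/navfair`.

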