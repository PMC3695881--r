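# pcnet

Physician collaboration networks (PCNs) from claims data: network
construction, centralisation/density indices, hospital outcome analysis,
and exponential random graph (ERG) models with MCMC maximum-likelihood
estimation.

## What it does

When physicians visit a common hospitalised patient they collaborate —
they act on the same record and each other's advice.  `pcnet` turns
claims-style visit records (one row per physician visit) into one
weighted undirected network per hospital, where the weight of a tie
between two physicians is the number of distinct patients both visited.
It then supports the full analysis such networks are built for:

* **Network indices** — Freeman degree centralisation
  `sum(d_max - d_i) / ((N-1)(N-2))`, betweenness centralisation
  `sum(C'_B(n*) - C'_B(i)) / (N-1)` on normalised betweenness, and
  density `2*N_t / (N(N-1))`; a star scores 1 on both centralisations,
  egalitarian graphs score 0.
* **Outcome analysis** — per-hospital mean cost per patient, readmission
  rate (% of patients with more than one admission episode) and mean
  patient age; Spearman correlations, OLS regressions, age-moderation
  models, extreme-group selection and pooled two-sample t-tests of ERG
  parameter t-values between outcome groups.
* **ERG models** — `Pr(X = x) ∝ exp(Σ_A η_A g_A(x))` on tie-level
  graphs, with Markov terms (edge, 2-star, 3-star, triangle) and
  alternating terms (k-star, k-triangle, independent two-path; constant
  λ > 1), a Metropolis dyad-toggle sampler driven by local change
  statistics, and Robbins–Monro MCMC maximum likelihood with standard
  errors from the inverse statistic covariance and convergence t-ratios
  `|mean_sim - obs| / sd_sim ≤ 0.1`.
* **Synthetic cohorts** — a claims generator with a tunable
  decentralised↔star attachment axis and cost/readmission outcomes
  planted on the realised network indices, so the whole pipeline can be
  validated without access to any private claims extract.

## Worked example

```r
library(pcnet)

cohort <- generate_cohort(synth_config(n_hospitals = 85, seed = 7))
cohort
#> synthetic claims cohort: 85 hospitals, 2375 patients, 64593 claims

visits <- filter_hospitals(cohort$claims, min_patients = 5,
                           procedure_code = "THR")
pcns <- build_pcns(visits)
pcns[["H001"]]
#> Physician collaboration network -- H001
#>   physicians: 14  collaborations: 26  patients: 23

tab <- analysis_table(summarise_pcns(pcns), compute_all_outcomes(visits))
correlate(tab, "density", "mean_cost_per_patient")
#>   variable_x variable_y              rho  p_value     n method
#> 1 density    mean_cost_per_patient 0.856 1.74e-25    85 rank
correlate(tab, "betweenness_centralisation", "mean_cost_per_patient")
#>   variable_x                 variable_y              rho  p_value  n method
#> 1 betweenness_centralisation mean_cost_per_patient -0.846 2.18e-24 85 rank
```

Dense networks cost more, centralised ones less — the generator plants
exactly these effects on the realised indices, and the pipeline recovers
them.  Fitting an ERG model to one network:

```r
g <- binarise(pcns[["H001"]], threshold = 1)
fit <- ergm_fit(g, ergm_spec(c("edge", "alt_k_star", "alt_k_triangle"),
                             lambda = 2), seed = 7)
fit
#> ERG model fit (MCMC maximum likelihood)
#>                estimate stderr t_value conv_t_ratio
#> edge            -0.7172 1.5240   -0.47        0.013
#> alt_k_star      -0.8739 0.5931   -1.47        0.020
#> alt_k_triangle   1.3034 0.4565    2.85        0.004
#> converged: TRUE
```

The t-value column (estimate / stderr) is what the group comparisons
consume.  Comparing a parameter's t-values between the 5 lowest- and 5
highest-cost networks of the shipped reference estimates:

```r
ref <- resolve_tvalues(reference_ergm_estimates())
tv <- function(grp, term) ref$t_value[ref$group == grp & ref$term == term]
tvalue_group_test(tv("low_cost", "two_star"),
                  tv("high_cost", "two_star"), "two_star")
#>   parameter mean_low se_low n_low mean_high se_high n_high t_statistic df p_one_tail
#> 1 two_star      1.824  1.327     5     9.688   3.445      5        2.13  8     0.0329
```

High-cost networks show a significantly stronger 2-star tendency — their
physicians accumulate many partners without a single dominant hub.

See the vignette
(`vignettes/physician-collaboration-networks.Rmd`) for the model
definitions, estimation schedule, generator design and limitations.

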