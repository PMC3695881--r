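---
title: "Physician collaboration networks: construction, indices, outcomes and ERG models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physician collaboration networks: construction, indices, outcomes and ERG models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnet)
```

## The problem

When several physicians attend the same hospitalised patient they read and
write the same patient record, exchange advice, and de facto collaborate.
Aggregating co-visitation over all patients of one hospital yields that
hospital's *physician collaboration network* (PCN): an undirected graph on
the hospital's physicians in which a tie means "visited at least one common
patient" and the tie weight counts those patients.  The package builds these
networks from claims-style visit records, measures how centralised or dense
each one is, relates those measures to hospital outcomes (mean
hospitalisation cost per patient and readmission rate), and models the
micro-structure of individual networks with exponential random graph (ERG)
models.

The motivating application is a cohort of total-hip-replacement (THR)
admissions across 85 hospitals; the raw claims are private, so the package
ships (i) a synthetic claims generator with the same schema and a planted
structure–outcome link, and (ii) a transcription of the published ERG-model
estimates for the 20 outcome-extreme networks, used as fixed inputs for the
group comparisons.

## From claims to networks

A claims row is one physician visit: hospital, patient, physician,
admission episode, date, claim category (`ancillary`, `medical`,
`hospital`), benefit amount, patient age, procedure code.  `read_claims()`
validates row by row and keeps rejects with reasons rather than dropping
them silently.  `filter_hospitals()` applies the eligibility rule (at least
5 distinct index-procedure patients) and restricts each retained hospital
to its index cohort.

`build_pcn()` projects the two-mode patient–physician relation of one
hospital onto physicians: the weight of `(i, j)` is the number of distinct
patients both visited.  Three conventions matter and are deliberate:

* only `medical` claims define visits (the other categories are lodged by
  the hospital and carry cost, not collaboration);
* co-visitation counts patients over the whole observation window, not
  per admission episode — the projection counts patients, and a patient is
  the same patient across readmissions;
* physicians with visits but no shared patient stay in the graph as
  isolates: they belong to the network's size `N`, which every
  network-level index divides by.

Outcome measures (`compute_outcomes()`): mean cost per patient sums the
benefit amounts of *all* claim categories over the hospital's cohort and
divides by the number of patients; the readmission rate is the percentage
of patients with more than one distinct admission episode; patient age
enters as the unweighted mean of one age per patient (the earliest record's
value when records disagree, which is deterministic and auditable).

## Network indices

On the dichotomised graph (`binarise()`, default threshold 1 shared
patient), with `N` nodes and degrees $d_i$:

* degree centrality $C'_D(i) = d_i / (N - 1)$;
* betweenness centrality
  $C'_B(i) = \sum_{j<k} \frac{g_{jk}(i)}{g_{jk}} \Big/ \frac{(N-1)(N-2)}{2}$,
  where $g_{jk}$ counts shortest $j$–$k$ paths and $g_{jk}(i)$ those through
  $i$; pairs with no connecting path contribute 0, which keeps the index
  defined on disconnected networks;
* density $= 2 N_t / (N (N-1))$ for $N_t$ ties.

The network-level centralisation indices are Freeman's: the summed gap to
the most central node divided by the maximum that sum can attain,

$$C_D = \frac{\sum_i (d_{max} - d_i)}{(N-1)(N-2)}, \qquad
  C_B = \frac{\sum_i (C'_B(n^*) - C'_B(i))}{N-1},$$

so a star scores 1 on both and any regular graph (e.g. a circle) scores 0
on degree centralisation.  Note the degree index uses *raw* degrees with
denominator $(N-1)(N-2)$: feeding normalised degrees through the same
denominator would cap the star at $1/(N-1)$, contradicting the index's
defining extreme, so the raw-degree convention is the coherent reading and
the one implemented.  Betweenness centralisation uses the normalised
centralities with denominator $N-1$.  Both need $N \ge 3$; smaller inputs
are a domain error, not a silent 0.

Node-level betweenness counts are delegated to igraph's exact algorithm;
the test suite checks them against an exhaustive path-counting oracle
(matrix powers at shortest distances) on all graphs it uses.

## Relating structure to outcomes

`analysis_table()` joins the per-hospital indices and outcomes.  The
association toolkit mirrors a conventional observational design:

* `correlate()` — Spearman rank correlation by default (reported as
  `rho`, two-tailed p); rank correlation is invariant under monotone
  transforms, which suits skewed cost scales.  The product-moment
  coefficient is one argument away; on the synthetic cohorts the sign and
  significance conclusions do not depend on the choice.
* `fit_simple()` — OLS of an outcome on one index.
* `fit_moderation()` — OLS on the index and the index × mean-age product.
  The moderator's main effect is *excluded by default*, mirroring the
  two-term design this package reproduces; `include_moderator_main = TRUE`
  gives the conventional three-term model.  A significant product term is
  read as moderation.
* `select_extremes()` — the k lowest- and k highest-outcome hospitals,
  ties broken by hospital id, deterministically.
* `tvalue_group_test()` — pooled-variance two-sample t-test between the
  low and high groups of one ERG parameter's t-values; one-tailed p for
  the observed direction; df is $n_1 + n_2 - 2$ (8 for two groups of 5 —
  published tables sometimes label this df 10, but the statistic values
  match the pooled equal-n formula
  $\bar{x}_H - \bar{x}_L$ over $\sqrt{SE_L^2 + SE_H^2}$).

No multiple-testing correction is applied; the number of tests run is the
caller's to report.  p-values are raw by design.

### Reconciling published estimate tables

`reference_ergm_estimates()` ships the published estimates, standard
errors and printed estimate/stderr ratios for the 20 outcome-extreme
networks.  The printed ratio column is preferred when it is consistent
with the rounded estimate and stderr (it was computed from unrounded
values, so it carries more precision), recomputed as estimate/stderr when
the printed column is corrupted, and flagged `NA` when recomputation would
divide by a stderr printed as 0.00 (`resolve_tvalues()`).  This single
rule reproduces the published group means to two decimals.  One published
group mean (high-readmission alternating two-path, −21.58) is not
reproducible from the printed table under any reading; the corresponding
group test is therefore computed from the published group means and
standard errors directly.

## The ERG model engine

An ERG model puts probability
$\Pr(X = x) = \kappa^{-1} \exp\{\sum_A \eta_A g_A(x)\}$ on graphs, where
each $g_A$ counts a local configuration.  Markov statistics are raw
counts: edges, k-stars ($S_k = \sum_i \binom{d_i}{k}$, hierarchical — a
triangle contains three 2-stars) and triangles.  The alternating
statistics down-weight higher orders geometrically with a constant
$\lambda > 1$ (default 2, the conventional choice), writing
$q = 1 - 1/\lambda$ and $sp_{uv}$ for common-neighbour counts:

* alternating k-stars
  $= \sum_{k \ge 2} (-1)^k S_k / \lambda^{k-2}
   = \lambda^2 \sum_i \left(q^{d_i} - 1 + d_i/\lambda\right)$;
* alternating k-triangles
  $= \lambda \sum_{(u,v) \in E} (1 - q^{sp_{uv}})$;
* alternating independent two-paths
  $= \lambda \sum_{u < v} (1 - q^{sp_{uv}})$.

The closed forms are the implementation; the tests evaluate the defining
alternating sums from enumerated subgraph counts and require equality.

$\kappa$ is never computed (outside enumeration tests at $N = 4$).
Everything runs on *change statistics* — the per-dyad differences
$g_A(x + ij) - g_A(x - ij)$, computed locally in compiled code and checked
against full recounts on hundreds of random cases.

`ergm_simulate()` is a Metropolis single-dyad-toggle sampler: propose a
uniform dyad, accept a toggle with probability
$\min(1, e^{\pm \theta^\top \delta})$.  Defaults: burn-in
$\max(10^4, 20\,D)$ toggles and thinning $D$ toggles for $D$ dyads.  Chains
use R's RNG, so a seed fixes the entire trajectory bit-for-bit.

`ergm_fit()` is stochastic-approximation (Robbins–Monro) MCMC maximum
likelihood, exploiting that the MLE of an exponential family equates
observed and expected sufficient statistics:

1. *Calibration*: a short run estimates the statistic covariance $D$;
   updates are scaled by a ridged inverse of $D$ (a Newton-type step —
   diagonal scaling is not enough because edge and star counts are
   strongly correlated).
2. *Updates*: subphases of $\theta \leftarrow \theta - a\,D^{-1}(g_{sim} -
   g_{obs})$ with the gain $a$ halved and the subphase length doubled each
   time ($a_0 = 0.1$, 4 subphases of 50, 100, 200, 400 single-sample
   updates); the estimate is the average over the final subphase.
3. *Check*: a long run (500 samples) at the final $\theta$ yields the
   sample covariance $\hat{S}$ of the statistics; standard errors are
   $\sqrt{\mathrm{diag}(\hat{S}^{-1})}$ (inverse Fisher information) and
   the convergence t-ratios $(\bar{g}_{sim} - g_{obs})/\mathrm{sd}(g_{sim})$
   must all fall within 0.1 for `converged = TRUE`.  If they do not, the
   covariance scaling is refreshed from this run and phases 2–3 repeat, up
   to 3 rounds.

The edge parameter starts at the logit of the observed density, other
terms at 0.  Degenerate situations are flagged, never looped on: an
observed empty or complete graph returns immediately with a `boundary`
flag (the MLE is at infinity), and a final chain spending >90% of its
samples at near-empty/near-complete graphs is flagged `degenerate`.
Parameter t-values divide estimate by stderr, with a floor guard so a
collapsed stderr yields `NA` rather than ±∞.

On a Bernoulli graph the whole machinery has closed forms — the edge-only
MLE is the logit of the observed density with variance
$1/(D p (1-p))$ — and the acceptance suite verifies both, plus coverage of
known parameters in an edge + 2-star recovery experiment at $N = 30$.

## The synthetic cohort generator

The generator (`synth_config()`, `generate_cohort()`) emulates the
*structure* the analysis assumes, not the marginal distributions of any
real insurer's data.  Per hospital: a lead physician and 5–47 index
patients (mean ≈ 26), each attended by a care team of 2–6 slots; a slot is
the lead with probability $0.97\,a$ (attachment $a$) and a uniformly drawn
colleague otherwise; 10–42 visits per patient spread over the team, one
medical claim each, plus hospital claims per admission and occasional
ancillary claims.  Lone-lead teams gain one colleague, so networks stay
non-degenerate and `attachment = 1` produces exact stars.

The attachment axis was calibrated once on realised indices (30-hospital
cohorts): $a = 0$ gives dense egalitarian networks (density ≈ 0.64,
degree centralisation ≈ 0.22), $a = 1$ near-perfect stars (centralisation
≈ 0.99), and the default $a = 0.6$ sits mid-range (density ≈ 0.39 ± 0.20,
degree centralisation ≈ 0.69, betweenness centralisation ≈ 0.56) — wide
enough spread for association analyses to have something to detect.

Outcomes are planted *on the realised indices*: per-patient cost is
$22500 + 17310 \cdot \text{density} - 12385 \cdot C_B + N(0, 12000)$
(slopes of the order of the published hospital-level regressions, floored
at 500), partitioned exactly over the patient's claims (55% hospital
claim, 1% ancillary when present, remainder over medical visits);
readmission is Bernoulli per patient with logit
$-1.1 - 2.5\,C_D + 3.5 \cdot \text{density}$, giving roughly 12%
readmissions at the default attachment, and a readmitted patient receives
a second admission episode.  Because cost depends on structure with known
signs, recovering the positive density–cost and negative betweenness–cost
correlations end-to-end is a genuine pipeline test (the acceptance suite
requires both signs at $\alpha = 0.05$ in ≥90% of 100 seeded cohorts; in
practice the realised rank correlations are around ±0.8, stronger than
real claims data, where unmodelled hospital heterogeneity would dilute
them).

What the generator does *not* emulate — and what passing tests therefore
do not certify about real data: case-mix and coding systems, cost scales
beyond rough magnitude, between-hospital heterogeneity unrelated to
network structure, physician turnover and time, and any dependence of
readmission on cost.  A cohort is a deterministic function of its full
configuration including the seed.

## Numerical choices and problem sizes

Tie threshold 1; $\lambda = 2$; convergence tolerance 0.1; RM gain 0.1
halved per subphase; ridge $10^{-4} + 0.05\,\overline{\mathrm{diag}(D)}$
on covariance inversions; extreme-group and age-conflict ties broken
deterministically (id order / earliest record).  The test suite runs
sampler-vs-enumeration checks at $N = 4$ (64 graphs), change-statistic
recounts on 200 random graphs ($N \le 8$), Bernoulli fits at $N = 50$,
recovery at $N = 30$ with 20 replicates, and 100 synthetic 85-hospital
cohorts; the whole suite completes in a few minutes on one CPU.

## Limitations

Only undirected, homogeneous (no nodal covariates) ERG terms are
provided; estimation is MCMC-MLE only (no pseudo-likelihood, no Bayesian
inference).  Networks never span hospitals.  Episode reconstruction
relies on admission identifiers, not dates.  Whether two physicians'
co-visits should be confined to the same admission episode is an open
interpretation question; the whole-window convention implemented here is
the one consistent with counting patients in the projection.
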