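# symptomnet

Contemporaneous symptom-network analysis for ordinal rating scales, built
for chronic-disease symptom research — the motivating setting is an
inflammatory bowel disease (IBD) cohort rating 18 symptoms on a 1–5
severity scale, but any person × item table of 1–5 ratings works.

Symptom co-occurrence is modeled as an undirected weighted network whose
nodes are symptoms and whose edges are **regularized partial
correlations**: with precision (inverse covariance) matrix Θ, the edge
weight between items *i* and *j* is

```
w_ij = -θ_ij / sqrt(θ_ii θ_jj)
```

Θ is estimated by the **graphical lasso**, which maximizes
`log det Θ − tr(SΘ) − λ Σ_{i≠j}|θ_ij|` over a log-spaced path of
penalties λ, with S the (PSD-repaired) Spearman correlation matrix of
the ratings. The penalty is selected by the **extended Bayesian
information criterion**, `EBIC = −2ℓ(Θ̂) + E log n + 4 E γ log p`
(γ = 0.5 by default), so weak, likely-spurious edges are pruned. Around
that core the package provides:

- **Covariate adjustment**: a screening regression of total severity on
  person-level covariates (B, standardized β, p, 95% CI, VIF,
  residual-diagnostic flags, noncentral-F post hoc power); covariates
  passing the screen enter the network as additional nodes, so
  symptom–symptom edges condition on them.
- **Centrality and core symptoms**: strength Σ|w|, expected influence
  Σw, and shortest-path closeness/betweenness with edge length 1/|w|;
  z-standardized tables; core symptoms ranked by strength;
  Fruchterman–Reingold layout coordinates.
- **Resampling**: nonparametric bootstrap edge CIs, case-dropping
  correlation-stability (CS) coefficients (≥ 0.25 minimal, ≥ 0.5 strong
  stability), and bootstrapped difference tests for edges and node
  strengths (95% intervals, uncorrected).
- **Node predictability**: per-node R² from its network neighbors
  (≥ 0.65 network-embedded, ≤ 0.30 externally driven).
- **A synthetic-data generator**: Gaussian-copula ordinal samples from a
  clustered sparse precision matrix with known ground truth, skewed
  marginals, and covariate effects — so the full pipeline is testable
  without any external data.

Everything is tidyverse-shaped: tables in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` / `plot_*()` for figures.

## Worked example

```r
library(symptomnet)

# a synthetic 324-person cohort: 18 items in 5 clusters, skewed 1-5
# ratings, disease-stage / years-since-diagnosis / treatment covariates
sim <- simulate_symptom_study(n = 324, seed = 7)

run <- run_pipeline(sim$table, seed = 7, resample = FALSE)
run
#> <symptom_run> n = 324, seed = 7
#>   unadjusted network: 40/153 edges (26.14%)
#>   adjusted network (+active_stage, years_since_diagnosis, treatment_otherwise): 43/210 edges (20.48%)
#>   core symptoms: bloody_purulent_stool, anal_fistula, tenesmus
```

The unadjusted network keeps 40 of the 153 possible edges (density
26.14%) after EBIC selection; the covariate screen (p < 0.001) passed
all three planted drivers, so the adjusted network has 21 nodes and
210 possible edges. Core symptoms are the top strength-centrality
nodes:

```r
head(rank_core_symptoms(run$centrality$unadjusted), 3)
#> # A tibble: 3 × 3
#>   node                  strength  rank
#> 1 bloody_purulent_stool    0.993     1
#> 2 anal_fistula             0.956     2
#> 3 tenesmus                 0.943     3

head(run$predictability[order(-run$predictability$r2), ], 3)
#> # A tibble: 3 × 3
#>   node                     r2 category
#> 1 bloody_purulent_stool 0.672 network-embedded
#> 2 tenesmus              0.667 network-embedded
#> 3 abdominal_distension  0.648 intermediate
```

Design-stage helpers: a 21-node network has
`required_sample_size(21)` = 231 free parameters (the conventional
minimum n), and the post hoc power of a 13-predictor severity
regression at f² = 0.15, α = 0.001, N = 324 is
`power_f_test(13, 0.15, 0.001, 324)` ≈ 0.968.

With `resample = TRUE` (the default) the run also carries bootstrap
edge CIs, CS coefficients, and difference tests;
`write_run_report(run, "report.json")` serializes everything to one
deterministic JSON file, and `autoplot(run$networks$unadjusted)`,
`autoplot(run$centrality$unadjusted)`, `plot_edge_ci()` and
`plot_stability()` draw the standard panels.

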