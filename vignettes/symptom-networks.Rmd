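---
title: "Methods: regularized symptom networks for ordinal ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularized symptom networks for ordinal ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The model

A symptom network treats each of *p* symptom items as a node of an
undirected weighted graph. Edges are partial correlations: the
association between two symptoms after conditioning on all other nodes.
Given a precision matrix Θ, the edge weight is
w~ij~ = −θ~ij~/√(θ~ii~ θ~jj~). Because individual symptom ratings on a
1–5 Likert scale are ordinal and heavily right-skewed (most patients
rate most symptoms "not at all"), associations are measured with
Spearman rank correlations (average ranks over the guaranteed ties)
rather than Pearson correlations.

Spearman matrices of discretized data can be slightly indefinite, so the
matrix is repaired before estimation by clipping negative eigenvalues at
zero and rescaling to unit diagonal (`nearest_psd()`). An already-PSD
matrix passes through untouched.

Estimation is an L1-penalized Gaussian maximum likelihood problem
(graphical lasso): maximize
log det Θ − tr(SΘ) − λ Σ~i≠j~ |θ~ij~|. The diagonal is unpenalized. The
solver is blockwise coordinate descent over the working covariance, with
each row/column update a lasso sub-problem, implemented in C++. The unit
tests cross-check it against an independently written ADMM solver (to
1e−5 and better on small problems).

The penalty λ is selected on a path of 100 log-spaced values from
λ~max~ (the largest absolute off-diagonal of S, where the network is
empty) down to λ~max~/100, by minimizing
EBIC = −2ℓ(Θ̂) + E log n + 4 E γ log p, where E counts nonzero
upper-triangle edges and ℓ = (n/2)(log det Θ − tr(SΘ)). The constant
terms of the Gaussian likelihood are omitted; they shift every EBIC
value equally and cannot change the selection. γ defaults to 0.5, the
conventional compromise between BIC-like consistency (γ = 0) and harsher
sparsity. An edge is "present" when |w| > 1e−8 — the threshold only
absorbs solver noise, since the lasso produces exact zeros — and network
density is E divided by the m(m−1)/2 possible edges.

## Covariates

Covariate control is done by adding covariates as network nodes, not by
residualizing the items: the adjusted network for p symptoms and c
covariates has p + c nodes, every symptom–symptom edge conditions on the
covariates, and centralities are computed on the full graph but reported
for symptom nodes. Which covariates enter is decided upstream by a
multivariable linear regression of the total severity score (row sum of
the p severity ratings) on all candidate covariates; predictors with
p < `alpha_screen` are selected. The screening level is explicit
configuration (default 0.001, a deliberately stringent level for
false-positive control) rather than hard-coded, since reasonable
analyses also screen at 0.05 or 0.01. The regression report carries
unstandardized B, standardized β = B·sd(x)/sd(y), 95% CIs, VIF (via
`car::vif`, cross-checked in the tests against explicit auxiliary
regressions), and diagnostic *flags* — a scale-location slope test for
heteroscedasticity, a Shapiro–Wilk residual-normality test, a max-VIF
flag — that never abort an analysis, mirroring how such checks are
reported in practice. The total-severity DV is the natural scalar
summary of the severity dimension; the package takes it as the row sum,
which is equivalent under linear regression to the mean.

Post hoc power for the screening regression uses the noncentral F
distribution with noncentrality λ = f²·N and degrees of freedom
(u, N − u − 1) — the standard "R² deviation from zero" convention. The
implementation is exact (`pf` with `ncp`); the acceptance suite checks
it against a 50,000-draw Monte Carlo within 0.005.

## Centrality, layout, and core symptoms

Strength (Σ|w|) and expected influence (Σw) are direct sums over
incident edges; on an all-positive network they coincide. Closeness and
betweenness are shortest-path indices with edge length 1/|w|, the
standard convention in network psychometrics: strong edges are short.
Closeness of node *i* is (m−1)/Σ~j~ d(i, j) over reachable *j*;
disconnected networks are handled over reachable pairs and flagged.
Betweenness follows the Brandes convention — unordered node pairs, with
equal-length shortest paths contributing fractional shares — computed by
igraph and cross-checked in the tests against a Floyd–Warshall
path-counting oracle. Verbal definitions of these indices in the applied
literature are sometimes looser ("directly connected nodes", "number of
times"); the package deliberately uses the standard all-pairs,
fractional-share definitions.

Core symptoms are ranked by strength alone, the primary criterion in
this literature; a composite multi-index view is available from the same
z-standardized table, but strength drives the headline ordering. Ties
are broken lexicographically and flagged. z-scores use the sample
(n−1) standard deviation; a degenerate index (zero spread) z-scores to
all zeros with a flag rather than NaN.

Layout uses the Fruchterman–Reingold algorithm (igraph) with |w| as
attraction weights, rescaled to [−1, 1]², deterministic under the seed.

## Resampling

Edge accuracy uses the nonparametric bootstrap: resample n persons with
replacement, re-run the entire estimation (Spearman → PSD repair →
EBIC-selected glasso), and take 2.5%/97.5% quantiles of each edge's
replicate distribution (defaults: 1000 replicates). Replicates that
fail estimation — e.g. a rare symptom becoming constant in a resample —
are recorded and skipped; more than 5% failures aborts.

Centrality stability uses case-dropping subsampling *without*
replacement (dropping is definitionally subsampling): for each drop
proportion q in 0.05, 0.10, …, 0.75, draw `n_per_drop` subsamples of
size round((1−q)n), re-estimate, and correlate the subsample centrality
with the full-sample centrality across nodes. The CS coefficient is the
largest q such that at every q′ ≤ q at least 95% of subsamples correlate
≥ 0.7 — the published convention behind the 0.25 (minimal) and 0.5
(strong) interpretive thresholds. Drop proportions leaving fewer than
p + 1 rows are dropped from the grid. One boundary case matters: if the
full-sample network is empty (as on independent noise), every strength
is zero, there is nothing to correlate against, and CS is *undefined* —
reported as such, never as a number. An undefined CS means no stability
can be attributed, which the classification reports alongside
"unstable".

Difference tests compare, for each pair of present edges (or each pair
of nodes, for strength), the bootstrap distribution of the difference;
a pair differs when the 95% quantile interval excludes zero, with no
multiplicity correction (these are descriptive, per-pair statements).
The acceptance suite verifies calibration: edges with identical planted
weights are flagged in no more than 10% of cases.

All resampling derives per-replicate seeds from the root seed by
counter, so results are identical whether replicates run serially, in a
different order, or are recomputed in isolation.

## Node predictability

Predictability of node *i* is the R² of an ordinary least-squares
regression of its ratings on the ratings of its nonzero-edge neighbors,
treating the 1–5 scale as numeric (consistent with the latent-Gaussian
view of the data). Conditioning on the *estimated* neighbor set is a
deliberate simplification of refitting a full mixed graphical model:
for all-numeric data, MGM nodewise regression reduces to penalized
linear regression, and the variance-explained-by-neighbors quantity is
what the R² categories describe. R² is computed in-sample by default
(the cited methodology's default), with a 10-fold cross-validated
variant behind a flag; it is clipped to [0, 1], isolated nodes score
exactly 0, and the categories are ≥ 0.65 network-embedded and ≤ 0.30
external-driven.

## The synthetic cohort generator

No generative model is mandated by the analysis itself, so the
generator uses the simplest mechanism whose regularized
partial-correlation network has a known target: a latent Gaussian
copula. The ground truth is a sparse symmetric positive-definite
precision matrix assembled from an item partition — dense support
within clusters, Bernoulli(`density_between`) support across clusters,
off-diagonal entries −`within_strength`/−`between_strength` so the
implied partials are positive (symptom networks are overwhelmingly
positive-dominant; a `negative_fraction` flag flips edges for stress
tests). Positive definiteness is enforced by setting the common
diagonal to 1.05× the spectral requirement, recorded in the truth
object; note this scaling means realized partial correlations are
`strength/diagonal`, smaller for larger, denser clusters.

Latent vectors are drawn from the correlation-scaled inverse of the
precision, shifted additively by covariate effects, and discretized by
per-item increasing thresholds into 1–5. The default 18-item profile
mirrors a five-cluster IBD symptom checklist (abdominal, intestinal,
nutritional, systemic, psychosomatic; sizes 2, 6, 3, 3, 4) with
category-1 probabilities spanning ~0.26–0.94, giving the strongly
right-skewed marginals typical of such instruments (item means roughly
1.1–2.6). Remaining category mass decays geometrically (decay 0.5).
Covariates emulate a realistic cohort: binary active stage (prevalence
0.58), log-normal years since diagnosis (mean 5.36, SD 5.77), and a
4-level treatment factor (reference: medication; probabilities 0.543,
0.049, 0.247, 0.16). Default latent effects — +0.4 SD for active stage,
+0.02 SD per year, +0.3 SD for "otherwise" treatment, uniform across
items — are modest shifts chosen once to make the covariate screen
meaningful at cohort scale without dominating the correlation
structure.

What the generator does *not* emulate: item-specific measurement error,
informative missingness (the pipeline is complete-case by contract),
differential item functioning across subgroups, longitudinal dynamics,
and any particular real cohort's exact marginal means. Passing tests
therefore demonstrate that the pipeline recovers the structures this
mechanism produces — not that any specific clinical dataset satisfies
the model's assumptions.

A property worth knowing when interpreting recovery tests: the
discretized data's population Spearman matrix is a distorted image of
the latent correlations (the tests verify the distortion against
numerical double integration of the copula), so the "true" precision of
the observed scale is not exactly sparse. EBIC-selected glasso also
genuinely trades shrinkage bias against edge count: with dense blocks of
strong partials it admits weak extra edges at large n. The recovery
tests therefore use a genuinely sparse truth — five 2-item clusters at
p = 10, the scaled-down analog of the five-cluster instrument — where
support recovery is clean (sensitivity ≥ 0.8, false-positive rate
≤ 0.1 at n = 2000).

## Problem sizes and numerical choices

Test and acceptance runs are sized for a single CPU: bootstrap suites
use 25–250 replicates and the CS grid 40–100 subsamples per proportion
(the package defaults remain 1000 and 250); recovery and stability
checks use p = 10, n = 2000; calibration uses 15–25 replicate datasets
of n = 500 with 150–200 bootstrap draws each. The full synthetic-cohort
pipeline in `scripts/acceptance.R` (n = 324, 18 items, 250 bootstrap
replicates, 50 subsamples per drop proportion) completes in about two
minutes.

Other conventions, stated once: quantiles are type 7 (linear
interpolation); symptom "presence" for descriptive prevalence is a
rating ≥ 2; solver tolerance defaults to 1e−4 on the working covariance
(self-consistent with 1e−6 to ≤ 1e−3 on all weights); edge lists are
written lexicographically by node index with full precision
(round-trips to 1e−12); JSON reports carry seed and configuration and
no timestamps, so identical inputs give byte-identical files.

## Limitations

Cross-sectional partial-correlation networks say nothing about
within-person dynamics or causal direction. Ordinal ratings are treated
as numeric in the predictability regressions. The covariate screen is a
single-stage p-value filter; it inherits the usual instability of
selection near the threshold. CS coefficients are bounded above by the
largest feasible drop proportion (0.75), so "CS = 0.75" means "stable
over the whole tested range", not unbounded stability. The graphical
lasso assumes a meaningful Gaussian copula for the ratings; heavily
degenerate items (near-constant) can make resampled estimation fail and
are better removed before analysis.
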