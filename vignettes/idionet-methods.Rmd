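---
title: "Person-specific symptom networks from EMA time series: models and methods"
author: "idionet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-specific symptom networks from EMA time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idionet)
```

## The problem

Acute concussion symptoms fluctuate within a person: most recover along a
linear or curvilinear trajectory over days to weeks, and many also move with
the time of day (arousal, activity, sleep pressure). When symptoms are
sampled intensively — here, Likert ratings of post-concussion symptoms
(0 "not at all" to 6 "extremely") prompted about five times per day for
about twenty days — the resulting series are *nonstationary*: their means
drift. A contemporaneous partial-correlation network estimated on such raw
series confounds genuine symptom-to-symptom coupling with shared temporal
drift, because any two recovering symptoms co-vary through time alone.

`idionet` fits *idiographic* (one person at a time) symptom networks while
accounting for this nonstationarity in two parallel ways, so that the two
analyses cross-validate each other:

1. **Temporal-embedded network** ("raw" network). Seven temporal predictors
   join the endorsed symptoms as nodes of a single regularized Gaussian
   graphical model. Because an edge in a partial-correlation network is
   conditioned on all other nodes, every symptom–symptom edge is thereby
   conditioned on time, and symptom–temporal edges display each symptom's
   trend and cycle structure.
2. **Detrended residual network.** Each symptom is first regressed on an
   L1-selected subset of the temporal predictors; the residuals —
   operationally, the stationary part of each series — then form a
   symptoms-only network.

## The temporal basis

Seven columns encode the temporal structure:

- `trend_linear`, `trend_quadratic`, `trend_cubic`: powers *t*, *t²*, *t³*
  of elapsed time, to capture monotone or undulating recovery (or
  exacerbation) over the study window;
- `sin24`, `cos24`, `sin12`, `cos12`: sine and cosine at 24-hour
  (circadian) and 12-hour (ultradian) periods, evaluated at clock time of
  day. Carrying *both* the sine and cosine of each frequency leaves the
  cycle's amplitude and phase free: a cycle peaking at any time of day lies
  in the span of the pair, so fits are invariant to how the clock is
  anchored (verified to 1e-8 in the test suite).

Two design choices deserve a note, because the axes could have been chosen
otherwise:

- *Trend time is elapsed study time* (hours since the person's first
  prompt), not time since injury: injury clock time is typically unknown,
  and since {*t*, *t²*, *t³*} spans the same space under any affine shift
  of *t*, fitted values and R² are unaffected by the origin.
- *Cycle time is actual clock time*, since diurnal processes are anchored
  to the day; the sine+cosine pair absorbs phase anyway.

All seven columns are standardized (mean 0, SD 1) before any penalized
fitting. This is essential rather than cosmetic: over 20 days the cubic
trend in raw hours reaches ~10⁸ while the sine columns live in [−1, 1], so
a common L1 penalty would be meaningless on the raw scale, and the embedded
correlation matrix would be numerically ill-conditioned. Raw (not
orthogonalized) polynomials are kept so coefficients remain readable as
trend terms; the collinearity among them is tolerated by both the LASSO and
the penalized network estimator (see *Limitations* for the one place it
bites). A column with no variance — every prompt answered at the same clock
time, say — is dropped with a warning rather than scaled to noise.

## Endorsement screening and missingness

Not every person experiences every symptom; a symptom rated 0 nearly
throughout carries no usable covariance. A symptom enters a person's models
only if it has at least 3 non-zero ratings *and* SD ≥ 0.1 rating units
(both configurable). Screened-out symptoms appear as en-dash cells in the
variance-explained grid — distinct from "0.00", which marks an endorsed
symptom for which no temporal predictor was retained.

Unanswered prompts are dropped listwise over the endorsed symptoms before
any model is fitted, so the detrending regressions and both networks see
exactly the same rows. Listwise deletion is the default of the network
tooling this package parallels; with whole prompts (rather than single
items) going missing, it discards little beyond the unanswered prompts
themselves. Missingness is treated as noninformative; modeling informative
missingness is out of scope.

## Detrending: LASSO selection, OLS refit

For each endorsed symptom the series is regressed on the standardized
basis under an L1 penalty (via `glmnet`), minimizing
(1/2n)·‖y − Xβ‖² + λ‖β‖₁ along a log-spaced λ path. λ is chosen by 10-fold
cross-validation at the CV-minimum, with fold assignment drawn from the
model seed so results are exactly reproducible; a contiguous-block CV
variant is available for users worried about autocorrelation leakage, and
if CV degenerates the selection falls back to BIC with a warning. Any
subset of the seven columns may be retained — no hierarchy is imposed
between trends and cycles, so a purely cyclic symptom is representable.

The retained set is then refit by ordinary least squares, and that refit
defines both the reported R² and the residuals. Reporting the *post-
selection OLS* R² (not the penalized fit's) matches the convention that a
symptom with an empty retained set is an exact "0.00": intercept-only
model, R² = 0, residuals = the centered series. Residuals are exactly
mean-zero and orthogonal to every retained column (asserted at 1e-10 and
1e-8 in the tests). No standard errors or post-selection inference are
attached to the regression coefficients; the regressions are a variance
decomposition and a residualizer, not a hypothesis test.

Simulation calibration (pilot oracle runs, frozen in the test suite): with
100 prompts and a single true linear-trend predictor, the true predictor is
retained in ≈100% of replicates at population R² = 0.6 and ≈95% at 0.3;
mean estimated R² is within 0.03 of truth. Under a pure-noise series the
retained set is empty in ≈70% of replicates, each noise column is retained
with probability ≈0.12, and the spurious R² averages ≈0.02. CV-minimum is
deliberately liberal; the `1se` rule is available where a sparser
decomposition is preferred.

## Network estimation: graphical lasso with EBIC

Both network types are Gaussian graphical models estimated from the
Pearson correlation matrix S (Spearman available; residuals are continuous,
and raw Likert ratings are treated as numeric — polychoric correlations are
not implemented). The estimator maximizes

log det Θ − tr(SΘ) − λ·Σ_{i≠j} |θ_ij|,

over positive-definite precision matrices Θ, with the diagonal unpenalized
— the graphical lasso. The solver (in C++) is the standard block coordinate
descent: each column of the working covariance is updated by an L1
regression subproblem, warm-started along a path of 100 log-spaced
penalties from λ_max (the largest absolute off-diagonal correlation) down
to 0.01·λ_max. At λ = 0 the solution equals S⁻¹ (asserted to 1e-5 against
direct inversion), and the penalized solution was cross-checked against an
independent implementation during development. Per-edge penalty weights
are supported (see below).

The penalty level is selected by the extended Bayesian information
criterion, EBIC = −2ℓ(Θ̂) + E·log n + 4γ·E·log p with E the number of
edges and γ = 0.5 by default (γ = 0 is plain BIC; configurable in [0, 1]).
Edges are reported as partial correlations
w_ij = −θ̂_ij/√(θ̂_ii·θ̂_jj).

EBIC-glasso at γ = 0.5 is deliberately specificity-first. In the package's
calibration runs (chain-structured truth, partial correlations 0.3, 100
latent-scale observations) edge sensitivity is ≈0.4 at specificity ≈0.98,
and a true-null network is returned empty in ≈99% of replicates. Users
should read sparse estimated networks accordingly: absent edges are weak
evidence of absence at this sample size.

Networks with fewer than 3 nodes are estimated but flagged
`uninterpretable`: with two nodes both necessarily show identical
centrality, so no ordering information exists.

### When the embedded network cannot fully clean symptom–symptom edges

One genuine limitation surfaced by the package's own simulations: in the
temporal-embedded network with a *uniform* penalty, the trend columns'
near-perfect mutual correlations (cor(t, t²) ≈ 0.97 over a typical
schedule) produce enormous likelihood gains as λ shrinks, so EBIC selects a
very small penalty. At that penalty, sampling noise in the symptom–symptom
partial correlations (≈n^(−1/2)) survives as weak spurious edges — even
when, in the population, all symptom covariation is carried by time and
the λ = 0 inversion shows exactly zero symptom–symptom partial correlation.
This is a property of the estimator class, not of the solver.

For this reason `embedded_network(..., penalize_temporal = FALSE)` leaves
every edge involving a temporal node unpenalized and puts only the
symptom–symptom block on the penalty path. Conditioning on time is then
unshrunk (as in an unpenalized regression adjustment) and the EBIC choice
governs only the symptom edges. Under a ground truth whose symptoms covary
*only* through shared trends and cycles, this configuration returns zero
symptom–symptom edges in ≥95% of replicates while retaining all
symptom–temporal edges — the behavior the uniform penalty cannot deliver.
The uniform penalty remains the default because it is the convention of the
tooling this package parallels; the flag is the recommended sensitivity
analysis whenever temporal structure is strong.

## Centrality

Strength s_i = Σ_j |w_ij| and one-step expected influence EI_i = Σ_j w_ij
are computed for every node (two-step EI available via `ei_order = 2`).
For all-nonnegative networks the two coincide; sign-flip invariance of
strength (and non-invariance of EI) is property-tested. Rankings break ties
lexicographically by node label so output is deterministic. For embedded
networks a symptom-only sub-ranking is reported alongside the joint
ranking, since temporal and symptom nodes are usually narrated separately.
`compare_centrality()` aligns the symptom nodes shared by the raw and
detrended tables and reports per-symptom centrality deltas, rank shifts and
the Spearman correlation of the two orderings.

## The synthetic-data generator

The raw study data this class of analysis is applied to are typically not
shareable, so validation rests on a generator whose ground truth is known.
`ground_truth()` + `simulate_person()` emulate the acquisition protocol:
5 prompts/day at 3-hour intervals for 20 days (100 scheduled prompts),
three preset schedules starting 08:00/09:00/10:00, a 90-minute response
window (answered prompts get a uniform response delay), and whole prompts
missing i.i.d. with probability 0.27 — matching the study's 73% average
response rate.

The latent process per symptom is a cubic polynomial in rescaled study
time plus 24-h and 12-h sinusoids with free amplitude and phase (phases
drawn uniformly, which exercises the phase-invariance of the basis), plus
a multivariate Gaussian residual whose correlation is governed by a sparse
precision matrix Ω — so the true partial-correlation network is known by
construction, and `target_r2` rescales each symptom's deterministic signal
so the population share of temporal variance over the realized schedule is
exact. Likert measurement cuts each latent series into 7 bins at
equal-probability thresholds of its marginal, shifted upward by 0.25
marginal SDs so that 0 is the modal floor category for weak symptoms —
reproducing the floor effects that make real "insufficient variance" cells
appear. Non-endorsed symptoms rate 0 throughout.

The default 10-person cohort (`default_cohort_truths()`) is heterogeneous
by design: persons differ in endorsement (2 to 18 symptoms), temporal R²
profiles (0 to 0.6), and residual structure. Person 5 endorses only
headache and fatigue, so its detrended-network centrality is
uninterpretable; person 7 has identity residual precision with strong
shared trends and cycles, so its detrended network should be (and in the
tests is) empty. Residual networks are chains (partial correlation 0.3 or
0.45) or banded structures (0.32/0.16 to first/second neighbors); the
stronger values were chosen so that, at ~73 complete prompts under Likert
measurement, roughly half the cohort retains detectable residual structure
and the other half comes out sparse — the qualitative split the method is
meant to reveal. Weak-chain persons sit deliberately near the estimator's
detection floor.

What the generator does *not* emulate: informative (e.g.
severity-dependent) missingness, within-day autocorrelation beyond the
modeled cycles, regime switches such as setbacks or medication changes,
item-level (rather than prompt-level) skipping, and ordinal measurement
distortions beyond thresholding (no response styles). Passing recovery
tests on these simulations therefore demonstrates internal consistency of
the estimation chain under the model's own assumptions, not robustness to
every feature of field EMA data.

## Numerical and reproducibility choices

- Solver tolerances: glasso convergence at 1e-4 of the mean absolute
  off-diagonal of S (1e-7 where exactness is asserted); inner coordinate
  descent at a tenth of that. The EBIC path length (100) and floor
  (0.01·λ_max) follow common practice and are configurable.
- A non-PSD input correlation matrix (possible when n < p, which the
  embedded network can approach for a person with many endorsed symptoms
  and many missed prompts) is repaired by eigenvalue clipping with a
  warning; estimation proceeds because the penalty regularizes.
- All randomness — CV folds, simulations, cohort seeds — derives from one
  master seed per fit (`idionet_control(seed = )`); per-symptom and
  per-person sub-seeds are drawn deterministically from it, so rerunning a
  bundle is byte-identical (the pipeline manifest hashes every artifact).
- Ties in rankings break lexicographically; table averages exclude
  not-endorsed cells while counting "0.00" cells as zero, exactly as the
  grid conventions state.
- Simulation problem sizes used in the shipped tests (100–200 replicates
  per cell, n = 100 prompts, p = 8 for structure recovery) were chosen as
  the smallest designs whose Monte-Carlo error is comfortably below the
  margins of the frozen thresholds.

## A worked example

```{r example, eval = FALSE}
library(idionet)

# a person with moderate temporal structure and a chain residual network
gt <- ground_truth(
  symptoms = c("Headache", "Fatigue", "Foggy", "Noise"),
  target_r2 = c(0.5, 0.3, 0, 0.4),
  Omega = chain_precision(4, 0.3),
  missing_rate = 0.27
)
ds <- simulate_person(gt, seed = 7)
fit <- idionet(ds)
summary(fit)

coef(fit)              # detrended partial-correlation matrix
residuals(fit)         # stationary symptom variation
plot(fit, network = "raw")

# cohort-level grid
sets <- simulate_cohort(default_cohort_truths(), seed = 101)
res <- analyze_cohort(sets, out_dir = "cohort_out")
res$table
```

## Known limitations

- Contemporaneous networks only: no lagged (vector-autoregressive) edges,
  so directionality is inaccessible and "influence" is a cross-sectional
  notion.
- Pearson correlations on 0–6 Likert ratings understate latent
  associations (the generator's own recovery runs show the attenuation);
  polychoric input is not implemented.
- EBIC-glasso's conservatism at 100 observations means moderate true edges
  (partial correlation ≈0.3) are detected less than half the time; absent
  edges should not be read as evidence of absence.
- Post-selection OLS R² is mildly optimistic under the null (≈+0.02 at 100
  prompts) because selection and fit reuse the same data.
- The uniform-penalty embedded network can retain weak spurious
  symptom–symptom edges when temporal structure is strong (see above); use
  `penalize_temporal = FALSE` as the sensitivity check.
- No edge-stability bootstrapping or centrality confidence intervals;
  single-person estimates at this sampling intensity are exploratory.
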