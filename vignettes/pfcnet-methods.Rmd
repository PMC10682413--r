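---
title: "Models and methods behind pfcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pfcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pfcnet re-implements, as a reusable and fully tested pipeline, a family of
analyses used to ask how whole-body exposure to simulated galactic cosmic
radiation (GCR) reorganizes prefrontal-cortex (PFC) neurotransmitter
signalling and behavior in mice. Three treatment groups are compared: an
unirradiated control group, an acute group (40 cGy in a single session) and
a chronic group (49.9 cGy spread over 24 exposure days, i.e.
`dose_rate_cgy_per_day()` = 2.08 cGy/day). The measured endpoints are
behavioral-economic demand, titrated psychomotor vigilance, and K+-evoked
microdialysis concentrations of five PFC neurotransmitters (DA, 5-HT, NE,
Glu, GABA), from which correlation networks, directed iRF-LOOP networks and
pairwise Granger causality maps are derived.

Because the underlying animal dataset is not public, the package ships a
synthetic-cohort generator that emulates the statistical structure every
downstream stage assumes. The generator is first-class, tested code: all
design-shape checks, calibration experiments and recovery experiments in
`tests/` and `scripts/acceptance.R` run against it.

## The synthetic dialysate model

Each subject contributes one microdialysis session: four 20-min samples per
perfusate block at 4, 30, 60 and 120 mM K+, 16 samples in all. The last
baseline sample is taken as t = 0, so the analyzed time course has 13
points (t = 0 to 240 min). This convention reproduces the error degrees of
freedom of the reported time-course ANOVA (error df 325 with n = 10/10/8
subjects), which is only consistent with 13 retained points.

A concentration is generated as

```
conc(t) = basal * fold * response(t) * subject_effect * noise(t)
```

* `basal` is the control-scale basal level (defaults: DA 0.8 nM, 5-HT
  0.6 nM, NE 1 nM, Glu 1500 nM, GABA 40 nM — the order of magnitude seen in
  rodent PFC dialysate, with Glu far above the monoamines).
* `fold` is the group's basal fold-change versus control. Defaults encode
  the printed contrasts: DA 2.71 (acute) and 2.14 (chronic), 5-HT 1.75 and
  1.96, NE 1.60 (chronic), plus NE and Glu acute/chronic separations of
  2.19- and 1.45-fold.
* `response(t)` is a per-block gamma-shaped kernel with unit baseline,
  peak amplitude expressed as percent of basal, a peak latency and an
  exponential decay rate. An amplitude of 0 (or 100) encodes an abolished
  (absent) response — the DA signature of both exposed groups — and
  amplitudes below 100 encode dips (the control Glu dip to ~53% under
  30-60 mM). Kernels are supported within their own 80-min block: the
  printed time courses return to baseline before each next switch, and
  block-local support lets block-wise cumulative targets be calibrated
  exactly.
* `subject_effect` is a mean-one lognormal random effect on the basal
  level (default SD 0.2 on the log scale), and `noise(t)` is mean-one
  multiplicative lognormal measurement noise with a configurable
  coefficient of variation (default 0.25, a typical replicate CV for
  LC-MS/MS dialysate quantification).

One deliberate calibration deserves mention. The printed control DA peaks
under 60-120 mM (~259-293% of basal) and the printed chronic/control
cumulative DA fold at 120 mM (1.69) cannot both hold in a noiseless
generator whose kernel peaks on the 20-min sampling grid: a peak of ~260%
at a sampled time forces the cumulative control response so high that the
fold cannot exceed ~1.5. The package resolves the tension in favour of the
cumulative fold, which its own tests assert exactly: the control DA 120 mM
amplitude is solved at profile-construction time so the noiseless
chronic/control cumulative ratio is exactly 1.69 (giving a ~148% peak).
All six printed fold-changes (2.71, 2.14, 1.75, 1.96, 1.60, 1.69) are then
recovered to machine precision by `compare_cumulative()` on the noiseless
default cohort.

### Cross-neurotransmitter coupling

Interactions between transmitters are induced through the innovation terms
of the noise: per subject, the five log-noise series follow a lag-1 vector
autoregression `e_t = C e_{t-1} + eta_t` whose matrix `C` is group
specific (row = target). Stationarity (spectral radius < 1) is enforced at
construction. The control matrix is near-diagonal with a reciprocal
Glu-GABA term; the acute matrix adds GABA->DA and monoamine couplings; the
chronic matrix makes GABA and NE drive DA. These defaults emulate the
*qualitative* reorganization reported for the study groups — they are
plumbing for the correlation, iRF and causality structure, not estimates
of physiology.

Because a lag-1 coupling leaves both a contemporaneous association (for
correlation and iRF analyses of within-block samples) and a predictive
lag structure (for Granger tests), one mechanism serves all three network
stages. Series are mean-corrected and variance-normalized from the exact
stationary covariance, so the noise CV contract (`empirical CV ->
noise_cv`) holds for uncoupled series and the sample mean converges to the
basal level in all cases.

### Designed recovery fixtures

`designed_coupling()` exposes three single-mechanism layouts used by the
validation suite; their strengths were fixed by an a-priori power analysis
at the study's sample sizes and then frozen:

* `glu_gaba` (reciprocal 0.8): with n = 10 control subjects the 4 mM
  Glu-GABA correlation edge (r >= 0.5 and p < 0.05) is recovered in ~96%
  of cohorts. A stricter "exactly one edge" check is only meaningful at a
  larger n: with 9 null pairs, the family-wise false-edge probability at
  n = 10 is ~20%, so the exactness test runs at n = 30 where it is ~2%.
* `da_ne` (DA -> NE 0.9 with DA autocorrelation 0.8): powered through the
  actual `irf_loop()` pathway (80/20 split) rather than a fit on all rows,
  which costs a few percent of recovery.
* `chronic_da_drivers` (GABA -> DA and NE -> DA at 1.6, source
  autocorrelation 0.6): with only 16 time points per subject the pairwise
  Granger test is weak, and the pairwise test of one driver treats the
  other as residual noise, so per-subject power saturates with coupling
  strength; couplings this strong are needed for the median over 8
  subjects to fall below 0.05 in >= 80% of cohorts.

## Economic demand

Consumption Q at price C (fixed-ratio requirement, ladder 2/5/10/30/50) is
modelled by the exponential demand equation

```
log10 Q = log10 Q0 + k * (exp(-alpha * Q0 * C) - 1)
```

with demand intensity Q0, elasticity rate alpha, essential value 1/alpha
and range constant k (log10 units). Fitting is nonlinear least squares on
`log10(Q + 0.1)`; the 0.1 offset keeps zero consumption representable, and
the model prediction receives the same offset so that exact model data are
fit with zero residual (without this, the offset alone would bias every
noiseless fit). Curves that are zero at every price cannot be represented
and are rejected with a diagnostic status.

`k` is treated as a single constant per dataset: either estimated jointly
("shared", the default, by profiling the summed curve SS over k) or fixed
by the caller. Per-curve k is deliberately not offered — k and alpha trade
off along a ridge, and per-curve k makes essential values incomparable
across curves. The optimizer exploits the fact that for fixed decay
`b = alpha * Q0` the un-offset model is linear in log10 Q0: a closed-form
profile over a log-spaced b grid locates the basin and a BFGS polish on
(log Q0, log alpha) finishes, with two fallback starts at
alpha = 1e-3 and 1e-2. Convergence is to a relative objective tolerance of
1e-14; on noiseless model data parameters are recovered to better than
1e-6 relative error with R^2 = 1.

Standard errors follow the regression convention
`SE_i = sqrt((SS/DF) * Cov_ii)` with `Cov` the inverse Gram matrix of the
analytic Jacobian at the optimum and `DF = n_points - 2` free parameters
per curve (a shared k is treated as a constant at the curve level).

The synthetic demand generator draws Q0 and essential value per subject as
mean-one lognormal perturbations (SD 0.15) of concentration-level means
(Q0 = 100/130/170/220 and alpha = 3.0/2.2/1.6/1.2 x 1e-4 for 0/5/20/50%
milk), with Poisson count noise around the model prediction. The means
rise (Q0) and fall (alpha) with milk concentration so essential value is
monotone in concentration, as in the study; their absolute scale was
chosen so that single-curve fits are usefully identified — at much smaller
consumption scales, extrapolating Q0 to zero price from a 5-point count
curve is intrinsically poor, a limitation of the design worth remembering
with real data. Under these defaults, fits on 200 cohorts recover alpha
with ~9% and Q0 with ~9% median relative error.

## Titrating psychomotor vigilance

The task engine implements the staircase exactly: 48 trials per session; a
response within the current stimulus-duration limit is a hit and the limit
drops 0.25 s, a miss raises it 0.25 s; the limit is floored at 0.25 s, has
no ceiling, starts at 10 s on a subject's first-ever trial and carries
over between sessions. The session metric — titrated reaction time —
averages hit reaction times with the full limit on miss trials.

A one-up/one-down staircase tracks the latency level with ~50% hit
probability, so the limit hovers near the median of the agent's latency
distribution (shifted upward by lapses); the property suite asserts the
long-run limit stays within the P40-P90 band of the latency distribution.

Simulated agents have a session-level latent mean RT
`asymptote + (initial - asymptote) * exp(-session / tau)`, lognormal
trial-to-trial variation, and a per-trial lapse probability producing no
response within any finite limit (indistinguishable from a slow miss, as
in the real task). Defaults: controls approach 2.5 s (tau 2.5 sessions,
lapse 3%), exposed groups approach 3.5 s more slowly (tau 5, lapse 6%),
yielding the ~1 s late-session separation reported for the exposed
cohorts.

## Microdialysis summaries and statistics

Basal level is the mean of the four 4 mM samples; cumulative level is the
sum of a block's four samples (the mean is available as a sensitivity
switch); percent-basal series divide each retained sample by the basal
level, dropping (with a diagnostic) series whose basal is zero.

Group statistics mirror the study's choices: unpaired two-tailed t tests
with pooled variance (Welch available but off by default) per
neurotransmitter and K+ level, with fold change as the ratio of group
means; two-way fixed-effects ANOVAs (treatment x time, or treatment x
concentration for behavior) with subjects as replicates and Tukey HSD
post-hocs; no multiplicity correction across neurotransmitters. Unbalanced
layouts are computed with sequential (Type I) sums of squares and flagged
via an attribute. Degenerate inputs use explicit conventions: zero
variance in both groups with equal means gives t = 0 and p = 1; constant
responses give F = 0 with a zero-variance flag; saturated designs (one
replicate per cell) report zero residual df rather than failing.

## Correlation networks

Pearson product-moment correlations are computed across subjects from
per-subject cumulative levels, separately per group and K+ level (10
pairs from 5 nodes), with two-tailed p-values from the exact t transform
on n - 2 df. An edge is retained iff signed r >= 0.5 *and* p < 0.05; the
threshold applies to signed r, so strong negative correlations never form
edges (the looser |r| variant would change the networks; the signed rule
is the stated one). Distributions of the 10 r values are compared across
the three groups by one-way ANOVA (df 2, 27) with Tukey HSD.

## iRF-LOOP directed networks

For each target neurotransmitter, an iterative random forest regresses the
target on the other four transmitters over the per-sample rows of one
group x K+ block (4 samples x n subjects; per-subject cumulative rows are
statistically vacuous for an 80/20 split at n = 8-10). Iteration 1 is a
plain impurity-importance forest; each later iteration re-fits with
per-split candidate-feature sampling weighted by the previous iteration's
normalized importances (ranger's split-select weights), concentrating the
forest on informative features. Defaults: 500 trees, 5 iterations, 80/20
train/test split, seeded and single-threaded for exact reproducibility.

Per-target importances are normalized to sum to 1 over the four sources;
edges at or above 0.2 are retained. Note a structural consequence of that
threshold: a target with *no* informative source has all four importances
near the balanced value of 0.25, so its edges are retained — balanced
connections are depicted by design, and only dominance (one source
absorbing most of the mass) pushes competitors below threshold. Held-out
R^2 per target is recorded as metadata and never used to filter edges.
Edge signs come from the univariate OLS slope of target on source over the
block's rows (zero slope or constant source flags the edge). Difference
networks take edge-wise absolute importance differences between two
groups at the same K+ level, treating absent edges as 0. Three groups x
four K+ levels yield the 12 directed networks; bidirectional relationships
are simply two directed edges.

## Pairwise Granger causality

Per subject, each ordered pair of the five 16-sample concentration series
(all blocks concatenated in time order) is tested with the nested-OLS F
statistic: for lag m in 1..3, the restricted model regresses the target on
an intercept and m own lags, the unrestricted model adds m lags of the
candidate cause, both on the common T - m rows, giving
`F = ((SSR_r - SSR_u)/m) / (SSR_u/(T_eff - 2m - 1))`. With T = 16 and
m = 3 the denominator df is 6 — short series are the regime this analysis
must live with, and the minimum-length precondition guards the df. Since
only a maximum lag is specified for the test, per-lag p-values are
reported and aggregated by their minimum over lags 1..3 (a "lag-3 only"
mode is provided). Per group and ordered pair, the distribution of
per-subject aggregated p-values is summarized by median and quartiles,
with the causal decision `median p < 0.05` and the eight DA-centric
families flagged. No multiplicity correction is applied across the 20
ordered pairs. The suite verifies exact agreement with an independent
implementation (`lmtest::grangertest`) per lag, type-I calibration at the
5% level on white noise, and affine invariance.

Pairwise (rather than conditional) Granger testing detects indirect
paths: if A drives B and B drives C, A will often "cause" C. The designed
chronic fixture therefore couples only the two intended drivers to DA, so
the clean Glu -> DA negative control is meaningful.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` chains simulate -> neurochem -> {corrnet, irfnet,
granger} plus demand and vigilance, writes tidy CSV/JSON artifacts and a
manifest with the package version, seed, thresholds, per-stage status and
MD5 of every output. All randomness derives from the single configured
seed (forests are seeded per block; stage seeds are fixed offsets), no
output embeds a timestamp, and reruns with the same seed are byte
identical — asserted file-by-file in the suite.

Problem sizes in the shipped tests and acceptance script are the study's
own: cohorts of 10/10/8 subjects (16 samples x 5 transmitters), 8 subjects
per group for behavior, 15 vigilance sessions, 200 simulated demand
cohorts for the recovery study, 2,000 null replicates for Granger
calibration and 100 cohorts per designed-recovery experiment.

## What passing tests do and do not show

The generator emulates the *structure* the analyses assume — sampling
grid, group means, multiplicative noise, lag-1 coupling — not the
physiology behind it: there is no potassium diffusion, probe recovery,
vesicular release or radiation-physics model, responses are smooth
kernels, and innovations are Gaussian on the log scale. Passing recovery
tests therefore show that the implementations detect the structures they
claim to detect at the study's sample sizes; they do not validate the
biological conclusions, and headline F statistics computed on synthetic
cohorts will generally be far larger than on real animals because the
generator's group separation is clean. Known limitations worth restating:
Q0 is poorly identified from 5-point count curves at low consumption
scales; Granger tests on 16-point series have low power and detect
indirect paths; and the 0.2 iRF threshold intentionally keeps balanced
(uninformative) connections visible.
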