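---
title: "Population decoding of spatial working memory: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population decoding of spatial working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wmdecode)
```

wmdecode analyzes spiking populations recorded while a subject holds one
of nine grid-arranged target locations in working memory across a delay,
under a drug-injection design that splits each session into pre,
early-post (injection to 30 min) and late-post (30–60 min) periods.
This vignette explains the statistical models the package implements,
the parameters that matter and their defaults, what the synthetic
session generator does and does not emulate, and the numerical decisions
taken where the design was genuinely open. It states no empirical result
beyond what the package's own tests and `scripts/acceptance.R` compute.

## The session contract

A session is a set of tidy tables (trials, units, spikes, gaze,
trajectories) plus metadata. Times are milliseconds from session start
and every epoch window is half-open `[on, off)`: the cue epoch spans
3000 ms, the delay 2000 ms, and the response epoch is analyzed over its
first 2000 ms. A single time convention avoids off-by-one binning when
counting spikes at epoch boundaries.

On disk a session is a directory of CSV tables with a `session.json`
sidecar, written and read by `write_session()` / `read_session()`.
Columnar text tables are what every stage consumes, they diff cleanly,
and round-trip exactly; a hierarchical binary container would add a
dependency without changing any analysis.

Trials are assigned to injection periods by their start (cue onset)
time: a trial that begins before the 30-minute boundary belongs to the
early-post period even if it ends after it. The boundary rule is a
package decision — any crossing trial has most of its epochs on the side
where it started.

## Spatial tuning

Per-trial epoch rates are spike counts over the epoch window divided by
its duration. Selectivity is a one-way fixed-effects ANOVA of rate on
target location, the classical F-test, run per unit and period. Because
injection periods can contain different numbers of trials, each
location is subsampled without replacement to the unit's minimum
per-period-per-location count; the test is repeated 50 times and the
median p-value kept. When counts are already equal the subsample is the
full data and the procedure reduces to the plain ANOVA — a property the
test suite asserts. Two significance levels coexist deliberately: 0.05
for the tuning census and 0.1 for including units in the cell-type
contrast analyses; both are explicit arguments.

The preferred location is the location with the largest full-data mean
rate (least-preferred the smallest); ties break toward the lowest
location index and are flagged. Ranked-tuning curves sort each unit's
nine location means from preferred to least preferred per period; the
session-average curve is fit by least squares against rank, and a
slope nearer zero indicates flattened tuning. Per-unit curves are
normalized by the unit's maximum mean rate across its periods before
averaging, so high-rate units do not dominate the session average while
cross-period amplitude changes remain visible; normalization can be
switched off.

Spike density functions convolve spike times with a Gaussian kernel
(SD 150 ms). The kernel is not renormalized at window edges, so the
first and last few hundred milliseconds of a trace are biased low;
integrals over interior windows conserve spike count to within 0.1%.
The polynomial surface `f(x,y) = p00 + p10 x + p01 y + p20 x² + p02 y²
+ p11 xy` is fit to the nine location means by least squares (six
coefficients, nine equations) and used for display only.

## Ensemble decoding

Target direction is decoded from z-scored per-trial spike counts with a
linear support vector machine and stratified five-fold cross-validation.
The nine locations are pooled by grid column into left/center/right —
depth is pooled because responses to same-direction targets are more
similar than to same-depth targets — giving a 33% chance level; a
9-class variant with four-fold cross-validation exists for sessions with
enough trials. Classes are balanced by subsampling without replacement,
repeated 20 times, and accuracy averaged.

Normalization parameters (feature means and SDs) and the SVM penalty are
estimated on training folds only; the penalty is selected by an inner
three-fold search over `C ∈ {0.01, 0.1, 1, 10, 100}`, ties toward the
smaller penalty. A label-permutation audit in the test suite verifies
that shuffled labels never decode above chance — the signature of
leakage. Multiclass reduction is libsvm's one-vs-one.

Ensembles are grown greedily: the best single unit, then the best pair
containing it, and so on to 16 units, where accuracy plateaus.
Ties break toward the lowest unit id. Greedy selection is performed on
pre-period data and the ensemble held fixed across periods by default
(per-period selection is available): holding membership fixed makes the
period comparison a statement about the same neurons. Chance is
estimated by re-running the full procedure on label-shuffled data (10
shuffles × 20 balancing subsamples); a session whose shuffled accuracy
is significantly above the binomial chance band is flagged for
exclusion.

## Population signal and projected precision

For a binary left-vs-right contrast on an ensemble of N units, let `Δf`
be the vector of per-unit mean-rate differences between the classes and
`Σ` the within-class covariance of trial rates. The package decomposes
decodability as

- `PS = |Δf|` — population signal, the tuning term;
- `PP = sqrt(Σᵢ cos²θ̂ᵢ / σ̂ᵢ²)` — projected precision, where `θ̂ᵢ` is the
  angle between the i-th eigenvector of `Σ` and the signal direction
  `u = Δf/|Δf|`, and `σ̂ᵢ²` the i-th eigenvalue; algebraically
  `PP² = u'Σ⁻¹u`, the inverse variance of the population response
  projected on the signal direction;
- `DPt = Φ(½ · PS · PP)` — the accuracy of the optimal linear readout of
  two equal-covariance Gaussian classes with these moments, with `Φ`
  read as the standard normal CDF applied to the discriminability
  argument.

`DPt` is invariant to unit permutation and to global rate rescaling
(`PS` scales by c, `PP` by 1/c); it equals 0.5 exactly when `PS = 0`,
in which case the signal direction is undefined and `PP` is reported as
not applicable. The squared cosines sum to one over the orthonormal
eigenbasis — asserted to 1e-10 in the tests — and `PP²` is bracketed by
the inverse extreme eigenvalues.

The empirical counterpart `DPe` is five-fold cross-validated linear
discriminant accuracy. The covariance estimator is the pooled
within-class sample covariance with its off-diagonal entries shrunk
toward zero by an analytic weight (the ratio of the summed estimation
variances of the off-diagonal entries to their summed squares, clamped
to [0, 1]) — a Schäfer–Strimmer-style rule that needs no inner
cross-validation. The same regularized `Σ` feeds both the discriminant
and `PP`, and class means are computed on the same balanced subsample as
the covariance, so `DPe` and `DPt` are plug-in estimates of the same
moments and directly comparable. Two small opposite biases remain
inherent to the estimators: cross-validation trains on 80% of trials
(pessimistic), while plug-in `|Δf|` and `Σ̂⁻¹` are slightly optimistic;
at a few hundred trials both are of order 10⁻³ in accuracy.

Random-ensemble sweeps draw ensembles of sizes 2, 3 and 5 (without
replacement within an ensemble; duplicates de-duplicated, and the whole
combinatorial space enumerated when it is smaller than the requested
count) from units with mean rate above 0.5 Hz, excluding center-column
trials. Top ensembles are those at or above the 75th percentile of
`DPe`, computed per period by default (a pre-frozen variant exists):
per-period selection asks "how good is the best code available in this
period", which is the relevant question when the code itself degrades.

## Waveform classification

Mean waveforms are upsampled ×100 with a cubic spline and the width
taken as the absolute time between the global voltage minimum and
maximum. Waveforms without both a positive and a negative deflection are
excluded, as are widths above 675 µs. The pooled width distribution is
fit with one Gaussian and with a two-component Gaussian mixture (maximum
likelihood; unequal variances) and the winner chosen by AIC. When the
mixture wins, the narrow/broad boundary is placed at the crossing of the
two weighted component densities between the means — the valley of the
fitted bimodal density, solved in closed form from the quadratic in the
log-densities. Widths exactly at the boundary go to the broad class.
Classification depends only on extremum times, so it is invariant to
affine voltage scaling. The mixture needs at least 50 widths; single
sessions with fewer units should pool widths across sessions and pass
the pooled fit to `classify_waveforms()`.

## Behavior, trajectories and gaze

Percent correct is compared to the 1/9 chance of guessing one of nine
targets with an exact one-sided binomial test; a 15-bin per-period time
course is available. Response time is the navigation-onset-to-trial-end
duration on correct trials; the SEM of a single trial is reported as 0
and flagged rather than propagating NaN.

Trajectories are scored on a 5×5 grid sized to tightly enclose the
targets (the bounding box of the nine targets padded by half the target
spacing). A cell is entered if any path point falls inside it, with the
path densified between samples (steps of at most 1/50 of a cell) so
sampling density cannot miss a crossing; entering a cell once or many
times scores 1. Only trials crossing the configurable start-enclave
line are included. A full session yields 25 cells × 9 conditions = 225
percentages, and between-period difference maps keep increases only.

Gaze analyses consume pre-labeled fixations and saccades — eye-movement
classification is upstream of this package. Fixations shorter than 6 ms
are discarded. The on-target window is one cell of the 16-cell screen
grid centered on the target's screen projection, tying the two gaze
analyses to a single spatial scale. Eye-position controls include
decoding target location from 16-cell fixation-count maps (matched in
feature count to a 16-unit neural ensemble), decoding gaze region from
neural activity during fixations (four regions around the well-separated
corner targets; sessions missing a region are excluded), and
Kruskal–Wallis saccade tuning in retinocentric vs spatiocentric frames
over 2×2 quadrants of a 40°×30° field, with bins power-matched across
frames by rank-pairing and random downsampling, requiring at least ten
saccades per bin and three acceptable bins.

## The synthetic generator

`generate_session()` emulates the statistical structure the analyses
assume, with ground truth emitted alongside and never read by any
analysis stage.

Tuning curves are 2-D Gaussian bumps over the grid coordinates
(default peak 12 Hz, baseline 2 Hz, bandwidth one grid spacing of 290
arena units, log-normal amplitude jitter 0.25): a smooth unimodal bump
is the simplest family consistent with plane-fit visualizations of
spatial tuning. Counts are doubly stochastic — expected rate times a
shared per-trial gain `max(0.05, 1 + ρz)`, `z ~ N(0,1)`, conditionally
Poisson or negative binomial (default Fano 1.4) — giving realistic
positive count correlations that grow with ρ (default 0.15).

The drug mode implements the minimal model matching the directional
cell-type effects: in the early post-injection period, narrow-spiking
units' tuning amplitude is multiplied by `g_NS = 0.5` (suppressing
preferred-location firing) and broad-spiking units gain
`δ_BS = 4 Hz × (1 − kernel)` (raising least-preferred-location firing);
both flatten tuning, reduce the population signal and degrade decoding.
Half the effect remains in the late post-injection period. Behavioral
defaults are a correct probability of 0.9/0.65/0.85 and trajectory
dispersions of 30/80/45 arena units across pre/early/late; navigation
slows from 3.0 to 4.0 s. No quantitative effect sizes exist to copy
for any of these — only directions and significance — so the defaults
are calibration choices picked once to be physiologically plausible and
are labeled as such. Saline and perception modes use period-independent
behavior and no rate perturbation.

Waveform widths are drawn from Gaussians at 220 µs (NS) and 420 µs (BS),
SD 40 µs — chosen so the fitted boundary lands in the high-200s, near
boundaries reported for primate cortex; these are generator choices, not
measurements. Waveforms are biphasic two-Gaussian templates with the
drawn trough-to-peak interval. Fixations arrive at 2/s with an on-target
bias of 0.3 and exponential durations (mean 250 ms); saccades connect
consecutive fixations. Default session size is 32 units (8 NS, 24 BS,
25% multiunits) and 12 trials per location per period — small enough
that a full multi-session analysis runs on a laptop in minutes, large
enough for every test to have power.

What the generator does not emulate: biophysical network dynamics,
temporal spike structure within epochs (rates are epoch-constant),
navigation physics, saccade kinematics, electrode drift, or sorting
errors. Passing tests therefore demonstrate that the analysis chain
measures what it claims on data with known structure — not that real
recordings satisfy that structure.

## Reproducibility and problem sizes

Every stochastic stage takes a seed derived from a master seed by a
polynomial string hash of `(master, stage, repetition)` reduced modulo
2³¹−1 (`derive_seed()`), so any stage can be re-run in isolation.
Identical configurations produce byte-identical result tables, and the
pipeline writes a manifest of stages, parameters and child seeds.

The test suite runs the full chain at deliberately scaled sizes chosen
to keep the default run within minutes: 10 replicate drug sessions of
32 units × 324 trials for the directional effect-recovery checks (greedy
ensembles evaluated with 2 balancing subsamples during selection and a
fixed penalty, 120 random 3-unit ensembles per session), 1000 null units
for type-I calibration, 10⁵ Monte-Carlo draws per configuration for the
theoretical-accuracy oracle, and 2000 widths × 20 seeds for mixture
recovery. The acceptance script reports chance levels from a 540-trial
session with the full 10 × 20 shuffle procedure.

## Known limitations

- The ANOVA assumes homoscedastic rates; spike counts are variance-mean
  coupled, and no transform is applied (the calibration tests show the
  type-I error is nonetheless nominal at moderate rates).
- SDF edges are biased low by up to half the kernel mass; analyses that
  average over epoch interiors are unaffected.
- `DPe` and `DPt` carry small opposite finite-sample biases (see above);
  comparisons between them should use matched trial counts.
- The greedy ensemble path is O(N × max_size) decodes and dominates
  runtime on large populations; fix the penalty and reduce balancing
  repeats during selection when N is in the hundreds.
- Screen geometry defaults (1024×768 px, 45×33.5 cm at 80 cm) enter the
  gaze analyses only through window sizes and the degree conversion;
  supply the true geometry for other rigs.
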