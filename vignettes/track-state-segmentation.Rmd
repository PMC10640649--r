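---
title: "Segmenting particle tracks into random and directed migration"
author: "peroxHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting particle tracks into random and directed migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peroxHMM)
```

## The problem

Organelles such as peroxisomes spend most of their time in a slow, roughly
isotropic "random" migration mode and only occasionally bind to the
microtubule network, where motor proteins pull them along in fast, straight
runs. Those directed runs are rare and short — a handful of frames at a
10 frames/s acquisition rate — so whole-track summaries wash them out:
ensemble mean squared displacement (MSD) curves of populations with and
without functional microtubule transport look essentially identical, and
speed thresholds are arbitrary because the apparent speed depends strongly
on the frame rate (see `downsample()`).

peroxHMM treats mode switching as the object of inference. Each track is
modelled as a two-state hidden Markov chain over its steps — state 1 random,
state 2 directed — and the switching structure (how often a particle binds,
how long it stays bound) becomes a set of fitted parameters that can be
compared between experimental conditions.

## Observables

A track is a sequence of 2-D positions $x_t$ (micrometres) at frame interval
$\Delta t$ (seconds). `compute_observables()` reduces each step to

* the dimensionless instantaneous speed
  $\iota_t = \lVert x_{t+1} - x_t \rVert / (\Delta t \cdot 1\,\mu m/s)$,
  where dividing by a 1 um/s reference makes $\log \iota_t$ well defined;
* the relative turning angle $\alpha_t$, the signed angle between the
  displacement arriving at a vertex and the one leaving it, in degrees on
  $(-180, 180]$.

Step $t$ carries the angle at vertex $t$; the first step of a track has no
angle and contributes through its speed only. A signed, zero-centred support
was chosen (rather than $[0, 360)$) so that both the isotropic and the
peaked angle distribution are natural densities on one support; densities
are per degree. Steps that cross a closed tracking gap use the true elapsed
time (frame difference times $\Delta t$) for the speed, and the two angles
touching a gap are marked absent by default (`gap_angles`), since the
interpolated geometry is not a measurement. Zero-length displacements are
floored at $\iota = 10^{-9}$ to keep the log-normal density finite, and
their adjacent angles are marked absent; absent angles contribute a
likelihood factor of one in both states, which discards no information and
keeps tracks with degenerate steps usable.

## The model

Conditional on the state, speed and angle are independent:

$$p(o_t \mid s_i) = p(\iota_t \mid s_i)\, p(\alpha_t \mid s_i).$$

Speeds are log-normal in both states with state-specific location and scale
$(\mu_{\iota,i}, \sigma_{\iota,i})$ — the mean and sd of $\log \iota$.
Angles are uniform on $(-180, 180]$ in the random state and zero-mean
normal with sd $\sigma_{\alpha,2}$ (degrees) in the directed state. The
normal is truncated to the support and renormalised rather than wrapped;
at the sds encountered in practice (tens of degrees) the truncation
correction is negligible, and the truncated form keeps the density proper
for any sd. A prior $\pi$ and a row-stochastic transition matrix $T$
complete the parameter set (`hmm_params`).

`forward_backward()` implements the scaled recursion (per-step
normalisation of the forward variables plus a per-step offset on the
emission log-densities), so underflow cannot occur at any track length; its
log-likelihood is exact and is checked in the test suite against explicit
enumeration over all state paths on short sequences. `viterbi()` decodes in
log space with ties broken towards the random state — the conservative
choice, since directed migration is the positive call.

## Fitting

`baum_welch()` runs EM with any subset of the parameter groups
`mu_iota`, `sigma_iota`, `sigma_alpha2`, `pi`, `T` frozen. M-steps are the
standard responsibility-weighted estimates; the angle sd uses only steps
that have an angle, weighted by directed-state responsibility.

Two details deserve explanation.

**The meaning of $\pi$.** In this package $\pi$ is reported as the overall
proportion of steps a track spends in each state — the quantity one wants
when comparing conditions. Inside the EM loop, however, the chain's initial
distribution is updated with the textbook initial-responsibility rule,
because that update is the exact maximiser of the EM surrogate and
guarantees a non-decreasing log-likelihood at every iteration (asserted to
$10^{-8}$ in the tests). Substituting the time-averaged occupancy *inside*
the loop — tempting, given the intended interpretation — breaks that
guarantee measurably. So the occupancy is computed from the
responsibilities at convergence and reported as `params$pi`
(`pi_update = "occupancy"`, the default); `pi_update = "initial"` reports
the raw initial-distribution estimate instead, which for a single long
sequence is degenerate (close to 0/1) and rarely useful.

**Identifiability.** The states are relabelled after any fit with free
speed parameters so that state 1 is the slower one. Initialisation is
deterministic — speed locations at the 25th/75th percentiles of
$\log \iota$, both scales at the overall sd of $\log \iota$,
$\sigma_{\alpha,2} = 30^\circ$, $\pi = (0.5, 0.5)$, diagonal-dominant $T$ —
so repeated fits of the same data are identical. Convergence is declared at
$|\Delta \log L| < 10^{-6}$ (at most 500 iterations); scales are floored at
$\sigma_\iota \ge 10^{-3}$ and $\sigma_{\alpha,2} \ge 0.5^\circ$ to keep
the M-step away from point-mass degeneracies when a state's responsibility
mass collapses.

**Two-stage protocol.** For dataset scans, `run_study()` first learns the
emission parameters from a designated set of tracks that visibly mix both
modes (or accepts them ready-made as an `hmm_params`), then freezes the
emissions and fits only $\pi$ and $T$ per track before Viterbi decoding.
Fitting emissions per track and averaging (the default `share =
"per_track"`) was preferred over one pooled fit as the stage-1 default
because it matches the per-track fitting used everywhere else and yields an
across-track dispersion for each parameter; a pooled joint fit is available
with `share = "pooled"`.

## The synthetic-track generator

`simulate_dataset()` produces the validation substrate: tracks that switch
between modes under a first-order Markov chain (defaults
$T_{12} = T_{21} = 0.1$ per step, initial probabilities $0.5/0.5$, 100
tracks of 200 steps at $\Delta t = 1$ s).

* *Random mode* is a discretised Ornstein–Uhlenbeck velocity process
  $v_{t+1} = (1 - \Delta t/\tau)\, v_t + \sqrt{\Delta t}\,
  (\sqrt{2D}/\tau)\, \epsilon_t$ with $\tau = 1.5$ s and $D = 5$ um^2/s,
  positions advancing by $\Delta t\, v_{t+1}$. The initial velocity is
  drawn from the stationary distribution of this update (per-component
  variance $b^2/(1-a^2)$), so tracks have no burn-in transient.
* *Directed mode* draws a speed from normal(10, 1) um/s (negative draws
  rejected), keeps the previous direction of motion, and adds unit normal
  velocity noise per component. On entering directed mode at exactly zero
  velocity the direction is uniform on the circle, since a zero vector has
  no direction.

The generator reproduces the statistical signatures the HMM relies on —
log-normal-ish speed separation and near-zero turning angles during
directed runs — and the empirical checks in the test suite (stationary
velocity variance, switch frequencies, occupancy, directed log-speed
centre) pin its moments to the closed forms. It does **not** emulate
localisation error, motion blur, photophysics, track fragmentation or
confinement, and its $\Delta t = 1$ s is ten times coarser than the
10 frames/s of real acquisitions. Passing validation on simulated tracks
therefore demonstrates that the estimator recovers the generative structure
when the model family is correct; it does not bound performance on real
microscopy data, where emissions are only approximately log-normal/normal.
Each track is generated from its own seeded substream of the root seed, so
single tracks can be replayed exactly.

## MSD analysis

`msd_curve()` computes the ensemble (from-origin) MSD,
$\mathrm{MSD}(t) = \frac{1}{N}\sum_i \lVert x_i(t) - x_i(0)\rVert^2$,
per cell, with tracks contributing to every lag they reach and the per-lag
track count recorded. A time-averaged variant exists behind a flag but is
off by default, since the from-origin form is the one the downstream
exponent summaries assume. `fit_alpha()` fits
$\mathrm{MSD}(t) \sim t^{\alpha}$ as the least-squares slope in log–log
space over a fit range defaulting to 0.1–20 s — lag zero is excluded
because the log fit is undefined there. The fit is unweighted by default;
per-lag counts can be used as weights. Tracks shorter than 50 steps are
filtered out first (`filter_min_steps`), the single length threshold used
across the package; it corresponds to 5 s at 10 frames/s and is
configurable.

## Validation and comparison statistics

`classification_metrics()` scores decoded against ground-truth states with
the directed state as positive. Two F1 conventions are reported:
`f1_standard` = $2PR/(P+R)$ (the default everywhere) and `f1_as_printed` =
$PR/(P+R)$, a variant lacking the factor 2 that appears in some write-ups;
both are carried so that either convention can be compared directly.
Zero-denominator ratios are reported as 0 and flagged rather than NaN.

`perturbation_experiment()` measures the sensitivity of decoding to the
fitted speed locations by adding normal noise to both entries of
$\mu_\iota$ and re-decoding; at noise sd 0 it reproduces the unperturbed F1
exactly (the test suite asserts identity, not approximation).

`run_ratio_curve()` summarises run-length structure: the fraction of tracks
containing at least $k$ consecutive directed steps, with a percentile
bootstrap CI from resampling tracks with replacement (1000 resamples by
default). Tracks, not cells, are the resampling unit, matching the
track-level curves being summarised. `aggregate_per_cell()` averages
per-track $\pi$/$T$ element-wise within cells (plain means — averaging
row-stochastic matrices preserves row sums), and `compare_conditions()`
applies a two-sided two-sample t-test with Bonferroni correction
$q = \min(1, mp)$. Welch's form is the default because per-cell variances
differ between conditions in practice; the classical equal-variance test is
available via `var_equal = TRUE`. The number of comparisons $m$ defaults in
`run_study()` to (condition pairs) × (metrics compared in the run) and is
reported next to each $q$.

## A worked validation run

```{r validation, eval = FALSE}
val <- run_validation(sim_params(), seed = 42)
val$report
val$mean_accuracy
summary(val$model)
```

`run_validation()` is the one-call version of the whole loop: simulate,
fit every track with all groups free, decode, score. The test suite runs
it at the full benchmark size (100 tracks × 200 steps) and asserts the
decoding accuracy, the recovery of the switching probabilities to within
three standard errors, EM monotonicity and the monotone decay of F1 under
emission-parameter noise; `scripts/acceptance.R` re-runs it from scratch
for any seed. Problem sizes in the unit tests are smaller (tens of tracks,
100–150 steps) — enough to pin each property without redundant computation.

## Known limitations

* Exactly two states; regimes like confined diffusion or mixed diffusivity
  classes need a different emission family and are out of scope.
* 2-D tracks only.
* Per-track fits need enough steps in *both* modes to estimate emissions;
  the two-stage protocol exists precisely so that whole-dataset scans do
  not ask every short track to identify its own speed distributions.
* The turning-angle model assumes directed runs are straight on the frame
  timescale; strongly curved transport would widen
  $\sigma_{\alpha,2}$ and weaken the angle's discriminative power.
* No model of localisation error: at very high frame rates apparent speeds
  of immobile particles are dominated by detection noise, which inflates
  the random-state speed distribution.
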