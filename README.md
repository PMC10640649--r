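# peroxHMM

Hidden Markov segmentation of 2-D single-particle tracks into **random**
and **microtubule-directed** migration.

Organelles like peroxisomes mostly jiggle in place (slow, isotropic motion)
and only occasionally bind to microtubules, where motor proteins carry them
in fast, straight runs. These directed events are rare and last only a few
frames, so whole-track summaries — mean squared displacement curves, speed
thresholds — fail to detect them or to distinguish experimental conditions
that alter microtubule transport. peroxHMM segments every track step by
step instead, turning binding frequency and run length into fitted,
comparable parameters. It is aimed at anyone with particle-tracking output
(e.g. TrackMate) who needs per-step motion-state calls and per-condition
switching statistics.

## The model

Each step of a track is reduced to two observables: the dimensionless
instantaneous speed ι_t = ||x_{t+1} − x_t|| / (Δt · 1 µm/s) and the relative
turning angle α_t ∈ (−180°, 180°]. A two-state hidden Markov chain with
per-step transition matrix T and state prior π emits, conditionally
independently given the state s_i,

- speed: ι_t | s_i ~ lognormal(μ_ι,i, σ_ι,i) for both states,
- angle: α_t | s_1 ~ uniform(−180°, 180°] (random state),
  α_t | s_2 ~ normal(0, σ_α,2), truncated to the support (directed state).

Parameters are estimated by scaled Baum–Welch (any parameter group can be
frozen, enabling a two-stage protocol: emissions learned once on
mixed-mode tracks, then π and T fitted per track), states are decoded with
Viterbi, and the expected state speeds follow from the log-normal mean
exp(μ + σ²/2). An Ornstein–Uhlenbeck-based simulator generates
switching-mode tracks with ground-truth states for validation, and helper
modules cover ensemble MSD with anomalous-exponent fits, precision/recall/
F1 validation, consecutive-run statistics with bootstrap CIs, and
per-cell condition comparison with Bonferroni correction.

## Worked example

Simulate 20 switching tracks, fit the full HMM to each, decode, and score
against the generative truth:

```r
library(peroxHMM)

ds    <- simulate_dataset(sim_params(n_tracks = 20), seed = 7)
model <- track_hmm(ds$tracks)
summary(model)
#> Two-state migration HMM: 20 tracks, 4000 steps (per_track fit)
#> <hmm_params>
#>   mu_iota:      [0.9091, 2.2953]
#>   sigma_iota:   [0.6592, 0.1464]
#>   sigma_alpha2: 5.878 deg
#>   pi:           [0.5282, 0.4718]
#>   T:            [[0.8982, 0.1018], [0.1149, 0.8851]]
#>   expected speeds: 3.08 um/s (random), 10.03 um/s (directed)
#>   total log-likelihood: -27046.26 (all fits converged)

pred    <- predict(model, type = "viterbi")
decoded <- split(pred$state, pred$track_id)[names(ds$truth)]
classification_metrics(ds$truth, decoded)
#> <validation_report> TP 1877  FP 13  TN 2099  FN 11
#>   recall 0.9942  precision 0.9931  F1 0.9936 (as-printed 0.4968)
#>   accuracy 0.9940  mean per-track accuracy 0.9940
```

Reading the output: the fitted speed locations `mu_iota` separate a slow
state (mean log-speed ≈ 0.91) from a fast one (≈ 2.30 ≈ ln 10, the
generative directed speed); `sigma_alpha2` ≈ 5.9° says directed runs are
nearly straight; `pi` is the proportion of steps spent in each state and
`T` the per-step switching probabilities (both ≈ 0.1, the generative
value). Decoding recovers the hidden states on ≈ 99% of steps; errors
cluster at state switches.

For real data, read tracks with `read_tracks_csv()` (header
`track_id,frame,x,y[,cell_id,condition]`, positions in µm) or
`read_trackmate_xml()`, then run the two-stage dataset scan:

```r
ts <- read_tracks_csv("tracks.csv", dt = 0.1)
st <- run_study(ts, stage1_ids = mixed_mode_ids)   # or emission_params = ...
st$per_cell          # per-cell mean pi / T
st$run_ratios        # directed-run-length curves with bootstrap CIs
st$comparisons       # condition t-tests with Bonferroni q
```

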