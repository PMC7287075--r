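---
title: "Models and methods behind serialTI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind serialTI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialTI)
```

serialTI implements, end to end, the computational analyses of a serial-order
(transitive inference, TI) experiment: a subject learns the implied ranking
of a 7-item list of images from rewarded pairwise choices while single units
are recorded in posterior parietal cortex. Because such recordings are rarely
deposited, the package is driven by a synthetic-data generator that emulates
the behavioral and neural structure those analyses assume; every analysis is
exercised and validated against that generator. This vignette explains the
models, the tunable parameters, the numerical choices, and what the tests do
and do not establish.

## The task

A list of `n = 7` items carries ranks 1..7 ("A".."G"). Every choice trial
presents two items; choosing the lower-ranked one is rewarded. A pair is
summarized by its **symbolic distance** (SD, difference of ranks, 1..6) and
**joint rank** (JR, sum of ranks, 3..13); the ranks are recoverable from the
two via `rankHigh = (JR + SD)/2`, `rankLow = (JR - SD)/2`
(`decomposeRanks()`). Over the 21 pairs of a 7-item list SD and JR are
numerically uncorrelated, which is what makes them separately decodable.

`buildSessionSchedule()` reproduces the session layout: 5 single-stimulus
blocks of 14 trials (each item once inside and once outside the recorded
cell's receptive field, shuffled), then up to 20 all-pairs blocks of 42
trials (every pair twice, once per positional arrangement, shuffled), i.e.
70 + 840 trials at 20 blocks. Trial timing uses the stated intervals; the
fixation delay is "positively skewed on [0.4, 1.2] s with mean 0.5 s", for
which we chose a truncated shifted exponential with its rate solved
numerically once — the distribution family is otherwise unconstrained.
Analysis windows are half-open `[start, end)` in ms relative to stimulus or
saccade onset; ranks are 1-based. Two named "visual" windows coexist in the
presets (5–150 ms in the VAC scheme, 40–150 ms elsewhere) because different
analyses use different windows; selection is per analysis.

## The behavioral generator

The source experiment fits no behavioral model, so the agent is the minimal
generative process reproducing the structure the analyses need:

* **Learning curve.** `P(correct) = logistic(b0 + L(t)(bSdMax·SD +
  bTerm·terminal))`, `L(t) = 1 − exp(−t/tauLearn)`. With the defaults
  (`bSdMax = 0.45`, `bTerm = 0.45`, `tauLearn = 100`) accuracy starts at 0.5
  and plateaus near 0.75 by trial 250–300, with the symbolic-distance
  ordering and the terminal-item advantage. The defaults were set from the
  analytic plateau mean over the 21 pairs (including the dilution by the
  spatial bias below). Both effects ramp with the same learning factor, so a
  first-trial agent is at exact chance.
* **Spatial win-stay / lose-shift.** After each choice the agent's location
  repeat probability is nudged by a stickiness increment so that the
  session-average probability of repeating the previous location equals
  `pWinstay` (0.56) after rewarded trials and `pLoseshiftStay` (0.48) after
  unrewarded ones. The increment is applied relative to the trial's
  *natural* repeat probability (known exactly before the draw: it is `p` or
  `1 − p` depending on where the lower-ranked item sits), with an
  exponentially weighted tracker plus a realized-rate feedback term. This
  construction matters: counterbalanced blocks make the natural repeat
  probability sit slightly below 0.5 once accuracy is above chance, so a
  naive "flip toward the previous location" override recovers neither the
  configured parameter nor a clean chance baseline. Forcing the repeat
  probability to be *conditionally* constant would be wrong in the other
  direction — it would make location independent of the items and destroy
  the learning curve.
* **Latencies.** Truncated normal on (0, 1500] ms with mean
  `rtMu − rtSdSlope·SD` (232 − 1.4·SD) and SD 31 ms, giving the ~7 ms range
  of mean latency across SD 1..6 at a huge-N ANOVA significance; single
  targets use a 150 ms mean.

One caveat the tests document: conditioning item-choice probability on the
outcome of the *most recent previous choice of that item* carries a
secular-trend confound once accuracy drifts upward during learning. For the
stationary agent the conditional probabilities are equal, as they must be;
for the learning agent the estimator shows a small *negative* difference
(rewarded choices slightly less likely to be repeated) even though the
generator contains no item-level reward mechanism. Empirically the same
slight negativity is what the source experiment reported, so we treat it as
a property of the estimator, not a bug of the generator.

## The spiking generator

Each unit's rate is `softplus(baseline + A·template(t)·gain·(1 + mod) +
outcome)`:

* **Templates.** Six parametric temporal-profile families — visual
  transient, visual sustained, presaccadic ramp, postsaccadic, suppressed,
  delay/tonic — stand in for the empirically clustered response classes. The
  families were designed so that between-family profile correlations stay
  below the `r = 0.7` cluster-membership cutoff (max ≈ 0.6) while
  within-family correlations (after KDE smoothing over a session) stay well
  above it; per-unit temporal jitter (`tShift`, `tScale`) and lognormal
  amplitude variability provide within-family spread.
* **Spatial gain.** The in-field stimulus's drive is multiplied by
  `spatialGain = 2`, matching the ~2:1 in- vs out-of-field response ratio;
  pair trials average the two single-stimulus rates pointwise (response
  averaging).
* **Ordinal modulation.** Smooth random per-level weights on JR (11 levels)
  and SD (6 levels) multiply the template drive. They ramp in with learning
  (`modTau = 100` choice trials) and then persist, because the neural
  correlates of JR and SD emerge during early learning and remain stable.
  Defaults put more weight on JR than SD (`jrScale = 0.2 > sdScale = 0.1`),
  reflecting the observed predominance of JR tuning.
* **Transient rank code.** A signed, zero-mean linear code over the in-field
  item's rank, scaled by a Gaussian schedule over choice trials (center 125,
  width 75), so rank selectivity is detectable during the first ~250 choice
  trials and absent before (single-stimulus phase) and after — the pattern
  probed by the best/worst shuffle test. The fraction of rank-coding units
  (`rankFrac = 0.5`) is a free generator parameter; the experiment reports
  only "some neurons".
* **Outcome.** `outcomeGain = 0` by default: outcome modulation in the data
  this emulates is negligible, and the null calibration of the Wilcoxon
  outcome tests depends on it.

Spikes are drawn by thinning an inhomogeneous Poisson process on a 1 ms rate
grid over a peri-trial span (−0.5 s to feedback + 0.6 s); there are no
cross-unit noise correlations and no biophysics. Eye traces are 1 kHz
fixation jitter plus a sigmoidal saccade whose position excursion begins at
the nominal saccade onset (midpoint +23 ms, 5 ms slope), chosen so the
velocity-threshold detector recovers the latency within ±5 ms.

## Analysis pipeline

* **Eye kinematics.** Velocity is position convolved with the derivative of
  a temporal Gaussian, `dG/dt = −k·t·exp(−t²/τ²)`, `τ = 8` ms. (The negative
  exponent is the standard Gaussian derivative; the positive-exponent form
  sometimes printed diverges.) `k` normalizes the *discrete* kernel so a
  position ramp passes with gain exactly 1.0; the symmetric support makes
  the filter zero-phase. Saccade onset is the first crossing of 30 deg/s
  sustained ≥ 5 ms — a default we set, since no detection rule is stated.
* **Rates and z-scores.** Epoch rates are counts over duration, supporting
  variable-end (stimulus-to-saccade) windows, which are rate- (not count-)
  normalized. Session z-scores use the population-SD (divide-by-N)
  convention, fixed for reproducibility since the convention is otherwise
  unstated.
* **KDE rate estimates.** Gaussian-kernel intensity estimates with the
  bandwidth minimizing a least-squares (MISE) cross-validation cost over a
  log-spaced grid, computed on 1 ms binned data by convolution; if the cost
  has no interior minimum the estimate falls back to Silverman's rule
  (which is also the bandwidth used for eye-movement densities).
* **Clustering.** Agglomerative hierarchical clustering of z-scored
  KDE-smoothed temporal profiles on `1 − r` distance, cut at distance 0.3
  (`r = 0.7`). Average linkage is our choice — it pairs naturally with
  correlation distance; the source specifies only "agglomerative
  hierarchical". Constant profiles (undefined correlation) are excluded
  with a notice. Leaves are ordered by reweighting the dendrogram with
  first-principal-component scores, a standard heuristic for
  adjacent-similarity ordering; an exact optimal-leaf-ordering DP was judged
  unnecessary since no analysis depends on the leaf order.
* **OLE decoding.** The optimal linear estimator is ordinary least squares
  of the target (JR or SD) on the population z-rate matrix
  (Salinas–Abbott-style linear readout); rank-deficient designs get the
  minimum-norm solution with a warning. Bootstrap CIs resample trials,
  refit, and take 2.5/97.5 percentiles; 10,000 iterations for final
  figures, with smaller counts as a fast mode (both reported conventions
  are supported). In this package the pseudo-population is simulated on a
  common session, so trials align trivially; for data pooled across
  sessions an alignment on (pair, arrangement, trial bin) would be needed
  and is not provided.
* **GPR smoothing and VAC.** Spike counts in 10 ms bins are square-root
  transformed (variance stabilization), making the observation model
  Gaussian so the GP posterior is exact — we deliberately do not reproduce
  an expectation-propagation approximation, which is an implementation
  vehicle for non-Gaussian likelihoods, not a scientific claim. The prior
  covariance is a product of a squared-exponential kernel over trial
  covariates (trial index, JR, SD as continuous inputs — the ordinal
  smoothing assumption is the point) and one over within-epoch time, which
  gives a Kronecker structure solved by two small eigendecompositions.
  Signal and noise variances maximize the marginal likelihood
  (Nelder-Mead, with a variance heuristic as fallback); length-scales are
  the median heuristic on trial index and fixed defaults (JR 2, SD 1.5,
  time 25 ms) — the kernel family and scales are our documented defaults,
  as none are stated in the source. Posterior-mean rates are averaged
  within each epoch, the baseline epoch is subtracted per trial, and the
  variance accounted for by JR or SD is the partial eta-squared
  `F·df1/(F·df1 + df2)` from Welch's unequal-variance one-way test
  (`stats::oneway.test`; the test suite checks it against a hand-coded
  Welch oracle to 1e-10). An option excludes the extreme JR levels {3, 13}
  before testing.
* **Resampling inference.** Bootstrap percentile CIs; label-shuffle tests
  preserving the label multiset, with the add-one p-value convention
  `p = (1 + #{null ≥ obs})/(1 + nPerm)` so p is never exactly zero; the
  best/worst stimulus test compares each unit's apparent best−worst span
  with its label-shuffled counterpart by a paired t-test across units
  (argmax ties break toward the lower rank; no training/test split, the
  convention matching the published analysis, though a split mode would be
  the bias-safe variant). Outcome and explanatory-variable effects use
  Wilcoxon and Kruskal-Wallis tests at per-unit alpha = 0.05 with
  rank-based eta-squared effect sizes; no multiple-testing correction is
  applied across units — population summaries are fractions significant.

## Problem sizes and seeds

All randomness flows from integer seeds through independent child streams
(`childSeeds()`), so every simulation and resampling result is reproducible
bit-for-bit; bundle round trips through `writeBundle()`/`readBundle()` are
bit-exact (full-precision text tables, binary float eye traces). The shipped
checks use desk-scale problem sizes chosen to keep each property comfortably
testable: e.g. 100 naive-agent blocks for the chance baseline, 141 sessions
of 840 choice trials for win-stay recovery, 142 units over a 238-trial
session for cluster-count recovery, 8–16 units for the VAC and decoding
closed loops, and 1,000 random datasets for the Welch oracle comparison.

## What passing tests do and do not show

The generator reproduces the *statistical structure* the analyses assume —
learning curves, SD/JR effects, response families, transient rank coding,
negligible outcome effects — not the recordings themselves. Real data add
non-Poisson variability, cross-unit correlations, drift and isolation
artifacts, uncontrolled stimulus features, and incomplete trials (fixation
breaks are not simulated; all analyses here use completed choice trials).
Consequently the package's tests validate correctness and calibration of
the machinery (parameter recovery, null calibration, oracle agreement), and
directional properties (e.g. JR VAC exceeding SD VAC under JR-dominant
tuning); they do not certify the published effect magnitudes, which cannot
be recomputed without the original recordings.
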