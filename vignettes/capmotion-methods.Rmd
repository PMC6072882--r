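---
title: "Recognizing forearm motions from capacitive muscle-deformation signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing forearm motions from capacitive muscle-deformation signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capmotion)
```

## The measurement model

A band of six electrodes worn over the clothes around the forearm forms six
equivalent plate capacitors with the limb. Muscle contractions deform the
limb surface, change the electrode-to-skin distance, and shift each channel's
capacitance by a few pF. Sampling the six channels at 100 Hz therefore gives
a noncontact record of muscle deformation, and distinct motion patterns leave
distinct quasi-static capacitance signatures. An inertial measurement unit on
the back of the hand simultaneously records the three Euler angles (pitch,
roll, yaw, degrees in [-180, 180]) at the same rate.

A trial of the measurement protocol holds the relaxed state (R) for a few
seconds, transitions to one of eight target patterns -- wrist
flexion/extension (WF/WE), pronation/supination (WP/WS), radial/ulnar
deviation (RD/UD), palm (P), fist (F) -- holds it for about 10 s, and
returns to relax. Each trial therefore contains exactly two motion
transitions, delimited by four boundaries L1 < L2 < L3 < L4: L1/L2 are the
initiation/termination of the outbound transition, L3/L4 of the return.

`capmotion` implements the full offline analysis: signal conditioning,
automatic boundary labeling from the IMU, window features, a quadratic
discriminant classifier, and the evaluation metrics, plus a synthetic trial
generator so the entire pipeline is testable without recordings.

## Preprocessing and features

Raw capacitance carries high-frequency noise well above the deformation
band. Each channel is filtered with a 4th-order Butterworth low-pass at
5 Hz. The filter is applied forward and backward (zero phase): offline
processing permits it, it leaves no group delay to bias the transition-time
metrics, and the effective magnitude response is the squared single-pass
response. Our implementation reflects the signal at both ends (about its end
points) and starts each pass from DC steady state, so constants pass through
exactly and edge transients stay out of the data.

A window of fixed length (default 100 ms = 10 samples) slides over the
filtered signals with a 1-sample stride, matching a recognition decision
every 10 ms. Per channel and window four time-domain features are computed:

* `AVE` -- the window mean;
* `STD` -- the population (divide-by-n) standard deviation;
* `MAX` -- the window maximum;
* `TAN` -- (last - first) / window length, with the length in samples.

Two conventions here are ours, fixed and asserted in tests because the
definitions admit variants: `STD` uses the population form, and the `TAN`
denominator is in samples (a 100 ms window divides by 10). Only the relative
scale of a feature matters to the classifier, so neither choice affects
decisions. The six channels' features are concatenated channel-major into a
24-element feature vector.

Windows are labeled by the segment containing their full extent: `R` before
L1 and after L4, the trial motion between L2 and L3. A window overlapping a
transition interval is flagged; flagged windows are excluded from training
and from accuracy metrics but remain in the decision stream, where the
prediction-time metrics need them.

## Automatic boundary labeling

Manual annotation of L1-L4 is the bottleneck of training, so boundaries are
computed from the Euler angles of the measured hand:

1. **Regulation.** Each axis that *decreased* from relax toward the motion
   plateau is flipped about its trial mean (x' = 2 mean(x) - x), so all
   axes move the same way; the three aligned axes are summed. The flip
   decision compares the axis mean over the middle 2 s of the trial (motion
   plateau) with its mean over the first second (relaxed). The slope signal
   S is the first difference of the regulated sum.
2. **Extremum detection.** Candidate extrema are local maxima of |S|,
   found by the sign-change rule on the differences of |S| (a
   second-order-difference test on the regulated signal). We use |S|
   rather than S because the return transition's slope is negative after
   regulation aligns the axes to the outbound direction. Candidates are
   sorted by magnitude, ties broken by earlier position. The largest is the
   first transition peak P1; the second peak P2 is the first candidate
   farther than a duration threshold (default 2000 ms) from P1. The
   threshold rejects secondary ripples of the same transition -- the
   low-excursion palm/fist profiles produce exactly such multi-peaked
   slopes. Flat-topped extrema (which arise in noise-free signals) are
   counted once at their first descent.
3. **Threshold detection.** The crossing threshold is the standard
   deviation of S over the trial's static middle 2 s -- an estimate of the
   slope noise floor. The points where |S| crosses it are boundary
   candidates; the crossings nearest each peak on either side become L1/L2
   (around P1) and L3/L4 (around P2).

The 2000 ms duration default is a convention: it must exceed any single
transition (hundreds of ms) and stay below the plateau length (about 10 s);
its exact value is uncritical inside that window and it is exposed in
`autolabel_params()`.

## The classifier

Each motion class is modeled as a multivariate Gaussian over the 24
features. `fit_qda()` estimates a mean vector and covariance matrix per
class -- with nine motions that is nine 24 x 24 matrices and nine 24 x 1
vectors -- and scores a window by the Gaussian log-density plus log prior:

score_k(x) = -1/2 log det(Sigma_k) - 1/2 (x - mu_k)' Sigma_k^{-1} (x - mu_k) + log pi_k.

Covariances use the divide-by-n form and priors are training proportions;
both conventions are documented so the cross-check against an independent
reference implementation can account for them. A ridge of
`1e-8 * tr(Sigma_k)/24` (absolute `1e-8` for a zero-variance class) guards
near-singular classes -- plateau windows make some features nearly constant
-- without materially moving decision boundaries. Exact score ties break
toward the lowest class index in the fixed ordering R, WF, WE, WP, WS, RD,
UD, P, F. The Mahalanobis terms are computed via Cholesky factors for
stability; a singular class covariance with ridge 0 is an error, not a
silent pseudo-inverse.

## Evaluation metrics

* **RA** -- percent of correct decisions outside the transition intervals.
* **Confusion matrix** -- row-normalized percentages c_ij = 100 n_ij / n_i.
  of class-i windows recognized as class j; rows sum to 100.
* **RA_c** -- the mean of the confusion diagonal, weighting every class
  equally regardless of its test size.
* **Prediction times** -- per transition, T_r is the time of the first
  decision opening a run of at least 10 consecutive decisions for the
  upcoming class (the trial motion outbound, R on return). PT1 = T_r - T_i
  (initiation) and PT2 = T_r - T_t (termination); negative values are
  early recognitions. A qualifying run may begin before the transition
  starts. One reading we had to fix ourselves: the search for the return
  transition starts after the outbound transition's termination, since the
  lead-in relax period would otherwise always supply a spurious R run.

Cross-validation folds are whole trials (five trials per motion gives
five-fold leave-one-out); `cv32`/`cv23` iterate all train/test trial
combinations and average, `cv11`/`cv64` operate across two recording
sessions, and `accumulated` refits from scratch on trials 1..k and tests
trial k+1. Relax windows from every trial's lead and tail are pooled into
class R.

The package ships the published benchmark tables of per-transition
prediction times (seven subjects, 16 transitions;
`reference_prediction_times()`) so their row, column and grand means can be
recomputed exactly. Formal repeated-measures inference on those values is
out of scope; reports expose the raw per-subject metrics.

## The synthetic generator

`generate_trial()` emulates what the analysis assumes about a trial:
motion-specific quasi-static capacitance offsets with smooth transitions,
and Euler trajectories whose slope peaks at the two transitions. Defaults
(all in `motion_profile()` / `session_spec()`):

* geometry: 3 s relaxed lead, 600 ms half-cosine transitions, 10 s hold,
  3 s tail (1720 samples);
* capacitance: 30 pF baseline, per-motion offset patterns with magnitudes
  of roughly 1-5 pF, Gaussian noise sd 0.05 pF, plus a 0.2 pF 20 Hz
  sinusoid so the 5 Hz filter is exercised;
* Euler angles: 30-60 degree excursions on the dominant axis for wrist
  motions; 3-8 degree excursions for the palm/fist "gesture" profiles with
  slightly higher angle noise (0.08 vs 0.05 degrees), reproducing the
  weak, multi-peaked slope signals that motivate the duration filter;
* trial-to-trial jitter of 5% on offsets, excursions and transition
  duration -- inter-trial variability magnitudes are not documented for
  the real system, so this is a convention, exposed in `session_spec()`.

Half-cosine ramps (rather than linear) give a single interior slope
extremum per transition, the unimodal case of the extremum detector; the
gesture profiles exercise its multi-peak branch. Euler noise is generated
band-limited (white noise low-passed to the signal band and rescaled),
because fused orientation output is smooth -- white per-sample angle noise
would make the slope signal, a first difference, noise-dominated in a way
real IMU output is not. Ground-truth boundaries are recorded at the ramp
endpoints, so labeler error is measurable exactly.

What the generator does **not** emulate: biomechanics (no muscle model,
no cross-talk between channels beyond the fixed offset patterns), posture
dependence of the relaxed state, electrode re-wear shifts, drift, or
class-conditional feature distributions with realistic overlap. Synthetic
classes are well separated, so pipeline accuracies near 100% on this data
are a correctness property of the implementation, *not* a reproduction of
the published human-subject accuracies (92.32% over nine patterns), which
used recordings that are not deposited.

## Indexing and numerical conventions

* Sample indices are 1-based (native R); a sample's time is
  (index - 1) x 10 ms. Boundaries are stored as sample indices, not ms, to
  avoid rounding drift; trial files carry an explicit `t_ms` column.
* Trial files are comma-separated UTF-8 with 6-decimal fixed formatting
  (lossless round-trip to 1e-6) plus a plain key-value sidecar.
* Candidate sorting and score ties break deterministically (earlier
  position, lower class index).

## Problem sizes

The test suite and the acceptance script size their simulations as: one
9-pattern session of 8 motions x 5 trials x 17.2 s for the end-to-end
benchmark (about 63 000 windows), 200 trials for labeler recovery, and
1000 test points for the classifier cross-check -- large enough for stable
statistics on well-separated synthetic classes, small enough to run in
seconds.

## Known limitations

The labeler assumes exactly two transitions per trial and fails loudly
otherwise; streaming (online) labeling is out of scope. Recognition is
discrete classification -- no continuous joint-angle estimation. Robustness
to re-wear and posture variation can be *measured* with the session-wise CV
schemes but is not modeled by the default generator profiles.
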