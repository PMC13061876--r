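---
title: "Instantaneous-frequency microstates: model, pipeline, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instantaneous-frequency microstates: model, pipeline, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifmicrostate)
```

## The model

Conventional EEG microstates segment the multichannel signal by the spatial
topography of its *amplitude*. This package implements the complementary
view: brief quasi-stable states of the spatial topography of the
*instantaneous frequency* (IF). In the theta–alpha band, posterior channels
often run slightly fast and anterior channels slightly slow (occipital IF
lead / frontal IF lag), and the momentary pattern of these per-channel
frequency deviations switches on a sub-second timescale. An IF microstate
is one such recurring spatial pattern.

The pipeline has five stages.

1. **Preprocessing.** Each recording (channels × samples, 200 Hz in the
   reference setup) is band-pass filtered to the analysis band — 4–13 Hz
   by default, covering theta (4–8 Hz) and alpha (8–13 Hz); the
   alpha-only variant is just `band_low_hz = 8`. The filter is a 4th-order
   Butterworth applied forward–backward (`signal::filtfilt`), i.e.
   zero-phase with effective order 8. Zero phase matters: any group delay
   would bias the phase derivative that follows. Five seconds are trimmed
   from each end afterwards, absorbing both filter and Hilbert-transform
   edge effects.

2. **IF extraction.** For each channel \(i\), the analytic signal
   \(a_i(t) = x_i(t) + i\,\mathcal{H}[x_i](t)\) is formed by the FFT
   construction. The wrapped phase \(\phi_i(t) = \arg a_i(t) \in
   (-\pi,\pi]\) is unwrapped by adding multiples of \(2\pi\), and

   \[\mathrm{IF}_i(t) = \frac{1}{2\pi} \frac{d}{dt}\,
   \mathrm{unwrap}[\phi_i(t)],\]

   estimated by central differences at interior samples (one-sided at the
   two ends). Phase slips — brief noise-driven branch-cut crossings —
   produce large spikes in the raw derivative; these are suppressed by a
   100-ms running median (21 samples at 200 Hz: window
   `round(window_ms * fs / 1000)` forced odd, rounding up). Out-of-band IF
   values that survive the median are retained, not clipped: the median
   filter is the only slip mitigation.

3. **Spatial normalization.** At every time point the mean across
   electrodes is subtracted from the channel IF vector and the result is
   divided by the across-electrode population (N) standard deviation — the
   row *is* the whole electrode population at that instant, hence N rather
   than N−1. The resulting z-scored 16-dimensional vectors are the
   observation sequence. Time points with zero spatial variance are
   flagged degenerate and excluded from model fitting.

4. **State model.** The z-scored vectors of *all* participants of *both*
   groups are pooled and clustered by Euclidean k-means (k-means++
   seeding, 20 restarts, fixed seed). The K centroids initialize a
   first-order hidden Markov model with diagonal-covariance Gaussian
   emissions, fitted by Baum–Welch on the pooled data with
   forward–backward recursions restarting at every participant boundary
   (no transition is ever counted across participants). Fitting once on
   pooled data is a design commitment, not a convenience: it prevents
   group-specific state reorganization, so the state identities are the
   same objects in both groups and group differences can only appear in
   the *dynamics*. Model order is chosen by the elbow of the information
   criteria, \( \mathrm{AIC} = 2p - 2\ln L\),
   \( \mathrm{BIC} = p \ln n - 2\ln L\), with
   \(p = (K-1) + K(K-1) + 2KD\) and the elbow formalized as the maximum
   discrete second difference of the criterion curve (BIC by default; both
   curves are always reported so the choice is auditable). Each
   participant's state sequence is then decoded by Viterbi under the
   shared model — Viterbi rather than per-sample posterior argmax because
   the temporal continuity that motivated the HMM should also constrain
   the decoded path.

5. **Dynamics and statistics.** From each decoded sequence we compute, per
   state \(i\): mean dwell time \(D_i = \frac{1}{N_i}\sum_e d_{i,e}\)
   (mean duration of its episodes), fractional occupancy
   \(f_i = \sum_e d_{i,e} / T\), and the empirical transition matrix
   \(P(i \to j) = N_{i\to j} / \sum_k N_{i\to k}\) over consecutive-sample
   pairs, self-transitions included. Group comparison per metric cell:
   natural-log transform, D'Agostino–Pearson normality test on the
   transformed values in each group, Welch's t-test if both groups pass at
   α = 0.05 and the Mann–Whitney U test otherwise, Benjamini–Hochberg FDR
   at q < 0.05 within each metric family, and signed significance scores
   \(\mathrm{sign}(\Delta) \times (-\log_{10} p)\) for the transition map.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| analysis band | 4–13 Hz | theta + alpha, the bands carrying large-scale phase structure; 8–13 Hz variant via config |
| filter | Butterworth order 4, zero-phase | standard EEG band-limiting; no group delay |
| edge trim | 5 s per side | removes filter/Hilbert transients |
| median window | 100 ms | suppresses phase-slip spikes at the cost of sub-window temporal detail (see below) |
| derivative | central difference | half the truncation error of a one-sided difference; exact for linear and quadratic phase |
| K (states) | elbow over 2–8 | second-difference elbow of BIC |
| EM | tol 1e-4 relative, ≤ 200 iterations | recorded in `fit_log`; means re-estimated from the k-means init (`freeze_means = TRUE` gives the stricter frozen-centroid reading) |
| emission variances | floored at 1e-6 | guards degenerate collapse on z-scored data |
| state order | descending pooled occupancy | makes state identities reproducible across seeds/restarts |

Two conventions worth making explicit. The occupancy formula is a time
*fraction*; the conventional "occurrence" (episodes per second) is also
computed, as `episode_rate_hz`, so both readings of emergence are
available. Zero transition probabilities would break the log transform;
they are floored at 1/(total transition count) — the smallest observable
nonzero probability — and flagged in the output. The Welch test is the
parametric default (the groups have unequal sizes); Student's is a switch.
Cohen's d always uses the pooled (n−1)-weighted SD on the *original*
metric scale, with positive sign meaning the contrast group is larger,
even when the test itself ran on logs.

## The synthetic cohort

The generator provides what real recordings cannot: ground truth. Each
participant's hidden state sequence is drawn from a first-order Markov
chain; each channel is then a unit-amplitude cosine whose instantaneous
frequency is `base_freq + offset_channel(state(t))`, with the phase
accumulated as the integral of the IF so it is continuous across switches
and the sample labelled `t` is centred on its own state interval. White
Gaussian noise is added. This is the *minimal* observation model for which
"spatial IF pattern" is exact ground truth.

Defaults mirror a two-group resting-state study: 29 + 18 participants, 16
channels on the standard 10–20 montage, 200 Hz, 60 s, a 10-Hz carrier,
K = 5 patterns (occipital-lead, frontal-lead, left–right, midline-fast,
temporo-occipital-fast; offsets within ±1 Hz), self-transition
probabilities of 0.94 in the younger group and 0.95 / 0.93 for states
1 / 5 in the middle-aged group — dwell times near 80–100 ms, the scale at
which resting-state IF microstates operate, with the group contrast living
entirely in the dynamics (patterns shared, mirroring the shared-model
design). `noise_sd = 0.2` relative to unit amplitude (≈ 11 dB) reflects
band-limited eyes-closed alpha, which is high-SNR; it is a free parameter
of the generator and is reported with every validation run. Per-participant
seeds derive deterministically from the master seed, so cohorts are
bit-reproducible.

What the generator does **not** emulate: volume conduction and channel
covariance, 1/f background, amplitude dynamics, artifacts, drowsiness.
Passing the recovery suites therefore demonstrates correctness of the
*pipeline machinery* on data satisfying its assumptions, not performance
on real EEG. A pink-noise background was considered and deliberately left
out: it would break the exactness of the IF oracles that make the suite
sharp.

## What recovery validation can and cannot show

The validation suite decodes synthetic cohorts and scores accuracy against
the generating state sequence after exact optimal label matching
(exhaustive permutation search; equivalent to Hungarian assignment for
K ≤ 8). Two blur mechanisms bound the achievable accuracy, and both are
properties of the *measurement chain*, not of the HMM:

- the **median filter** completely erases any state episode shorter than
  about half its window — the window's median is then the surrounding
  state's value. With geometric dwells at self-transition 0.94, roughly
  5% of samples sit in episodes of ≤ 5 samples and another 9% in episodes
  of 6–10 samples; those samples are unrecoverable by any downstream
  model. Measured error rates by true-episode length confirm this (≈ 85%
  for ≤ 5 samples, ≈ 53% for 6–10, < 7% above).
- the **band-pass filter** strips the FM sidebands that carry switch
  timing, smearing a 3-sample IF transition over ~20 samples when the
  4–13 Hz band is applied to a 9–11 Hz switching carrier.

Consequently pooled decoding accuracy plateaus near 85–89% under the
default conditions, and the fitted self-transition probabilities are
biased upward by a few hundredths (merged short episodes look like longer
dwells). The model-order elbow is robust to all of this and reliably
selects the generating K = 5. These ceilings are stated here rather than
hidden behind adjusted simulation parameters; the same mechanisms operate
on real data, which is worth remembering when interpreting absolute dwell
times near the median-window scale.

The validation suites use 47 participants at 10 s of usable signal each
(12 s generated, 1 s trimmed per side) — enough pooled samples (~94,000)
for the transition estimates' sampling error (≈ 0.002) to be negligible
against the effects measured, while keeping the full suite inside a few
minutes. The null-calibration suite (500 replicates of the
metrics-to-statistics path at the study's group sizes) runs on bare label
sequences: the statistical path never sees the waveform, so signal
synthesis would only add runtime, not information.

## Numerical choices and degenerate inputs

- Forward–backward uses per-step scaling with the per-sample maximum of
  the log emission densities factored out, so likelihoods stay finite for
  any dimension; a non-finite likelihood aborts with the iteration index.
- EM stops when the relative log-likelihood gain drops below 1e-4
  (trace and convergence flag kept in `fit_log`); the trace is checked to
  be non-decreasing in the tests.
- k-means ties and permutation invariance are handled once, after
  fitting, by the canonical occupancy ordering; ties broken by the
  first-channel centroid value.
- Constant (zero-spatial-variance) time points are flagged and skipped in
  fitting; decoding keeps them so the label sequence preserves the time
  base.
- Groups too small for the normality test (n < 8) or constant fall back
  to the nonparametric path with a warning; identical groups give p = 1
  (ties-corrected Mann–Whitney), and two constant equal groups are an
  error rather than a fabricated p-value.
- The elbow needs at least three candidate K values; fewer is an error,
  not a silent default.

## Known limitations

- Temporal resolution is bounded by the median window; dwell times below
  ~50 ms are not observable, and short-episode erasure biases fitted
  self-transitions upward (quantified above).
- The Gaussian diagonal-covariance emission model is a modelling choice;
  spherical or full covariance would change the likelihood geometry
  (configurable in principle, diagonal is the implemented default for
  z-scored inputs).
- The EDF writer/reader covers the common equal-rate continuous case
  only.
- No covariate adjustment: group comparison is two-sample only, matching
  the design it implements.
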