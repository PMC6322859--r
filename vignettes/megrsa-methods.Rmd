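---
title: "Spatial and temporal RSA of paired-design MEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial and temporal RSA of paired-design MEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megrsa)
```

## The scientific problem

During sentence reading, a strongly constraining context lets the brain
predict the upcoming word before it appears. If such predictions carry
item-specific content, then two *different* sentence contexts that predict
the *same* word should evoke more similar neural activity during the
prediction interval than two contexts predicting different words. The
design that operationalizes this is a set of N sentence pairs (2N
sentences): the two members of a pair predict the same sentence-final word
(SFW), one ending with the expected word and one with an unexpected word.
`megrsa` implements the analysis machinery for this design on epoched MEG
data, together with a synthetic generator that embeds the hypothesized
signal structure so every statistical claim can be checked by parameter
recovery.

## Similarity measures

All similarity is plain Pearson correlation of raw signal values; raw
`r` values are averaged (no Fisher z), with a per-comparison undefined
flag (NA) wherever a pattern has zero variance — undefined values are
excluded from averages with counts kept, never imputed.

* **Spatial RSA.** For a comparison between trials $a$ and $b$, the
  instantaneous sensor vectors are correlated at every time sample,
  giving a similarity time series $R(t)$. Within-pair comparisons pair
  the two members of each pair (N comparisons); between-pair comparisons
  pair sentences from different pairs ($2N(N-1)$ of them; a count-matched
  random subsample is used where computational balance matters).
* **Cross-temporal (temporal generalization) matrices.** The pattern of
  trial $a$ at time $i$ is correlated with the pattern of trial $b$ at
  time $j$ for all $(i, j)$ in the one-second interval before SFW onset,
  after downsampling to 300 Hz; correlation values are smoothed with a
  truncated Gaussian kernel (40 ms support, 8 ms SD), along both axes by
  default (smoothing one axis only is available via `smooth_axes`).
* **Temporal RSA.** Within a fixed time window, each sensor's time course
  in trial $a$ is correlated with the same sensor's time course in trial
  $b$, giving a topographic map of temporal similarity; at the source
  level the same map is computed over beamformer virtual channels.

## Window detection and group tests

The analysis window is found from the *combined* similarity series (the
mean of the within- and between-pair group averages): the longest
contiguous run of samples with $R$ above a threshold of 0.04 (0.03 as a
sensitivity setting) inside the search interval, by default the
SFW$-1$-onset-to-SFW-onset second. Group inference on window-averaged
values uses a two-sided paired t-test across participants
(`window_test`); the presentation-order control is a 2×2
repeated-measures ANOVA (Order × Pairs) computed by the difference-score
formulation, with partial $\eta^2 = F/(F + df_2)$.

## Cluster-based permutation inference

Three cluster tests share one permutation scheme: within each
participant the within/between condition labels are exchangeable under
the null, and swapping them is equivalent to flipping the sign of that
participant's within-minus-between difference. Each of `n_perm`
permutations flips every participant independently with probability 1/2;
the maximal cluster mass per permutation forms the null; p-values use the
$(b+1)/(n_\text{perm}+1)$ convention (minimum $\approx 0.001$ at 1000
permutations) and clusters in the highest or lowest 2.5% are significant.

* **Matrix test** (`matrix_cluster_test`): per-cell paired t-values;
  cells with uncorrected $p \le .05$ form clusters under 4-connectivity
  (edge-adjacent cells; the adjacency convention is a package choice —
  nothing in the method fixes it); mass = summed t.
* **Sensor test** (`sensor_cluster_test`): the group-mean difference map
  is thresholded at its 95th percentile across sensors (5th for the
  negative tail); supra-threshold sensors within 40 mm form clusters;
  mass = summed mean difference. The percentile threshold is recomputed
  inside every permutation, so statistic and null are computed
  identically — the exchangeability requirement. Note two consequences
  that are easy to miss: (i) percentile thresholding *always* produces
  clusters, so all inferential weight is on the permutation null; and
  (ii) an effect spanning $k$ sensors can only survive thresholding if
  $k$ is at most about 5% of the array.
* **Grid test** (`grid_cluster_test`): identical, with clusters formed by
  contiguous grid points (within 1.1 grid-spacing steps, the face
  neighbors of the lattice).

Percentiles use the linear-interpolation (R type 7) definition
throughout.

## LCMV beamforming

Source time courses come from linearly constrained minimum variance
filters $W_g = (L_g^\top C^{-1} L_g)^{-1} L_g^\top C^{-1}$, with $C$ the
trial-averaged sensor covariance on 30 Hz low-passed, linearly detrended
data from SFW$-1$ onset to 1 s after SFW onset, and $L_g$ the 3-column
lead field of grid point $g$. At $\lambda = 0$ the unit-gain constraint
$W_g L_g = I_3$ holds to machine precision. Regularization
$C + \lambda \overline{\mathrm{diag}(C)} I$ defaults to $\lambda = 0$
with an automatic fallback to 5% when the condition number of $C$
exceeds $10^8$ (the fallback is recorded on the filter object). Note
that raising $\lambda$ *increases* the data-window output variance — the
$\lambda = 0$ filter is the variance minimizer by construction — while
monotonically shrinking the white-noise gain $\lVert W\rVert^2$; both
properties are tested. The 3-orientation series is reduced to a scalar
by the first left singular vector of the participant-level concatenated
series (sign fixed so its largest-magnitude entry is positive); the
concatenation scope is per participant because the orientation is a
property of the source, not of a trial — per-trial SVD would let noise
re-pick the orientation trial by trial.

## The synthetic generator

`simulate_dataset()` builds each trial as evoked + item identity + noise:

* **Word-evoked component** (amplitude default 0.5): a spatial-pattern
  process shared by *all* trials of a participant, time-locked to every
  word onset and active 120–515 ms after it (raised-cosine edges, 30 ms).
  Its topography is redrawn every ~130 ms, which reproduces the
  diagonal-banded structure of empirical cross-temporal matrices. This
  component is what makes the *combined* similarity series exceed the
  0.04 threshold in the post-word interval, so the detected window tracks
  the 120–515 ms response of the word before the SFW (i.e. −880…−485 ms
  relative to SFW onset).
* **Item-specific component** (amplitude default 0.5): per pair, a
  spatial pattern (unit across-sensor SD, spatially smoothed over the
  layout) times a smooth random temporal waveform, *identical for the two
  members of a pair*, confined exactly to the effect window (default
  −880…−485 ms). `identity_mode = "dynamic"` redraws the pattern every
  `identity_tau` seconds (linear crossfade between knots), which confines
  within-pair cross-temporal similarity to the diagonal.
* **Noise** (SD default 1): zero-mean Gaussian with sensor covariance
  $\sigma^2 \exp(-d/\ell)$, $d$ the inter-sensor distance and $\ell$ =
  30 mm; temporally white by default with an optional AR(1) switch.

With patterns at unit across-sensor SD, the expected instantaneous
spatial correlation contributed by a shared component of amplitude $A$
at envelope value $h$ is roughly $A^2h^2 / (A^2h^2 + \sigma^2)$ — the
default amplitudes were chosen from this formula so that the *direction*
of the effects is comfortably recoverable at desk scale; no claim about
empirical effect magnitudes is intended, and no study quantifies them.

What the generator deliberately does not emulate: physiological
artifacts, 1/f spectra, gradiometer reference correction, realistic head
geometry, inter-participant anatomical variability, or any
expectancy-related amplitude differences. Passing recovery tests
therefore show the *pipeline* is correct and calibrated under the
assumed signal structure, not that real MEG data satisfy that structure.

The toy forward model places a half-spacing-offset 10 mm lattice inside
a hemisphere and uses the quasi-dipolar field
$(q \times (s - r)) \cdot n_s / |s - r|^3$. Sensor orientations $n_s$
are radial plus a small (0.3, seeded) tangential tilt: a perfectly
radial array on a sphere is exactly blind to radial dipoles, which would
make every lead field rank 2; the tilt is what makes all three
orientations visible, mirroring the imperfect radiality of real axial
gradiometers. Grid points with a degenerate gain triplet abort with a
diagnostic.

## Design bookkeeping

`random_pair_design()` builds balanced synthetic designs (half nouns,
half verbs, seeded expectancy order and SFW-1 vocabulary).
`build_presentation_order()` emits pseudo-randomized orders with at
least `min_separation` sentences *between* the members of a pair
(default 30) and at most `max_run` (default 3) equal-expectancy
sentences in a row. Pure rejection sampling is hopeless at this size (a
random permutation violates the separation constraint ~30 times in
expectation for 120 pairs), so the generator repairs a random
permutation by bounded randomized swaps and fails with a diagnostic
after `max_attempts` moves; every emitted order is re-checked by an
independent brute-force scan. The within-category comparison set
excludes within-pair comparisons by default (they share identity, not
merely category); `include_within = TRUE` gives the literal reading.

## Numerical conventions

* Time is in seconds relative to SFW onset; windows are half-open
  `[start, end)`; 4.0 s at 300 Hz is exactly 1200 samples. Sensor
  coordinates are mm.
* The low-pass filter is a zero-phase order-4 Butterworth (the filter
  family and order are package choices; the method only fixes the 30 Hz
  cutoff). The forward–backward pass uses mean removal plus
  odd-reflection padding, giving exact DC gain and ≥48 dB attenuation at
  twice the cutoff.
* The Gaussian smoothing kernel is truncated at the stated 40 ms support
  ("time window" is read as total support) and renormalized over the
  available support at the edges, so constants pass through unchanged.
* Resampling decimates after an anti-alias low-pass at 80% of the new
  Nyquist; only downsampling is allowed.
* Correlations with zero-variance inputs are NA, excluded from averages
  with counts logged.
* All randomness (layouts, designs, noise, subsampling, permutations) is
  seeded; identical config + seed gives bit-identical results, and the
  seeded helpers restore the caller's RNG state.

## Simulation studies and their sizes

The `study_*` functions are the package's reproducibility surface (the
test suite and `scripts/acceptance.R` call the same code). Problem sizes
are fixed package choices: the core study condition is 12 participants,
40 pairs, 64 sensors at 300 Hz with epochs covering the 1-s prediction
interval (`study_config()`); the null calibration studies shorten the
epoch to the tested window and the matrix-cluster FWER study runs at 20
pairs / 32 sensors / 100 Hz to keep the time-by-time matrices small.
Between-pair sets are count-matched to the within-pair sets in the
studies (the same matched-count control the analysis itself offers).

* `study_type1_window()` — 200 null datasets; the window test's
  rejection rate at $\alpha = .05$ should sit in the binomial band
  [0.022, 0.088].
* `study_fwe_cluster()` — 100 null datasets per test, 200 permutations;
  familywise error should not exceed 0.07.
* `study_recovery()` — 50 datasets with the default item signal:
  detection power of within > between and the overlap of the
  auto-detected window with the embedded −880…−485 ms window.
* `study_diagonal()` — dynamic patterns (lifetime 100 ms): the mean
  |row − col| lag of significant matrix-cluster cells must stay below
  the lifetime.
* `study_beamformer()` — unit gain, noiseless single-source recovery,
  and the difference-map peak on noisy data. Because correlation maps
  are scale-invariant, leakage blurs the peak by about one grid step, so
  a hit is the peak landing on an injected point *or a face neighbor*;
  the exact-peak rate is reported alongside.
* `study_perm_null()` — Kolmogorov–Smirnov distance between the sampled
  sign-flip null and the exhaustive $2^n$ null at $n = 8$.

## Known limitations

* The generator's noise is spatially correlated but temporally white by
  default; real MEG noise is strongly autocorrelated. The AR(1) switch
  exists but the calibration studies run the default.
* The sensor-level cluster test's percentile threshold makes it blind to
  near-global effects (everything above the 95th percentile is, by
  construction, 5% of sensors).
* Localization claims are grid-step-limited (see above); anatomical
  labeling is out of scope.
* Empirical effect magnitudes from real recordings are not reproduced
  or asserted anywhere; the package's claims are combinatorial,
  numerical-equivalence, calibration and recovery claims.

## A small end-to-end run

```{r pipeline, eval = FALSE}
cfg <- sim_config(n_participants = 8, n_pairs = 20, n_sensors = 32,
                  sample_rate = 300, seed = 11)
res <- run_pipeline(cfg, n_perm = 1000, seed = 4)
print(res)
```

The pipeline simulates (or accepts) a dataset, detrends and low-pass
filters it, detects the supra-threshold window from the combined
similarity series, runs the window test, the cross-temporal matrix
cluster test, the sensor-level temporal RSA cluster test, and the
source-level LCMV analysis, reusing the detected window throughout, and
returns a manifest (config snapshot, seeds, comparison counts, file
checksums when an output directory is given).
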