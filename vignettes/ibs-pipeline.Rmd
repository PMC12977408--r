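---
title: "Quantifying interbrain synchrony in dyadic fNIRS hyperscanning: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interbrain synchrony in dyadic fNIRS hyperscanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two people collaborate on a computer task — a Guide describing a hidden
reference path, a Drawer steering a cursor — while cortical hemodynamics are
recorded from both heads with continuous-wave fNIRS (16 channels, two
wavelengths, 7.81 Hz, six regions of interest: left/right frontopolar PFC,
dorsolateral PFC, and TPJ). The scientific question is whether *interbrain
synchrony* (IBS) — the wavelet coherence between homotopic ROI signals of the
two partners in the 0.01–0.08 Hz band — carries information about the state
of the collaboration, and in particular whether an unexpected task disruption
(80% of navigation icons vanishing at the 10-minute mark) changes IBS level,
its temporal trend (slope), or its temporal regularity (percent determinism).

`nirsync` implements the complete analysis: a synthetic-data generator with
known ground truth, the optical-density preprocessing chain, wavelet-transform
coherence with cone-of-influence (COI) exclusion, the three IBS features, the
permuted-dyad null, communication and path-accuracy behavioral features, and
the mixed-model inference program. Because no public recording of this
paradigm exists, every stage is validated against the generator, whose
parameters are the study protocol's constants.

## The synthetic dyad model

For each dyad, each homotopic ROI pair receives

$$x_{\mathrm{guide}}(t) = \kappa(t)\, s(t) + \sqrt{1-\kappa(t)^2}\; p_g(t), \qquad
  x_{\mathrm{drawer}}(t) = \kappa(t)\, s(t) + \sqrt{1-\kappa(t)^2}\; p_d(t),$$

where $s$, $p_g$, $p_d$ are independent unit-variance Gaussian processes
band-limited to 0.01–0.08 Hz (white noise through a zero-phase FFT
band-pass). With equal spectra the squared wavelet coherence of the pair is
$\kappa^4$ in expectation, so coupling is controllable with an analytic
target. $\kappa$ switches from `coupling_pre` to `coupling_post` at the
disruption marker in the experimental group only; `ibs_trend` adds a linear
drift in squared-coherence units per second within each period (implemented
as $\kappa(t) = (\kappa_0^4 + b\,t)^{1/4}$). A single latent $s(t)$ feeds all
six ROI pairs, since no inter-ROI coupling structure is specified by the
paradigm.

Channel-level signals add, per participant:

* a **Mayer wave** (0.1 Hz) and a **respiratory** oscillation (0.25 Hz) with a
  common phase within a participant and per-channel *signed* gains. The sign
  heterogeneity represents variable optode sensitivity to superficial flow; it
  is what makes the systemic subspace identifiable — a strictly positive gain
  pattern would be nearly collinear with the (positive) cortical gain pattern
  and PCA filtering would remove the cortical signal along with the systemic
  one;
* a **cardiac** oscillation (1 Hz) with per-channel phase (pulse-arrival
  variation), which both marks good scalp contact for quality control and is
  deliberately *not* rank-1, so the variance-ranked PCA cut removes the
  systemic waves before touching the heartbeat;
* white measurement noise (`noise_sd`, default 0.1 µM);
* **motion artifacts**: Poisson-timed exponential spikes (≤ 2 s) and
  persistent baseline steps, injected into both chromophores with the same
  sign, as optical coupling events are chromophore-unspecific;
* **bad channels** (probability `bad_channel_prob`): no cardiac or cortical
  component, inflated noise — the ground truth for the exclusion-logic tests.

Amplitudes (Mayer 3.0, respiration 0.8, cardiac 0.5, cortical SD 0.4 µM) were
chosen once so that the Mayer wave dominates total OD variance — the premise
of variance-ranked systemic filtering — while the cardiac line stays clearly
detectable; they are exposed through `sim_params(amplitudes = ...)`. HHb is an
anticorrelated scaled copy of O₂Hb (ratio −0.4) with its own private
component; systemic interference drives HHb with positive ratio 0.5.
Concentrations map to two-wavelength intensities by inverting the modified
Beer–Lambert law with the same extinction table, 3 cm separation and partial
pathlength factors [6, 6] that preprocessing uses, so the generator–analysis
round trip is exact up to the deliberately injected nuisance signals.

Behavioral streams: binary speech series are two-state Markov chains at 10 Hz
with ~2 s mean bouts; default on-fractions (control 0.72/0.055, experimental
0.65/0.115, post-disruption ratio shift ×0.90 and ×1.33) reproduce the
study-scale observables — total speaking time near 460 s per 10-minute period,
Guide-dominated ratios rising after the disruption in the experimental group
only. The cursor follows the reference path at constant speed with smooth 2-D
jitter whose SD (0.02 screen units) rises by ×2.3 after the disruption for
experimental dyads, mirroring the observed error-score increase; the screen is
the unit square, as no pixel units are defined by the paradigm. Perceived
difficulty is a truncated normal on the 0–10 VAS with the group × period means
and SDs of the paradigm's difficulty profile. The reference path is an axis-aligned staircase
whose every turn coincides with an icon; 202 icons exist, 41 remain after the
disruption.

What the generator does **not** emulate: hemodynamic response convolution
(cortical dynamics are band-limited Gaussian, not evoked responses), real
optode geometry or light transport, serially-correlated physiological
amplitude drift, speech–motion coupling, or non-Gaussian artifact shapes.
Passing tests therefore demonstrate that the *analysis machinery* recovers
known structure under realistic noise — not that it would be unbiased on any
particular real dataset.

## Preprocessing (steps 1–7)

1. **Optical density**: $OD(t) = -\ln(I(t)/\bar I)$ with the per-channel mean
   intensity over the whole recording as reference (the reference window is
   not otherwise constrained).
2. **Motion artifacts**: per channel, windows of `t_motion` = 0.5 s are
   flagged when the excursion exceeds `sd_thresh` = 20 × SD of the
   first-differenced signal or `amp_thresh` = 0.5 OD; flags are dilated by
   `t_mask` = 2 s. Flagged segments are corrected by subtracting a smoothing
   spline (p = 0.99; `smooth.spline` with λ = (1−p)/p; p = 0 degenerates to
   linear detrending), re-levelled to the adjacent clean mean over a 10-s
   window (a full Mayer cycle, so the level estimate is unbiased by the
   dominant oscillation). A residual step across the segment is removed from
   all subsequent samples only when it exceeds three standard errors of the
   window means — so baseline shifts are repaired but spike corrections do not
   inject spurious steps. A wavelet pass follows: a periodized Daubechies
   (8-tap) pyramid whose depth leaves frequencies below ~0.12 Hz in the
   approximation, with detail coefficients outside the Tukey fences
   (`wavelet_iqr` = 1.5) zeroed. On clean band-limited signals the distortion
   is below 5% RMS while isolated spikes shrink more than five-fold. The
   transform is written in the package because no wavelet library ships with
   the target environment; it is orthogonal and reconstructs to machine
   precision.
3. **Systemic PCA**: per wavelength, the leading principal components whose
   cumulative variance first reaches 80% are *removed*. fNIRS pipelines
   describe this step ambiguously — "preserving 80% of variance" can mean
   retaining the leading components or removing them — so both modes are
   implemented (`pca_mode = "remove"`, the filtering convention, is the
   default). Removal operates per wavelength on OD, before concentration
   conversion.
4. **Modified Beer–Lambert**: per channel and sample the 2×2 system
   $OD_\lambda = (\varepsilon_{\lambda,O_2Hb} C_{O_2Hb} +
   \varepsilon_{\lambda,HHb} C_{HHb})\, d\, \mathrm{ppf}_\lambda$ is solved
   with d = 3 cm, ppf = [6, 6] and a standard compiled extinction table
   (760 nm: 0.586/1.5485; 850 nm: 1.058/0.6913 mM⁻¹cm⁻¹), giving µM.
5. **Channel quality**: Welch PSD of each O₂Hb channel (30-s Hann segments,
   50% overlap). "Presence of a peak around 1 Hz" is operationalized as
   maximal power in 0.8–1.2 Hz at least twice the median power of the
   surrounding 0.4–2 Hz band. On synthetic ground truth this rule attains
   sensitivity and specificity above 0.9.
7. **ROI averaging**: good channels are averaged per ROI; ROIs with only bad
   channels are discarded; participants with more than one missing ROI are
   excluded, and their dyads leave the analysis — the exclusion flow bad
   channels → discarded ROIs → excluded participants → excluded dyads.

## Wavelet coherence and the cone of influence

The coherence estimator follows the standard recipe: analytic Morlet wavelet
(ω₀ = 6), 12 voices per octave, squared cross-spectrum over the product of
auto-spectra, all smoothed in time by a Gaussian matched to scale and across
scale by a boxcar spanning 0.6 octaves. Two conventions deserve comment:

* **Time-smoothing span.** The Gaussian SD is `time_smooth` × scale with
  default 2.5. The minimal span (1 × scale) leaves the null expectation of
  squared coherence near 0.5, which would compress the usable dynamic range;
  with 2.5 the level of independent band-limited signal pairs settles near
  0.25, the coherence level characteristic of non-interacting pairings in
  this paradigm, while self-coherence stays at 1. The span is a visible,
  logged parameter.
* **COI convention.** The one-sided edge-effect duration is fixed to
  $\tau(f) = \sqrt 2 / f$, rounded up to whole seconds: 142 s (2 min 22 s) at
  0.01 Hz and 18 s at 0.08 Hz. This is the convention that reproduces the
  protocol's a-priori estimate and motivates the 3-minute rests; the
  Torrence–Compo e-folding time ($\sqrt 2 s \approx 1.37/f$) would give
  137 s. Cells with $f < \sqrt2/\mathrm{dist\ to\ edge}$ are excluded
  *before* the record is cropped to the task window, so rest periods absorb
  the edge effects; with 180-s rests no in-task cell is lost at any conserved
  frequency.

Coherence is computed on the full recording including rests, then cropped —
the interpretation implied by the edge-effect rationale. Batch computations
of band-averaged levels (`batch_ibs_levels`) first low-pass and decimate the
series (the band tops out at ~0.095 Hz, far below Nyquist), which leaves
levels unchanged to <1e-3 while cutting cost ~16-fold; full `wtc_result`
objects for slope and recurrence analysis are computed at the native rate.

## IBS features

* **Level** is the mean coherence over valid (in-band, outside-COI) cells of
  a period, before vs after the disruption.
* **Slope** is the OLS slope of the frequency-averaged coherence series,
  reported in coherence units per second (per-second rather than per-sample
  for sampling-rate independence). At least 10 valid samples are required;
  fewer yields a flagged missing value.
* **%DET** comes from recurrence quantification with embedding dimension
  m = 1 (the coherence series is already a slow scalar state variable),
  minimum diagonal line length 40 samples (≈5.1 s at 7.81 Hz), Theiler
  window 1, and a radius selected per signal by bisection to a target
  recurrence rate of 0.10 ± 0.005. The target rate is an assumption —
  radius-selection routines in common use do not fix one — and is
  exposed in `rqa_params()`. RR dispersion across dyads can be inspected from
  the feature table (`rr` column) to verify comparability. The recurrence
  plot is traversed diagonal-by-diagonal, so no N×N matrix is materialized;
  on short series the counts match an exhaustive reference implementation
  exactly. Note that %DET at lmin = 40 is only informative for series whose
  dynamics span many samples — exactly the situation of heavily smoothed
  coherence series; white-noise-like series are driven to %DET ≈ 0.

* **Permuted dyads**: all Guide × Drawer pairings that never interacted —
  n(n−1) pairs for n dyads — evaluated on the pre-disruption window only.
  Simulation miniatures subsample these pairs for tractability; the subsample
  size is recorded in each run.

## Statistics

The inference program is a fixed set of likelihood-ratio ANOVAs of full vs
reduced linear mixed models —

* control: `level ~ DyadType + (1|ROI)` vs `level ~ 1 + (1|ROI)` on
  pre-disruption real + permuted levels;
* manipulation checks: `outcome ~ Time × Group + (1|Dyad)` vs main effects,
  for the error score, total speaking time and speech ratio, and
  `(1|Individual)` for perceived difficulty;
* hypothesis tests: `feature ~ Time × Group + (1|Dyad/ROI)` vs main effects
  for level, slope and %DET, falling back to crossed `(1|Dyad) + (1|ROI)` on
  convergence failure, the standard remedy when the nesting is too thin to
  identify;
* moderation: `feature ~ Time × Group × Delta + (1|Dyad) + (1|ROI)` vs the
  model without the Delta terms (a 4-df comparison under the full factorial
  expansion).

Comparisons default to **ML** fits: REML likelihoods are not comparable
across fixed-effect structures; REML comparisons remain available behind
`reml = TRUE` for strict procedural replication, but are not the default. Standardized effects are β·sd(x)/sd(y) with Wald 95% intervals;
marginal R² is the fixed-effects variance fraction; the partial R² of a term
is the marginal-R² difference of full and reduced models, floored at zero.

`simulate_feature_table()` generates outcome tables directly from the
mixed-model data-generating process (dyad and ROI-within-dyad intercepts plus
residual), which is what calibration and power must exercise — the type-I
error of the Time × Group LRT sits inside [0.02, 0.09] at α = 0.05 over 200
replicates, and `sensitivity_simulation()` reports power across an effect
grid with the minimal detectable effect interpolated at 0.8 power — the
simulation-based sensitivity analysis the null findings call for.

## Problem sizes and numerical choices

Simulation-based checks use sizes chosen to make each property decisive while
keeping a complete run of the suite in minutes: coupling recovery uses 30
dyads per κ ∈ {0, 0.3, 0.6, 0.9} at the full 26-minute protocol; the
real-vs-permuted miniature uses 20 dyads at κ = 0.6 over 20 seeds with 40
permuted pairs per seed; calibration uses 200 feature-level replicates of 40
dyads. FFT lengths are padded to powers of two (R's mixed-radix FFT degrades
badly on lengths with large prime factors — the 7.81 Hz protocol length
12184 = 2³ × 1523 is such a case). The smoothing kernels and boundary
renormalization weights are precomputed once per series geometry. Degenerate
inputs are handled explicitly: constant series flag a degenerate radius,
all-zero signals produce empty motion masks, a Drawer who never speaks flags
the speech ratio invalid rather than dividing by zero, and rank-deficient
fixed-effect designs are rejected with the collinear terms named.

## Known limitations

* The generator's coupling is stationary within periods; transient IBS
  dynamics (and any sliding-window analysis of them) are out of scope.
* Only homotopic, undirected, zero-lag coherence is computed.
* No short-separation-channel regression exists in the chain, matching the
  study's acquisition; the PCA filter is the only systemic control.
* The %DET timescale interpretation (native-rate lmin = 40) is one of several
  defensible readings; it is pinned and documented rather than resolved.
* Real recordings exhibit slow nonstationarities and artifact families the
  generator does not produce; quantitative recovery rates reported by the
  tests are generator-specific.
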