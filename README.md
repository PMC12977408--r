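# nirsync

Interbrain synchrony (IBS) analysis for dyadic fNIRS hyperscanning.

Two people collaborating on a task — here a Guide verbally steering a Drawer
along a hidden reference path — show coherent low-frequency hemodynamics in
homotopic cortical regions. `nirsync` implements the full analysis chain for
such studies: it simulates two-person 16-channel fNIRS recordings with known
interbrain coupling, preprocesses raw two-wavelength intensities into
ROI-averaged oxy-/deoxyhemoglobin series, quantifies IBS by wavelet transform
coherence (WTC) in the 0.01–0.08 Hz band with cone-of-influence exclusion,
derives three IBS features per region and task period, builds the
permuted-dyad null, computes communication and path-accuracy behavioral
features, and runs the complete mixed-model inference program.

## The quantities at the core

For homotopic ROI series $x$ (Guide) and $y$ (Drawer), squared wavelet
coherence is

$$R^2(s,t) = \frac{\left|S\!\left(s^{-1} W_{xy}(s,t)\right)\right|^2}
  {S\!\left(s^{-1}|W_x(s,t)|^2\right)\, S\!\left(s^{-1}|W_y(s,t)|^2\right)},$$

with analytic Morlet transforms $W$ (ω₀ = 6, 12 voices/octave) and smoothing
$S$ in time (Gaussian matched to scale) and scale (0.6-octave boxcar). Cells
inside the cone of influence — within $\tau(f) = \sqrt{2}/f$ seconds of the
record edges, 2 min 22 s at 0.01 Hz — are excluded, which is why recordings
flank the 20-minute task with 3-minute rests. Three features are computed per
dyad × ROI × period (before/after the 10-minute disruption):

* **level** — mean coherence over time and frequency;
* **slope** — OLS trend of the frequency-averaged coherence series
  (coherence/s);
* **%DET** — percent determinism from recurrence quantification of that
  series (m = 1, lmin = 40 samples, Theiler window 1, radius selected per
  signal for a recurrence rate of 0.10).

Genuine interaction is established against *permuted dyads* — all n(n−1)
pairings of Guides and Drawers who never interacted — and hypotheses are
tested by likelihood-ratio comparisons of linear mixed models
(`feature ~ Time × Group + (1|Dyad/ROI)` against the no-interaction model,
and companions for behavioral outcomes).

## Worked example

Simulate a small study (8 dyads, 10-minute task, disruption halfway,
interbrain coupling κ = 0.5 in both groups) and run the whole pipeline:

```r
library(nirsync)

params <- sim_params(n_dyads = 8, rest_duration = 180, task_duration = 600,
                     disruption_offset = 300, coupling_pre = 0.5, rng_seed = 42)
study  <- simulate_study(params)
res    <- run_pipeline(study, config = list(split_time = 300, task_duration = 600,
                                            permuted_per_guide = 3))

head(res$features, 4)
#>   dyad_id   group     roi period level     slope pct_det
#> 1 dyad001 control fpPFC_L    pre 0.270  0.000215   0.889
#> 2 dyad001 control fpPFC_L   post 0.289  0.000124   0.785
#> 3 dyad001 control dlPFC_L    pre 0.256  0.000113   0.805
#> 4 dyad001 control dlPFC_L   post 0.287 -0.000299   0.896
```

The feature table holds one row per dyad × ROI × period: the coherence level,
its temporal slope, and the determinism of the coherence series. The control
analysis compares real against permuted pairings on the pre-disruption window:

```r
lv <- res$permuted_levels
mean(lv$level[lv$kind == "real"])      #> 0.279
mean(lv$level[lv$kind == "permuted"])  #> 0.239
res$stats$control$dyad_type$lrt        #> chi2(1) = 22.27, p = 2.4e-06
```

Real dyads carry ~0.04 more coherence than never-interacting pairings — the
coupling injected by the generator, recovered through the full chain
(Beer–Lambert inversion, motion correction, PCA systemic filtering, quality
control, ROI averaging, WTC). The manipulation checks and hypothesis tests
read the same way:

```r
res$stats$control$mean_error$lrt   #> chi2(1) = 61.62, p = 4.2e-15  (disruption degrades accuracy)
res$stats$hypothesis$level$lrt     #> chi2(1) = 1.92,  p = 0.17     (no coupling change was simulated)
```

The error-score interaction is large — the experimental group's cursor
degrades after the disruption by construction — while the IBS level shows no
Time × Group interaction, matching the generating model in which κ does not
change. `sensitivity_simulation()` quantifies what interaction size the
design could have detected.

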