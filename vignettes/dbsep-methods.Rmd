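---
title: "Evoked-potential biomarkers for DBS programming: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evoked-potential biomarkers for DBS programming: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Programming a subthalamic deep-brain-stimulation (DBS) system means finding,
for each hemisphere, the contact configuration and current that suppress
rigidity without provoking side effects. The clinical reference procedure is
the monopolar review: each contact of the directional 1-3-3-1 lead (eight
contacts: a distal ring, two triply segmented levels, a proximal ring, plus
the two segmented levels driven in ring mode — ten configurations in all) is
tested with increasing current. The current at which rigidity resolves is the
bottom of the therapeutic window (bTW), the current at which side effects
appear its top (tTW), and the therapeutic window is TW = max(tTW − bTW, 0).

This package implements, end to end, an analysis chain that predicts those
three outcomes per configuration from two cheap measurements:

* **Cortical evoked potentials (EPs).** Stimulating at 10 Hz for 50 s while
  recording 64-channel EEG yields 500 stimulus-locked epochs per
  configuration. Averaging reveals a short-latency positivity near 3 ms (P3)
  over ipsilateral motor cortex (F3/F4) and a long-latency positivity near
  10 ms (P10) over ipsilateral prefrontal cortex (AF7/AF8). P3 tracks
  recruitment of the dorsolateral motor target, P10 tracks spread into
  substantia nigra, which is side-effect-related.
* **Electric-field overlap with a sweet spot.** A field model at 1 mA per
  configuration, multiplied voxel-wise with a binary mask of the motor sweet
  spot and summed, gives one scalar per configuration ("EF overlap").

Outcomes are modelled at the group level with linear mixed models carrying a
random intercept per hemisphere, e.g. `tTW ~ P3 + (1|hemisphere)`, and the
EP-based, image-based and combined models are ranked by AIC.

Because no patient recordings are distributed, the package ships a
synthetic-cohort generator that emulates every input the pipeline consumes;
all tests and the acceptance report run against that generator.

## Signal chain

1. **Trigger detection.** The surface channel over the implanted pulse
   generator (EXG1) sees the stimulation artifact at millivolt scale. Onsets
   are the first crossings of `median + 8·MAD` of the rectified trace, with a
   refractory lockout of half the inter-stimulus interval. A fall-back to
   half the peak height covers noise-free (simulated) channels.
2. **Epoching.** Windows of −1 to +99 ms around each onset; 100 ms at 10 Hz
   means back-to-back epochs, and 50 s of stimulation gives exactly 500.
   Onsets whose window leaves the record are dropped and counted.
3. **Baseline correction.** The mean over [−1, 0) ms is subtracted per epoch
   and channel.
4. **Artifact reduction.** The two mastoid channels (EXG2/EXG3) see the
   artifact but negligible brain response. Their grand average is the
   template; per scalp channel one scale factor is fitted by least squares on
   the epoch average over the fit window (default −0.1 to 8 ms) and the
   scaled template is subtracted from every epoch. The residual pulse spike
   inside −0.1 to 1.5 ms is then replaced by linear interpolation. Template
   subtraction runs first: interpolation would destroy exactly the waveform
   the fit needs. On the synthetic mixtures this removes ≥ 20 dB of early
   artifact energy while biasing the 3 ms peak by well under 10%.
5. **Band separation.** Two 2nd-order Butterworth pairs: 150–1,000 Hz for the
   short-latency peak and 1–150 Hz for the long-latency peak. Filters are
   applied forward–backward (zero phase) with odd-reflection padding and
   steady-state initial conditions, so peak latencies — which define the
   analysis windows — are not shifted and constants map exactly to their
   steady-state response even on 100 ms epochs. Causal filtering would bias
   the 3 ms latency by a substantial fraction of the window.
6. **Peaks.** P3 is the maximum of the absolute averaged waveform on F3/F4
   within 2–5 ms, P10 on AF7/AF8 within 8–15 ms; ties break toward the
   earlier sample. Absolute amplitudes are the analysis quantity; a signed
   maximum is available by flag.

### The intensity screen

Per hemisphere and peak type, the clinical configuration is recorded at three
intensities: a 0.5 mA sub-threshold control, the rigidity-suppression
intensity, and the highest tolerated intensity. Each single epoch is sampled
at the averaged-EP peak latency and a one-way ANOVA across the three
intensity groups decides (at α = 0.05) whether the hemisphere contributes
that peak to the group analysis at all. Two choices here were open:

* *Which averaged EP defines the latency?* We use each intensity group's own
  average. Using only the highest-intensity latency would hand that group a
  selection advantage under the null (its latency is chosen where its own
  noise is largest) and inflate the false-inclusion rate.
* *What is a single-epoch amplitude?* The absolute value of the epoch at that
  latency. The screened quantity is deliberately simple; the screen's job is
  gross presence/absence, not estimation.

A structural note: because the template is estimated from finitely many
epochs, a small common-mode residual is shared by all epochs of a recording,
which couples epochs within an intensity group and inflates the ANOVA's
nominal size slightly. The effect scales with the square of the
scalp-to-mastoid artifact ratio, which is below one by construction (the
mastoids sit close to the IPG cable path), keeping the inflation to a few
percent. This is a property of the template method itself, not of the
simulation.

## The field model

Imaging pipelines treat the electric-field computation as a black box; here
it is an explicit point-source model. Each active contact is a current point
source in an infinite homogeneous medium of conductivity σ = 0.2 S/m (a
standard grey-matter value, configurable): the field of one source at
distance r is I/(4πσr²), sources superpose as vectors, radii below 0.2 mm
are clamped, and magnitudes are reported in V/mm on an isotropic 0.5 mm grid
spanning a 40 mm cube around the lead. Ring mode is weight 1/3 on each
segment of a level. Two properties carry all downstream meaning and are
tested exactly: linearity in current, and the multiply-and-sum overlap with
a binary mask. Absolute units cancel in the regressions, so any consistent
field convention preserves the model structure.

Masks can be read from NIfTI-1 files (a minimal reader/writer is included,
as no NIfTI package is available in the target environment); the synthetic
anatomy uses ellipsoid stand-ins, clearly labelled as such.

## The synthetic cohort: what it states, and what it does not

The generator is a stated world, not a tuning knob. Its defaults mirror the
acquisition protocol where the protocol states values:

* 12 hemispheres, of which 3 lack a P3 source and 1 lacks a P10 source
  (matching the reported 9/12 and 11/12 detection rates);
* 16,384 Hz sampling, 50 s of 10 Hz stimulation (500 epochs of 100 ms),
  64-channel 10–20 montage plus EXG1–EXG3, 60 µs biphasic pulses;
* ten configurations per hemisphere; monopolar cathodic mode with case
  return.

Where the protocol is silent, one realistic choice was made and frozen:

* **Anatomy.** A template space with the nominal lead tip at the origin and
  the shaft along +z. The sweet-spot stand-in is an ellipsoid centred
  dorsolateral at (1.5, 0.5, 6.0) mm with semi-axes (2.5, 2.0, 3.5) mm; the
  substantia-nigra stand-in sits ventral at (0, 0, −2.5), semi-axes
  (3.0, 2.5, 3.0), and follows the lead's lateral offset so its overlap
  gradient stays axial. Per-hemisphere variability is a Gaussian tip jitter
  (SD 0.5 mm) and a uniform segment rotation.
* **Couplings.** P3 coupling is linear in the hemisphere-normalised
  sweet-spot overlap (peak 4 µV at the 3 mA reference intensity); P10
  coupling is a square-root (concave) function of normalised
  substantia-nigra overlap (peak 6 µV), so dorsal clinical configurations
  retain a screenable P10 — as they must, given the reported 11/12 P10
  detections on clinical configurations. Responses scale linearly with
  intensity above a 1 mA activation threshold and vanish below it, which
  makes the 0.5 mA control genuinely sub-threshold.
* **Outcomes.** With `ov` the normalised overlap and `p10` the anatomical
  substantia-nigra coupling (µV),

      tTW = 3.0 + 2.5·ov − 0.25·p10 + u_t + ε
      bTW = 1.2 − 0.8·ov + 0.20·p10 + u_b + ε

  with hemisphere intercepts u ~ N(0, 0.5²) mA, residuals ε ~ N(0, 0.5²) mA,
  clipping at 0 mA and TW = max(tTW − bTW, 0). The sign structure encodes
  the reported relations: richer sweet-spot recruitment raises tTW and
  lowers bTW; nigral recruitment does the opposite. The outcome formula uses
  the *anatomical* nigral coupling even in the hemisphere without a
  measurable P10 cortical source — side effects arise from nigral current
  spread whether or not the scalp sees a P10.
* **Noise and artifact.** 1/f background at 2 µV RMS per channel
  (independent across channels; no volume-conducted noise model). The noise
  floor is the one generator constant with no protocol anchor; it was set
  once so that the three-intensity screen retains, at the desk-scale epoch
  count used by the test suite (125 epochs), the sensitivity the full
  500-epoch protocol would have at a higher floor — the screen's
  source-pattern invariant and the desk-scale runtime budget jointly pin it.
  Per channel there is also a biphasic
  artifact kernel with an 0.8 ms exponential tail, per-hemisphere spatial
  amplitude patterns of 50–150 µV/mA on scalp, 375–750 µV/mA on the
  mastoids and 2,000 µV/mA on EXG1. Evoked bumps are Gaussian kernels (FWHM
  1.5 ms for P3, 4 ms for P10) with a fixed spatial spread to named
  neighbour channels — a mixing pattern, not a forward model.

What a green test therefore establishes: the pipeline recovers what this
generative structure implies (counts, peak parameters, screen pattern,
slope signs, AIC ordering). What it does not establish: performance under
real-EEG pathologies that the generator does not emulate — correlated
cross-channel noise, movement artifacts, drifting electrodes, template
shapes that differ between mastoid and scalp, or lead localisation error.

One structural fact surfaced by the generator is worth recording: at a
stimulation rate of exactly 10 Hz, background-noise components at harmonics
of 10 Hz are phase-locked to the epochs and do not average out; their
coherent bandwidth shrinks as 1/(total duration). At the full 50 s this is
negligible, and at the 12.5 s used in scaled test runs it is still small,
but runs much shorter than that degrade the screen first through this
mechanism, not through per-epoch noise.

## Mixed models

All fits use maximum likelihood (not REML) so that AIC values are comparable
across fixed-effect structures. Fixed-effect t statistics use residual
degrees of freedom (n − number of fixed effects); with 90–120 rows the
difference from finer df approximations is cosmetic, and no Satterthwaite
implementation is available in the target environment. Two R² flavours are
reported and labelled: *conditional* (squared correlation between fitted
values including the random intercepts and the observations — the headline
number) and *marginal* (fixed-effect variance over total variance); which
definition the original analyses used is unknowable from the outputs, so
both are exposed. Singular fits are flagged, never silently accepted.

Missing data are handled per model: each model uses every row where its own
predictors exist, which is what produces the differing group sizes (120 rows
for field-only models, 90 for P3 models, 110 for P10 models with the default
source pattern). Because AIC comparisons across different row sets are not
well defined, `compare_models(common_rows = TRUE)` optionally refits all
candidates on the intersection first; the default reproduces the per-model
policy.

The parameter-recovery suite fits the generator's own predictors
(normalised overlap, anatomical nigral coupling) on measurement-noise-free
tables — it calibrates the estimator, so the generating slopes must sit in
their 95% confidence intervals at the nominal rate. The sign-pattern and
AIC suites use measured amplitudes with 0.3 µV measurement noise. A caveat
noted in development: the raw overlap score enters the fitted models, but
couplings are driven by within-hemisphere *normalised* overlap, so the raw
slope is hemisphere-dependent; recovery is therefore asserted against the
matched predictor, and the sign/AIC properties against the realistic one.

## Numerical choices and degenerate inputs

* Butterworth biquads are designed by bilinear transform with pre-warping;
  coefficients were verified against an independent reference
  implementation to 10⁻⁷.
* Zero-phase filtering uses odd-reflection padding (9 samples) plus
  steady-state initial conditions; both the R reference path and the C++
  fast path are tested for bit-level agreement.
* The artifact kernel is rendered at an oversampled rate (so that a 60 µs
  pulse cannot cancel inside one sample at reduced rates) and
  integrate-and-dumped to the recording rate.
* Peak ties break toward the earliest latency; flat windows report zero
  amplitude at the window start.
* A zero-energy artifact template, an all-zero trigger channel, a screen
  group with zero variance, fewer than two hemispheres (or rows per
  hemisphere) for a mixed model, grids that do not match between field and
  mask, and negative generator SDs all raise explicit errors.
* All randomness flows from explicit integer seeds; identical inputs give
  bit-identical recordings, tables and CSV outputs.

## Known limitations

* The point-source field ignores tissue anisotropy, the lead body and
  encapsulation; only linearity and the overlap functional are claimed.
* The spatial EP spread is a fixed mixing pattern; no volume conduction.
* The screen's slight size inflation under template-noise coupling (above)
  is inherent to template subtraction with finitely many epochs.
* A rank-correlation property between sweet-spot overlap and noise-free tTW
  holds exactly on the default pose and whenever the nigral slope is zero;
  with jittered poses and both covariates active, near-tie configuration
  pairs can swap ranks — a direct consequence of the two-covariate outcome
  model, retained deliberately.
* Ring-mode equals equal-current steering by symmetry; hardware current
  imbalances are out of scope, as are image registration, atlas rendering
  and any real-imaging ingestion.
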