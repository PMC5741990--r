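---
title: "Models and methods behind trfnirs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trfnirs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trfnirs)
```

This vignette documents the models implemented in **trfnirs**, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical and design choices that were genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

A time-resolved fNIRS instrument records, every 300 ms frame, one DTOF per
channel and wavelength: a histogram of photon arrival times with 16 ps bins
over the 12.5 ns window of an 80 MHz pulse train. The statistical moments
of a DTOF over an integration window are

- N = Σ cᵢ (photon count),
- ⟨t⟩ = Σ tᵢcᵢ / N (mean time-of-flight),
- V = Σ tᵢ²cᵢ / N − ⟨t⟩² (variance),

with bin i located at `t0_offset_ps + (i − 1) · bin_width_ps`. Only the
change Δ⟨t⟩ relative to the lead-in rest baseline is carried downstream:
of the three moments it weights late (deep) photons most strongly relative
to its own noise, which is what makes it the moment of choice for cortical
activation.

**Integration window.** The instrument convention for integration limits is
not standardized, so `compute_moments()` uses a fraction-of-peak rule:
after subtracting a constant background (mean of the leading bins — at most
the first 10% of the window — that precede the DTOF onset), the window runs
from the first to the last bin reaching 1% of the corrected peak. Both
fractions are arguments, surfaced again in `moment_integration()`, and the
chosen window is returned with every `moment_frame`. The background
estimate deliberately uses only pre-onset bins: with a 12.5 ns window and a
3 cm channel, "the first 10% of bins" would otherwise straddle the pulse
itself.

## Signal conditioning

The chain is fixed in the order motion correction → band-stop → detrend
(`preprocess_series()`), and each stage logs its parameters.

**Motion-artifact reduction** (`mara_correct()`): frames whose moving
standard deviation (window 2 s) exceeds `threshold_factor = 3` times the
run-median moving SD are grouped into artifact segments; inside each
segment a smoothing-spline trend (`spar = 0.6`) is subtracted, and the
series is reassembled with constant offsets so that 3-frame boundary means
match. An artifact-free series is returned bit-identical. Two consequences
are worth knowing. First, after a corrected baseline *step*, the following
clean frames are re-leveled by a constant — the step cannot be removed any
other way — which is inconsequential for the baseline-referenced,
detrended quantities used downstream. Second, the detector presumes the
moving SD is noise-dominated: on a strictly noiseless series the run-median
moving SD is near zero and the physiological response itself would be
flagged, so already-clean model series should skip the chain
(`preprocess = FALSE` where offered). Measured data are never in this
regime.

**Band-stop filter** (`bandstop_filter()`): Butterworth band-stop with
edges 0.08–1.5 Hz, applied forward–backward (zero phase, so block timing
feeds the correlation feature unshifted), after demeaning and odd
reflection padding of two periods of the lower edge. The upper edge sits
below the 1.667 Hz Nyquist frequency of the 300 ms frame interval. The stop
band covers the three physiological oscillations modelled in the simulator
(Mayer waves ≈ 0.1 Hz, respiration ≈ 0.2 Hz, cardiac ≈ 1 Hz) while passing
the 1/60 Hz fundamental of the 30 s/30 s block design. A single band-stop
(not cascaded notches) was chosen because the band between the
physiological components carries no task information here. The default
order is 5 per edge: the filter contract asks for at least 20 dB of
two-pass attenuation at 0.1 Hz, and order 4 measures −17.3 dB there
(order 5: −20.9 dB, largest pole modulus 0.956, safely stable).

**Detrend** (`detrend_series()`): least-squares polynomial removal, order 1
by default ("slow drifts" read as linear), configurable to 3.

## The layered head model and sensitivity factors

The head is a slab of ten 0.2 cm layers (scalp 1–2, skull 3–4, brain 5–10);
the deepest layer extends to infinity. The baseline optical properties are
literature-typical and declared in `head_model()` — absorption 0.11–0.19
cm⁻¹, reduced scattering 7.4–11 cm⁻¹ depending on tissue class and
wavelength, refractive index 1.4 with index-matched boundaries — because no
patient-specific values are available; they are configuration, not physics
buried in code.

`run_photon_mc()` traces photons with isotropic scattering at the reduced
scattering coefficient (similarity relation) and **no absorption during
tracking**; each packet detected in the annular detector ring (3 ± 0.5 cm)
carries its per-layer path lengths L_k. Absorption enters only afterwards
as the weight `exp(−Σ μa,k L_k)`, so a single photon set serves every
absorption vector: the DTOF simulator, the sensitivity factors, and every
frame of a recording reuse the same paths. Paths are abandoned beyond 8 ns
of flight time; at baseline head absorption the weight at 8 ns is below
1e-10, so no moment is affected. The tracker uses its own counter-based
generator (xoshiro256+), so a seed fully determines the photon set
independently of R's RNG state.

The sensitivity factor of layer k is SF_k = −∂⟨t⟩/∂μa,k, estimated by
central differences at ±0.005 cm⁻¹ with shared paths (a strongly
correlated estimator whose Monte Carlo error is reported per layer from a
per-photon influence-function linearization). SF_k is positive: more
absorption preferentially removes late photons and shortens ⟨t⟩. Two
checks pin the physics down, both recomputed by the acceptance suite: the
layer sum must equal the global-absorption derivative (chain rule), and for
a homogeneous semi-infinite medium the global derivative must match the
extrapolated-boundary time-domain diffusion solution
(`td_diffusion_moments()`) — an independent closed form, not a fit.

The intracerebral SF is the sum over layers 5–10, i.e. depths from 0.8 cm
down. (Layer indexing is 1-based from the surface; describing these layers
as "below 1 cm" is approximate — the explicit indices govern.) Conversion
then proceeds per wavelength as Δμa = −Δ⟨t⟩/SF and per frame as
[ΔHbO; ΔHbR] = E⁻¹[Δμa(760); Δμa(830)], with E the extinction table
(compiled hemoglobin spectra, cm⁻¹ per µM, source and condition number
recorded on the object).

**Window-consistent sensitivity factors.** When the measured moments are
computed over a fraction-of-peak window, the SFs must be evaluated under
the *same* rule (`integration` argument of `run_sensitivity_mc()`): the
window truncates the depth-sensitive late tail of the DTOF, and full-time
SFs would overestimate the sensitivity, biasing recovered amplitudes low.
Even with matched windows the recovery is calibrated only to first order —
the ±0.005 cm⁻¹ linearization and the filtering losses leave the recovered
ΔHbO amplitude below truth at activation-sized absorption changes (the
time-course shape and sign, which the decoder uses, are preserved; the
acceptance suite measures the correlation).

## What the simulator emulates — and what it does not

`simulate_activation_series()` builds moment-level series as

> amplitude × (task boxcar ⊛ HRF, unit peak) + Σ physiological sinusoids +
> Gaussian noise,

with the three sinusoids at 0.1, 0.2 and 1 Hz and noise SD in signal units.
The 1 Hz cardiac tone is representable at the 300 ms frame interval
(Nyquist 1.667 Hz) and no anti-aliasing is applied, since the simulation is
defined at the frame rate. The HRF is the canonical double-gamma
(`hrf_model()`: response gamma peaking ~5 s, undershoot gamma ~15 s,
ratio 1:6), a field-standard choice made configurable because only "the
hemodynamic function" is specified by the protocol. Open amplitude choices
are declared once and reported with every corpus: activation amplitude 5
and physiological amplitudes (1, 1, 1) in the same units as the noise SD,
which is drawn uniformly from [1, 10] per data set — a uniform draw being
the least-informative reading of "varying degrees of noise between 1 and
10". Sinusoid phases are randomized per draw (physiological background is
present in both classes). The reference corpus is 50 activation + 50 rest
series; per-item seeds are derived from the master seed and recorded, so a
corpus is byte-reproducible.

`simulate_dtof_recording()` emulates the raw instrument: per frame the
brain-layer absorption is baseline plus extinction-weighted ΔHbO/ΔHbR, the
frame's noiseless DTOF comes from reweighting the shared photon set, counts
are scaled so the baseline frame expects `photons_per_frame` detected
photons, and Poisson shot noise is drawn per bin. Real recordings contain
several things this generator deliberately omits: instrument response
functions and timing jitter, dark counts and ambient background, probe
coupling drifts, scattering changes, systemic physiology that correlates
with the task, and anatomical realism beyond a layered slab. Passing tests
therefore demonstrate that the *pipeline arithmetic and physics* are
right — not that patient data of any particular quality will decode.

## The classifier and the answer rule

Features per channel are CNR = (mean over task frames − mean over rest
frames)/SD over rest frames (all rest frames including the lead-in) and
the Pearson correlation r with the boxcar ⊛ HRF model, both computed after
the same conditioning chain used in training. The classifier is a
support-vector machine on the standardized two-feature space
(`e1071::svm`, cost 1). The default kernel is **linear** rather than
radial-basis: both features increase monotonically with activation
strength, and a linear boundary extrapolates correctly to responses far
stronger than any training example, whereas an RBF decision function decays
back toward the training bias far from the support vectors and can reject
an unambiguously activated channel. (RBF remains available via the
`kernel` argument.) A channel counts as activated only if the classifier
says so *and* its CNR is positive — the target response is an
oxyhemoglobin increase, and this guard prevents a "yes" driven by a
deactivation pattern. ΔHbR is reported but never fed to the classifier.

A question is answered "yes" iff at least one of the channels is activated;
summary CNR/r are averaged over the activated channels for a "yes" and
over all channels for a "no". One shared model serves all four channels,
which have nominally identical geometry.

`cycle_average()` folds a series over the 60 s task+rest cycle and reports
mean ± SEM per folded frame. Whether the 30 s lead-in is dropped before
folding is not dictated by the protocol; the default drops it (cycles then
align with task onset), and `include_lead_in = TRUE` folds from t = 0,
dropping the incomplete trailing cycle with a warning.

## Numerical choices and problem sizes

- Moment arithmetic is plain summation; the tests hold it to exact
  agreement with a direct-sum oracle on integer counts.
- The filter runs on demeaned, reflection-padded series so DC passes
  exactly and edge transients stay out of the retained frames.
- Finite-difference step for SFs: ±0.005 cm⁻¹, shared paths; MC standard
  errors accompany every profile, and seed-to-seed agreement is tested at
  3 pooled standard errors.
- Degenerate inputs fail loudly: empty DTOF windows, zero rest-period SD,
  zero-variance series, singular extinction matrices, stop bands beyond
  Nyquist, chromophore/timeline length mismatches.
- Problem sizes in the routine suite: 10⁵–3×10⁵ photons for transport
  checks and 10⁶ for the homogeneous-medium physics validation; 10⁶
  detected photons per frame and 1100 frames for the DTOF-level recovery;
  100 corpus sets and 100 decoding runs (noise SD ≤ 5) for the end-to-end
  evaluation. These sizes give Monte Carlo errors comfortably inside the
  asserted tolerances while keeping a full run at desk scale.

## Known limitations

- The slab geometry has no curvature, no CSF layer and no heterogeneity
  within a layer; sensitivity factors for a real head differ accordingly.
- Absorption reweighting is exact, but scattering changes would require
  retracing; they are out of scope.
- The artifact detector's relative threshold degenerates on noiseless
  input (see above) and its spline correction assumes artifacts are rare
  and segmentable; continuous motion is not correctable this way.
- Amplitude calibration of recovered hemoglobin changes is first-order
  only; the decoder consumes shape and sign, which are robust.
- The decoding evaluation is synthetic. Decoding rates on simulated
  questions say nothing about patient-level accuracy, which depends on
  probe placement, task compliance and physiology that the generator does
  not model.
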