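---
title: "Distinguishing fluid from solid breast masses with coherence imaging and gCNR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing fluid from solid breast masses with coherence imaging and gCNR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(slscgcnr)
```

## The problem

Benign fluid-filled breast masses with internal echoes (complicated
cysts) are notoriously hard to tell apart from hypoechoic solid masses
on conventional B-mode ultrasound: both appear as dark regions, and
acoustic clutter partially fills the cyst lumen. The clinical
consequence is uncertainty, two-year imaging follow-up, and biopsies or
aspirations of masses that are in fact simple fluid.

Short-lag spatial coherence (SLSC) imaging sidesteps the amplitude
ambiguity by displaying a different physical quantity: the spatial
coherence of the backscattered wavefront across the receive aperture.
Diffuse soft-tissue speckle is predicted by the van Cittert–Zernike
(VCZ) theorem to be highly coherent across nearby receive elements
(coherence approximately `1 - m/N` at element lag `m` for an unapodized
`N`-element aperture at the transmit focus), while a fluid cavity
returns only incoherent electronic noise. Solid masses scatter like
tissue — whatever their echogenicity — so they remain bright in SLSC
while fluid turns distinctly dark. The generalized contrast-to-noise
ratio (gCNR) of matched mass/tissue regions then turns that visual
difference into an objective number in [0, 1], and a fixed decision
threshold turns the number into a content call.

This package implements the full computational chain — RF channel-data
simulation, delay-and-sum B-mode, both SLSC formulations, gCNR, and the
threshold/ROC/agreement evaluation — so the comparison between
pathways can be reproduced end to end on synthetic cohorts.

## The two SLSC formulations

Both start from delay-aligned element signals `s_i(n)` (dynamic receive
focusing, no apodization).

**Offline formulation.** At each pixel, the normalized cross-correlation
between elements `i` and `i+m` is computed over a short axial kernel
(after subtracting each element's kernel mean — the coherence is defined
on zero-mean signals), averaged over the `N - m` pairs to give the
coherence function `R(m)`, and summed over lags `m = 1..M`:

    SLSC pixel = sum_{m=1}^{M} R(m),   R(m) in [-1, 1]

Negative pixels are set to zero. Pixels therefore lie in `[0, M]`.

**Real-time (GPU-style) formulation.** The order of normalization and
summation is reversed, which is what makes the computation map onto
parallel hardware: per depth sample and lag, the pair-summed
cross-correlation `C_ij` and pair-summed energies `C_ii`, `C_jj` are
accumulated, each is then summed over the axial kernel, and only then
is the ratio taken:

    SLSC pixel = sum_{m=1}^{M} Re[ sum_k C_ij / sqrt(sum_k C_ii * sum_k C_jj) ]

The real-time pathway operates on analytic (complex) signals — the
conjugate in the cross term implies complex data — and performs no mean
subtraction, because no such step appears in the formulation. These are
deliberate pathway differences, not bugs: the package treats the
offline/real-time discrepancy as a study object, quantified per mass as
`|gCNR_realtime - gCNR_offline|`. By Cauchy–Schwarz the per-lag ratio is
bounded by 1, so both pathways return exactly `M` on fully coherent
data — a convenient identity used in the tests.

Two shared conventions were chosen where the formulations are silent:
negative pixels are clipped to zero in *both* pathways (display and gCNR
comparability require one convention; the clipping is classically stated
for the offline path only), and any zero-energy pair or zero denominator
contributes 0 rather than NaN, so degenerate kernels cannot poison the
gCNR histograms.

### Parameters

* `M = 7` — the short-lag cutoff, 10% of the 64-element receive
  aperture. The standard operating point for breast SLSC.
* `kernel_samples` — axial correlation kernel; default one wavelength of
  two-way RF travel, `round(2 fs / f0)` = 6 samples at 40 MHz sampling
  and 12.5 MHz center frequency.
* Element indexing in the formulas is 1-based; the implementation is
  0-based internally with the translation confined to the accessors.

## gCNR and ROI protocol

`gCNR = 1 - sum_j min(h_mass(x_j), h_tissue(x_j))` over histograms of
the two ROI sample sets on shared equal-width bins spanning the pooled
range. Probability normalization (each histogram sums to 1) is forced by
the bound `sum min <= 1`. The histogram bin count is not fixed by the
definition; the package defaults to 256 equal-width bins (natural for
8-bit-comparable data), and a bin-stability test guards the choice
(changing 128 to 512 bins moves the Gaussian-fixture gCNR by < 0.03).
gCNR is computed on pre-normalization, pre-log pixel values for
beamformed images, and directly on grayscale values for the screenshot
surrogates.

The ROI protocol mirrors the clinical one: the mass ROI is an ellipse
within the mass (the lesion ellipse shrunk by a margin factor, default
0.8); the tissue ROI has the same shape, size and depth, laterally
offset with an edge-to-edge gap drawn from 0.9–8.2 mm; if no lateral
placement fits the field of view, the tissue ROI moves above/below the
mass at a depth gap under 5 mm and the fallback is recorded. The same
ROI pair is used for every pathway of a given mass.

## Decision rule and evaluation

A mass is called fluid when its SLSC gCNR is at or above the threshold
(ties count as fluid, consistent with "below threshold means solid").
The default threshold is 0.73, the previously established operating
point; 0.62, the ROC-derived alternative, is reported alongside.
Sensitivity is the fraction of fluid-truth masses called fluid,
specificity the fraction of solid-truth masses called solid; mixed
masses (a mixture of TP and TN by construction) and simple cysts
(trivially identified on B-mode) are excluded. ROC curves sweep the
threshold 0 to 1 in steps of 0.01; AUC is trapezoidal with (0,0) and
(1,1) anchors after sorting by false-positive rate; the "optimal"
threshold minimizes the Euclidean distance to the (0, 1) corner with
ties going to the smallest threshold.

Fleiss' kappa is implemented with the Landis–Koch interpretation bands
(poor / slight / fair / moderate / substantial / almost perfect at
0, 0.20, 0.40, 0.60, 0.80). The band listing sometimes quoted with five
labels for six ranges and a 0.80–0.81 gap is internally inconsistent;
Landis–Koch is the coherent reading and matches the usual "moderate"
label for kappa near 0.53.

## What the simulator emulates — and what it does not

The synthetic-data module replaces clinical RF acquisitions with a
single-scattering simulator on a linear array (128 elements, walking
64-element receive aperture, 12.5 MHz center, 40 MHz sampling, 0.3 mm
pitch — pitch is not standard-documented for this probe class, and only
relative geometry matters for the tested properties).

* **Tissue** is fully developed speckle: uniform random scatterers with
  zero-mean Gaussian amplitudes at 10 per resolution cell. The
  resolution cell uses pulse-echo (two-way) widths — `c/(4B)` axially
  and half the one-way beam width laterally — because the two-way cell
  is the speckle correlation cell that the scatterers-per-cell rule
  refers to; with the one-way cell the envelope SNR falls measurably
  short of the Rayleigh value 1.91.
* **Transmit** is a focused Gaussian beam with a diffraction-limited
  waist and geometric spreading away from the focus; receive uses the
  exact element–scatterer distances with fractional-sample (linear)
  interpolation. A full per-element transmit simulation is deliberately
  out of scope — the `1 - m/N` coherence check is delegated to an
  analytic fixture (below) because the simulated coherence profile
  depends on the transmit model.
* **Pulse**: Gaussian-modulated sinusoid at 60% fractional bandwidth,
  typical of high-frequency linear arrays.
* **Fluid lesions** contain no scatterers; their channels carry only
  electronic noise and clutter. **Solid lesions** scatter at a reduced
  echogenicity gain. **Mixed masses** are a fluid ellipse containing 1–3
  solid septa, emulating a cluster of cysts.
* **Noise**: iid electronic noise at 20 dB channel SNR (relative to
  tissue RF rms) and one fully element-coherent clutter waveform per
  scan line at −25 dB. The defaults were fixed once against the
  module's own contracts: with electronic noise alone, the short-lag
  coherence inside a fluid lesion must stay below 0.2 (it measures
  ≈ 0.02 at these settings), while clutter must degrade B-mode contrast
  without masking the coherence contrast. Raising clutter much beyond
  −25 dB mainly decorrelates the interior of hypoechoic *solid* masses
  (the clutter is no longer negligible against their reduced echoes),
  which inverts the intended effect — hence the conservative default.
* **Cohort**: one phantom per mass, lesion semi-axes 1.8–3.2 mm, centers
  at 12–18 mm depth, transmit focus at the lesion depth (the clinical
  protocol places the focus within 1 cm of the mass). Solid gains are
  drawn uniformly from 0.35–0.85 (≈ −9 to −1.4 dB), spanning markedly
  hypoechoic to near-isoechoic solids. Below ≈ 0.3 the simulated solid
  interior decorrelates appreciably — off-axis scattering from the
  surrounding unapodized aperture competes with the weak in-lesion
  echoes — which is real physics but not the coherence-preserving solid
  mass the clinical comparison is about.

Not modeled: elevation dimension, attenuation/TGC, harmonic
propagation, scan conversion, and the proprietary nonlinear display
filters of clinical scanners. The screenshot surrogate is only
log compression at 60 dB plus 8-bit quantization, so absolute
pseudo-real-time gCNR values from real clinical screenshots would not
match it. Passing tests therefore demonstrate the *method chain* under
controlled statistics, not clinical performance: the simulated cohort
separates fluid from solid essentially perfectly (AUC ≈ 1 at desk
scale), whereas clinical AUCs are lower because real masses and real
clutter are harder.

### The coherence fixture

Because the simulated absolute coherence profile is
implementation-dependent, the coherence estimator is validated against
an analytic fixture: zero-mean Gaussian element signals constructed
with an exact Toeplitz cross-element covariance equal to any prescribed
correlation profile (via the symmetric matrix square root), band-limited
axially to the probe passband. On the VCZ triangle `1 - m/64` the
estimator recovers the profile with mean absolute error well under
0.05, and the mean SLSC pixel lands at `7 - 28/64 = 6.5625` within the
small negative bias (~0.1) expected from normalized correlations over
six-sample kernels.

## Numerical choices and degenerate inputs

* Fractional delays: linear interpolation (testable against analytic
  sinusoids to 1e-3); delays outside the recorded trace zero-fill and
  set a `truncated` flag.
* Envelope: magnitude of the analytic signal along depth (FFT
  construction).
* Echo synthesis deposits each scatterer impulse on a 4x oversampled
  grid and convolves with the pulse by FFT; the implied amplitude
  ripple at the center frequency is < 3% with exact phase.
* Screenshot quantization: linear map of `[-DR, 0]` dB to 0..255,
  round-half-up; per-pixel quantization error is at most half a grey
  step (DR/510 dB).
* All-equal gCNR inputs return 0 with a warning; empty ROIs error.
* Every stochastic operation takes an explicit integer seed; per-mass
  seeds are split from the master seed by a fixed congruential rule, so
  experiments are bit-reproducible end to end.
* Desk-scale defaults: 64 scan lines and ~25 mm depth (the full
  256-line clinical grid is a `probe_config` away); the default cohort
  is 8 fluid + 16 solid masses. These sizes keep a full experiment
  within minutes while leaving every statistical contract testable.

## Open design points resolved here

* The real-time formulation's printed summation bound ("N_i − m" with a
  doubly-used index) is read as the sum over the `N − m` element pairs,
  the only reading consistent with the pair structure of the offline
  coherence function.
* "Correlation C_ii and autocorrelation C_ij" in common descriptions
  swaps the terms; `C_ij` is the cross term here.
* When two orthogonal views per mass are simulated (`n_views = 2`), the
  decision uses the view whose gCNR is closest to the active threshold —
  the most uncertain orientation, which is the conservative clinical
  choice.
* Transmit aperture size and apodization are unspecified in the
  emulated acquisition; the fixture-based validation makes the
  estimator's correctness independent of that choice.

## Limitations

The clutter model (one fully coherent interference waveform per line)
is the simplest construction that degrades B-mode differently from
SLSC; real acoustic clutter is spatially structured and only partially
coherent. Solid-mass echogenicity below ≈ 0.3 gain conflates
echogenicity with coherence in this simulator, as noted above. The
cohort's separability is by construction near-perfect, so cohort-level
metrics here exercise the pipeline rather than estimate clinical
operating characteristics.
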