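# slscgcnr

Fluid-filled breast masses (complicated cysts) mimic hypoechoic solid
masses on B-mode ultrasound, driving uncertainty, follow-up imaging and
unnecessary biopsies. Short-lag spatial coherence (SLSC) imaging
displays the spatial coherence of the backscattered wavefront instead of
its amplitude: diffuse tissue speckle is coherent across nearby receive
elements (the van Cittert–Zernike prediction `1 - m/N` at element lag
`m` for an `N`-element aperture), while fluid returns only incoherent
noise and turns dark regardless of how the mass looks on B-mode. The
generalized contrast-to-noise ratio

    gCNR = 1 - sum_j min( h_mass(x_j), h_tissue(x_j) )

of matched elliptical mass/tissue regions (histogram overlap on shared
bins) converts that contrast into an objective score in [0, 1], and a
fixed threshold (0.73, with 0.62 as the ROC-derived alternative) turns
the score into a fluid/solid content call.

This package is aimed at ultrasound-imaging researchers who want the
full computational chain reproducible in one place:

* **Synthetic RF channel data** — speckle phantoms with fluid, solid and
  mixed (septated) elliptical lesions, focused transmit, walking
  64-element receive aperture, electronic noise and coherent clutter
  (`make_phantom()`, `simulate_channel_data()`, `make_cohort()`).
* **Beamforming** — dynamic receive focusing (`receive_delays()`,
  `apply_delays()`), delay-and-sum B-mode with analytic-signal envelope
  (`das_bmode()`), log-compressed display and an 8-bit screenshot
  surrogate (`render_display()`, `render_screenshot()`).
* **Both SLSC formulations** — the offline coherence-function form
  (normalize per pair, then average and sum lags 1..M;
  `slsc_offline()`) and the real-time GPU-style form (sum correlations
  over pairs and kernel, then normalize; `slsc_realtime()`,
  `lag_sums()`), with `M = 7` and a one-wavelength axial kernel by
  default.
* **Quantification and evaluation** — the matched-ROI protocol
  (`place_rois()`), gCNR (`gcnr()`, `gcnr_for_mass()`), threshold
  classification (`classify_mass()`), sensitivity/specificity, ROC with
  trapezoidal AUC on a 0.01 threshold grid (`roc_curve()`,
  `optimal_threshold()`), and Fleiss' kappa with Landis–Koch bands
  (`fleiss_kappa()`).
* **An end-to-end experiment driver** — `run_experiment()` simulates a
  cohort, beamforms every pathway, applies one ROI pair per mass,
  computes per-pathway gCNR, and reports ROC/threshold tables and the
  offline-vs-real-time consistency. A thin CLI wrapper lives in
  `inst/scripts/slsc_pipeline.R`.

See the methods vignette (`vignettes/slsc-gcnr-methods.Rmd`) for the
model details, parameter choices and limitations.

## Worked example

```r
library(slscgcnr)

probe <- probe_config()                     # 64 scan lines, 64-el aperture
fluid <- lesion_spec(c(0, 15), c(2.5, 2.5), "fluid")

field <- make_phantom(probe, list(fluid), density = 10, seed = 100)
chan  <- simulate_channel_data(field, probe, focus_depth = 15,
                               noise = noise_spec(), seed = 101)
al    <- apply_delays(chan)

imgs <- list(bmode_offline = das_bmode(al),
             slsc_offline  = slsc_offline(al),
             slsc_realtime = slsc_realtime(al))
roi <- place_rois(fluid, imgs$bmode_offline, seed = 102)
round(gcnr_for_mass(imgs, roi), 3)
#> bmode_offline  slsc_offline slsc_realtime
#>         0.960         1.000         1.000
```

The fluid mass is almost perfectly conspicuous on SLSC (gCNR 1.0: the
mass and tissue histograms do not overlap at all) and slightly less so
on B-mode, where clutter and noise partially fill the lumen. A solid
mass at 70% tissue echogenicity in the same geometry gives gCNR ≈ 0.24
(B-mode) and ≈ 0.21 (offline SLSC) — well below the 0.73 threshold, so
it is correctly called solid.

A full simulated study:

```r
ex <- run_experiment(experiment_config(seed = 42))
summary(ex)
#> slsc_experiment: 24 masses (24 records), seed 42
#>   AUC bmode_offline          1.000
#>   AUC slsc_offline           1.000
#>   AUC slsc_realtime          1.000
#>   ...
#>   SLSC pathway agreement: median |dgCNR| = 0.013, 100% same call at 0.73
#>
#> Threshold report (fluid-vs-solid subset):
#>       pathway     threshold sensitivity specificity auc
#>  slsc_offline          0.73           1       1.000   1
#>  slsc_offline          0.62           1       0.938   1
#>  ...
#> Decision trace: 24/24 fluid/solid masses correct at 0.73
```

At desk scale the synthetic cohort is near-perfectly separable by
design; the value of the run is the pathway comparison (offline vs
real-time SLSC agree to a median gCNR difference of ~0.01) and the
threshold behaviour (one borderline solid sits between 0.62 and 0.73).

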