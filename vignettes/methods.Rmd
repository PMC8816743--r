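---
title: "Quantifying AIS mitochondria clustering and TAU sorting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying AIS mitochondria clustering and TAU sorting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aismito)
```

## The biological measurements

In cultured neurons, the axon initial segment (AIS) — the proximal 20–60 µm
of the axon marked by ANKYRIN-G/TRIM46 enrichment — gates the axonal sorting
of the microtubule-associated protein TAU. A subset of neurons carries a
stationary cluster of mitochondria in the proximal AIS, followed by a
mitochondria-poor central AIS, and impairing these specific mitochondria
perturbs TAU sorting so that TAU accumulates in the soma ("missorting", a
tauopathy hallmark). `aismito` implements the image-quantification pipeline
behind these observations:

1. **AIS start detection.** An intensity profile of the AIS-marker channel
   is taken along a hand-traced (or generated) polyline from the soma into
   the axon, smoothed with a 1 µm centered sliding mean, and the AIS start
   is the first arclength at which the smoothed profile reaches 30% of its
   maximum. The rule is scale-invariant (a fraction of the maximum) but not
   offset-invariant, so profiles must be background-free or the offset
   documented.
2. **Mitochondrial presence profiles.** The mitochondrial channel is
   thresholded per cell into a binary mask (accounting for
   intensity differences between cells), sampled along the same line-ROI as
   a 0/1 presence profile, aligned to the per-cell AIS start, and averaged
   across cells — replicate means first, then the unweighted mean of
   replicate means ("biological-replicate-weighted mean"). Aligned positions
   covered by fewer than `min_cells` cells are dropped rather than averaged
   over tiny n. Statistics use the mean of each replicate over 10 µm
   windows; the proximal window is centered on the AIS start and the central
   and distal windows are shifted by one fixed offset so window spacing is
   identical across experiments.
3. **Cluster classification.** Each valid cell is scored on three criteria:
   (1) mitochondria present in the proximal AIS (±7.5 µm of the start);
   (2) relative absence in the central AIS; (3) visibly
   brighter/accumulated proximal mitochondria. Cells meeting 3, 2 and ≤1
   criteria are classed `+`, `~` and `-`. The cohort statistic
   `Ratio = n_total / (n_+ + 0.5 n_~)` is reported exactly as defined
   (values ≥ 1), together with its reciprocal `positive_fraction`, which
   lives on the 0–1 scale of a fraction of cells showing the morphology;
   the two describe the same quantity and their product is 1.
4. **Somatic intensity fold-changes.** Somatodendritic ROIs are found via
   MAP2; somatic TAU intensity is background-corrected (annotated background
   ROI, else the mean of the lowest decile of non-cell pixels, computed per
   image) and normalized to the mean of control cells, making the control
   mean exactly 1 and cancelling global offsets and gains.
5. **Axon caliber.** The volume-marker channel gives a diameter every 1 µm
   as the full width at half maximum of the perpendicular intensity cut;
   cross-sectional area is extrapolated as `(d/2)² · 0.6 · π`.
6. **Trafficking.** Two-channel time-lapse movies (photoconverted cluster
   mitochondria red, all others green) are turned into per-channel
   kymographs (max projection across a narrow band perpendicular to the
   axon path). Trafficking events that pass the cluster are detected,
   classified antero-/retrograde and cluster-/other-origin, and expressed
   as fractions of each cell's total events; cells without any movement are
   excluded rather than counted as zero.

## The synthetic-data generator

No raw images are deposited with the study this pipeline replicates, so the
package ships a scene generator that emulates the *statistical structure* of
the data and carries full ground truth. A scene is a five-channel frame
(MAP2, AIS, MITO, TAU, VOL) rendered from an explicit geometry: a soma disc,
smooth random neurite polylines with bounded curvature (so paths never
self-cross), flat-top tube cross-sections whose FWHM equals the nominal
neurite width, and Gaussian mitochondria puncta. The default conditions are

* 0.25 µm pixels, 96 µm field (384 px), one axon (60 µm) and three
  dendrites, soma radius 8 µm — typical of the epifluorescence data the
  pipeline was designed for;
* AIS onset 5 µm from the soma edge, rendered as a 1 µm linear ramp to a
  25 µm plateau (a step-onset fixture is kept in the unit tests); the ramp
  shape means the 30%-rule detector lands ~0.27 µm after the true onset,
  well inside the 0.5 µm acceptance band;
* baseline mitochondria at 0.15 puncta/µm with σ = 0.4 µm; a
  cluster-positive cell adds 6 puncta within ±7.5 µm of the AIS start at
  3× amplitude and keeps central-AIS baseline puncta with probability 0.3;
* somatic TAU at `tau_somatic_fold` times a fixed axonal reference (the
  treatment effect enters only here; axonal TAU is unchanged);
* somatic MAP2 at 2.3× the dendritic level;
* noise: Poisson shot noise on signal + background, Gaussian read noise
  (sd 2), constant background 10. Photobleaching is off by default.

Movies script every moving particle explicitly (start time/position, signed
velocity, duration, channel, origin), render a stationary red band at the
cluster, and flag events that would leave the axon as clipped.
`random_event_script()` additionally guarantees that every track crosses the
cluster span (only such events are counted) and that same-channel tracks
stay ≥ 8 µm apart in kymograph spacetime, so scripted ridges remain
resolvable; each event's origin is drawn up front so the cluster-origin
marginal is exactly the requested Bernoulli probability.

What the generator does **not** emulate: optics (no PSF; puncta are ideal
Gaussians), 3-D structure (the real data are projections and are treated as
2-D throughout), mitochondrial fission/fusion, pauses or speed changes
within a trafficking run, and photobleaching unless enabled. Passing
recovery tests therefore demonstrates that the estimators are correct on
data obeying the stated generative model — not that they are robust to every
artifact of real microscopy.

## Numerical and design choices

* **Pixel conventions.** Coordinates are 0-based with pixel centers at
  integer coordinates; arclength 0 is the first path point (the somatic
  end); all distances are µm via one isotropic `pixel_size_um`.
  Anisotropic input is rejected.
* **Sliding mean.** Centered boxcar with truncated (shrinking) windows at
  the edges; a 1 µm window at 0.1 µm sampling spans 11 samples. Centered
  smoothing is the common plot-profile convention and preserves affine
  profiles in the interior; whether the original analysis used a centered or
  trailing window is not documented, so the window is a parameter.
* **Window layout.** Proximal = [−5, +5] µm around the AIS start; central
  and distal are shifted by a configurable offset (default 15 µm, giving
  [10, 20] and [25, 35]). The offsets are knobs because only the equality of
  spacing, not its value, is fixed by the source procedure.
* **Segmentation.** The trained pixel classifier of the original workflow is
  replaced by deterministic thresholding behind a pluggable config
  (`global_otsu` per-cell-normalized by default, `adaptive_local` and
  `fixed` as alternatives) — reproducible without training data, and the
  downstream statistics consume only the binary mask. MAP2 somata are found
  by erosion (neurites are thin and vanish under a 1.2 µm erosion) followed
  by area ≥ 80 µm² and eccentricity ≤ 0.9 gates; MAP2-positive pixels
  outside a 2 µm margin around accepted somata form the dendritic mask. The
  MAP2-positive threshold is background-relative (30% of the way from
  background to the 99.5th percentile) because Otsu splits soma from
  dendrites, not signal from background, on histograms dominated by
  background.
* **Cluster criteria defaults.** The source criteria are visual; the
  numeric defaults (proximal presence ≥ 0.3, central ≤ 0.5 × proximal,
  proximal peak ≥ 1.5 × the 90th-percentile intensity of
  mitochondria-occupied positions outside the proximal window) were
  calibrated once against the generator so that its strong-cluster and
  no-cluster classes separate cleanly, and are exposed as configuration.
  Comparing the proximal peak against mitochondria-occupied positions
  (rather than the whole-profile median) keeps criterion 3 a
  mitochondria-vs-mitochondria comparison, as "visibly brighter than
  comparable mitochondria" demands; with a whole-profile reference the
  criterion is trivially true for any punctate channel.
* **Kymograph detection.** Stationary structure is removed by per-row
  temporal median subtraction (the anchored cluster band is, by
  construction, never an event), the remainder is Otsu-thresholded, and
  ridge pixels are re-linked across frames with a vertical dilation sized to
  half the per-frame displacement of the fastest expected particle
  (`max_speed_um_s`, default 0.8 µm/s) — fast movers shift by many rows per
  frame and are otherwise not 8-connected. Gates: net displacement ≥ 2 µm,
  |fitted speed| ≥ 0.1 µm/s, ≥ 3 frames, distance range overlapping the
  cluster span (padded by one frame of travel to absorb sampling
  quantization at the span edge). Crossing same-channel tracks are not
  disambiguated (the original counts were manual, leaving no oracle); the
  scripted test movies keep concurrent tracks separated instead, and this is
  a known limitation for dense real movies.
* **Statistics.** Tests map figure-legend names onto standard procedures:
  Welch t-test, ordinary one-way ANOVA with Dunnett (single-step, via
  multcomp) or Tukey corrections, and a heteroscedastic variant pairing
  Welch's ANOVA omnibus with Sidak-adjusted Welch-t contrasts against
  control (a close, slightly conservative stand-in for Dunnett's T3, whose
  studentized-maximum-modulus tables no installed backend provides).
  Shapiro–Wilk normality checks are reported per group. The unit of
  analysis defaults to cells, with a flag for replicate means, because the
  profile statistics are explicitly computed on replicate means while the
  intensity statistics quote per-cell n.
* **Problem sizes.** The shipped recovery experiments use 45-cell cohorts
  for presence probabilities, 50 + 50 cells for classifier operating
  characteristics, 40 cells/arm for fold-changes, 20 scripted movies (up to
  10 events) plus 25 × 20 events for trafficking fractions, and 1000
  simulated null datasets for the type-I check — sizes at which the binomial
  error bands used in the assertions are meaningfully tight.

## Known limitations

* The AIS-start detector inherits the bias of the 30% rule: on ramp-like
  onsets it reports a point ~0.3 µm into the ramp; on offset-contaminated
  profiles it can collapse to arclength 0 (flagged with a warning).
* The cohort ratio as defined is ≥ 1 while a "fraction of cells showing the
  cluster" lies in [0, 1]; the two are reciprocals and both are emitted, so
  consumers can match whichever scale their comparison data use.
* Event detection assumes piecewise-linear runs; pausing particles are
  merged into one event or split at the pause depending on the gap, and
  sub-pixel localization is not attempted.
* The somatic fold-change estimator divides by the control mean; it refuses
  to run when the control corrected mean is non-positive rather than
  guessing a rescue.
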