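# aismito

Quantification of mitochondrial clustering at the axon initial segment (AIS)
and of axodendritic TAU (mis)sorting from multi-channel fluorescence
microscopy of cultured neurons.

In a subset of cortical neurons, mitochondria form a stationary cluster in
the proximal AIS (within ±7.5 µm of the AIS start) followed by a
mitochondria-poor central AIS, and the integrity of these specific
mitochondria matters for keeping TAU out of the somatodendritic compartment.
`aismito` implements the measurements behind such observations as a tested,
scriptable pipeline:

* **AIS start** from an AIS-marker line profile: 1 µm centered sliding mean,
  start = first arclength where the smoothed profile is ≥ 30% of its
  maximum.
* **Mitochondrial distribution**: per-cell thresholding into binary masks,
  0/1 presence profiles along the axon, alignment to the AIS start,
  biological-replicate-weighted averaging, and 10 µm window means
  (proximal / central / distal).
* **Cluster classification** per cell by three criteria (proximal presence,
  central absence, proximal brightness), categories `+` / `~` / `-`, and
  the cohort statistic `Ratio = n_total / (n₊ + 0.5·n~)` together with its
  reciprocal `positive_fraction`.
* **Somatic intensity fold-changes** (e.g. TAU after mitochondrial
  impairment): MAP2-derived somatodendritic ROIs, per-image background
  subtraction, normalization to control cells (control mean ≡ 1).
* **Axon caliber**: FWHM diameter of a volume marker every 1 µm and the
  cross-section extrapolation `area = (d/2)²·0.6·π`.
* **Mitochondrial trafficking** from two-channel time-lapse movies:
  kymographs along the axon, event detection with direction
  (antero-/retrograde) and origin (cluster vs other) calls, per-cell event
  fractions.
* **Statistics**: Welch t, one-way ANOVA with Dunnett or Tukey correction,
  heteroscedastic Welch ANOVA with against-control contrasts, replicate
  summaries.
* A **synthetic-microscopy generator** (`generate_scene()`,
  `generate_timelapse()`, `generate_cohort()`) that renders neuron scenes
  and scripted movies with full ground truth, so the entire pipeline is
  testable without any raw data.

## Worked example

```r
library(aismito)

# a cluster-positive synthetic neuron with ground truth
cfg <- scene_config(cluster_present = TRUE, seed = 42)
scene <- generate_scene(cfg)
path <- scene$annotations$paths[[1]]       # axon polyline, soma end first

# 1. AIS start from the AIS-marker profile
ais <- detect_ais_start(extract_profile(scene$stack, "AIS", path))
ais$start_um
#> [1] 5.25            # ground truth: 5 um from the soma edge

# 2. presence + intensity profiles, cluster call
mask <- segment_mitochondria(scene$stack)
presence <- binary_presence_profile(mask, path, scene$stack$pixel_size_um)
intensity <- extract_profile(scene$stack, "MITO", path)
call <- classify_cluster(presence, intensity, ais)
call$category; round(call$proximal_presence, 2); round(call$central_presence, 2)
#> [1] "+"
#> [1] 0.5             # half the proximal window is mitochondria-positive
#> [1] 0               # central AIS essentially empty

# 3. cohort ratio from category counts
cluster_ratio(n_plus = 3, n_tilde = 2, n_minus = 5)[c("printed_ratio", "positive_fraction")]
#> $printed_ratio
#> [1] 2.5
#> $positive_fraction
#> [1] 0.4
```

`ais$start_um = 5.25` sits 0.25 µm past the true onset — the expected bias
of the 30%-of-maximum rule on a 1 µm ramp — and the `+` call reflects the
generated cluster (proximal presence 0.5 with an empty central AIS and
amplified proximal brightness). See the `methods` vignette for the model
behind every step and the design decisions.

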