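# cbctscatter

Prior-CT hybrid-domain scatter correction for cone-beam CT (CBCT), with a
complete simulated phantom study around it.

## The problem

Cone-beam CT acquired in the treatment room would let brachytherapy teams
image, plan, and treat cervical-cancer patients without moving them — but
the wide cone irradiates the whole volume at once, and the detector
collects a large, smooth haze of Compton-scattered photons on top of the
primary signal. That scatter depresses reconstructed CT numbers by
hundreds of Hounsfield units (HU), warps them across the field (cupping),
and destroys soft-tissue contrast, which in turn breaks model-based dose
calculation.

Radiotherapy patients, however, already have a high-quality planning CT.
This package implements a correction that uses it as a prior, in two
stages (hence *hybrid-domain*):

1. **Projection domain.** An empirical uniform scatter level s̄ is
   estimated — the constant such that 90% of the object's detector
   signals are larger — and subtracted from the raw projections with a
   soft-cut rule that keeps the corrected signal strictly positive. FDK
   reconstruction of the result gives the first-pass volume CBCT_c.
2. **Image domain.** The prior is segmented by HU windows into air, fat,
   muscle, and bone (windows [−1024, −500], [−125, −60], [15, 85],
   > 190 HU); each class's reference linear attenuation coefficient (LAC)
   is the mode of the prior's windowed histogram converted through the
   water calibration μ = HU/1000 · μ_w + μ_w. Filling the classes with
   their reference LACs gives a template CBCT_t, and the scatter ratio
   r = CBCT_t / CBCT_c measures the remaining multiplicative error where
   the segmentation is trusted. A binary mask f rejects implausible
   samples (|r| or its in-plane gradient above the 80th percentile,
   unclassified voxels), and a masked normalized convolution
   r_f = (r·f)∗∗w / (f∗∗w) spreads the sampled ratio into a smooth field.
   The corrected volume is CBCT_fc = CBCT_c · r_f; the high-HU applicator
   is finally restored from a rigidly registered reference model.

Image quality is scored with per-ROI statistics and three standard
figures: RMSE over ROI means, spatial nonuniformity
SNU = max − min of same-tissue ROI means, and contrast-to-noise ratio
CNR = |mean_r − mean_b| / σ_r. The dosimetric impact is probed with a toy
attenuation-aware point-source dose engine (ten dwell positions, 5 mm
step, 30 s each), 3D *local* gamma analysis at (1%, 1 mm), (2%, 1 mm),
(2%, 2 mm) with dose thresholds 3/6/9/12 Gy, and the DVH metrics D90 and
D2cc.

Everything needed to study the method is generated in-package: a seeded
digital female-pelvis phantom (340 mm × 200 mm elliptical body, organ
inserts at 191–199 HU, muscle-equivalent background at 130 HU, an
adipose shell, bone-mimicking polymer inserts, and a titanium-like
tandem applicator), a cone-beam projector with a low-frequency scatter
model, and Poisson counting noise.

## Worked example

```r
library(cbctscatter)

bench <- runBenchmark(defaultRunConfig(), verbose = TRUE)
benchmarkReport(bench)
```

On the default seeded configuration (256 × 192 × 96 phantom at 1.5 mm,
360 views, ~3 min on one CPU) the report ends with:

```
## Summary metrics (vs ground truth)
raw        RMSE    593.6 HU | muscle SNU  228.9 HU | CNR  2.54
firstPass  RMSE    295.6 HU | muscle SNU  698.5 HU | CNR  0.46
corrected  RMSE    148.9 HU | muscle SNU  309.3 HU | CNR  0.38

## Gamma pass rates (%)
1%, 1 mm   thresholds 3/6/9/12 Gy: 83.16 / 95.43 / 98.54 / 99.68
2%, 1 mm   thresholds 3/6/9/12 Gy: 85.49 / 96.30 / 99.22 / 100.00
2%, 2 mm   thresholds 3/6/9/12 Gy: 99.05 / 100.00 / 100.00 / 100.00

D90 target: ref 5.441 Gy, corrected 5.422 Gy (APD -0.35%)
```

Reading it: the raw reconstruction is ~600 HU off (deep scatter
cupping); the uniform subtraction halves the error; the image-domain
ratio step halves it again. The remaining error is concentrated in the
unsampled muscle background (see the methods vignette for why that is
the method's structural limit on this phantom). Dose computed on the
corrected volume agrees with dose on the ground truth for 99.0% of
voxels at the (2%, 2 mm) criterion with a 3 Gy threshold, and the
target's D90 agrees within 0.4%.

The same pipeline is scriptable from a shell via
`inst/exec/cbctscatter` with subcommands `simulate`, `correct`,
`evaluate`, `gamma`, and `benchmark`; volumes are NIfTI or MetaImage
files, configurations are YAML (see `defaultRunConfig()`).

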