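---
title: "Hybrid-domain CBCT scatter correction with a planning-CT prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-domain CBCT scatter correction with a planning-CT prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cbctscatter)
```

This vignette is the package's account of its science: the model behind
each stage, the parameters that matter and their defaults, what the
synthetic data generator does and does not emulate, the numerical
choices, and the known limits. Every number quoted here is computed by
the package's own tests or by `scripts/acceptance.R`; nothing is taken
on faith.

## 1. The measurement model

A circular cone-beam scan measures, at each detector pixel and view,

$$ I = I_0 \exp(-p) + S, \qquad p = \int \mu \, dl , $$

the Beer–Lambert primary plus an additive scatter signal $S$ that is
spatially smooth and can rival or exceed the primary behind a pelvis.
Reconstructing $-\log(I/I_0)$ directly treats $S$ as extra transmission
and depresses the reconstructed linear attenuation coefficient (LAC) —
the familiar cupping artifact with CT numbers hundreds of HU too low.

The package's correction uses the patient's planning CT as prior and
works in two domains.

**Projection domain (steps 1–2).** A single scan-wide constant
$\bar{s}$ estimates the scatter floor: object pixels are those with
$I < 0.9\,I_0$, and $\bar{s}$ is the nearest-rank 10th percentile of
their pooled intensities ("90% of the object signals are larger").
Subtraction uses a soft-cut rule that is exact where
$I - \bar{s} \ge \varepsilon I$ and rolls off as
$\varepsilon I \exp\!\big((I-\bar{s}-\varepsilon I)/(\varepsilon I)\big)$
below it — value- and slope-continuous at the switch and strictly
positive ($\varepsilon = 0.05$). FDK reconstruction (cosine weighting,
frequency-domain ramp filter with zero padding to the next power of two,
voxel-driven distance-weighted backprojection) yields the first-pass
volume $\mathrm{CBCT}_c$.

**Image domain (steps 3–6).** The prior is segmented by HU windows —
air $[-1024,-500]$, fat $[-125,-60]$, muscle $[15,85]$, bone $>190$ HU;
out-of-window voxels are treated as air and flagged unclassified. Each
class's reference LAC is the mode of the prior's windowed histogram
(1 HU bins, ties toward the window centre) through the water
calibration $\mu = \mathrm{HU}/1000 \cdot \mu_w + \mu_w$ with
$\mu_w = 0.020\,\mathrm{mm}^{-1}$. Filling classes with their reference
LACs gives the template $\mathrm{CBCT}_t$ and the scatter ratio
$r = \mathrm{CBCT}_t / \max(\mathrm{CBCT}_c, 10^{-4})$. A binary mask
$f$ zeroes implausible samples: $|r|$ or its per-slice central-difference
gradient above the 80th nearest-rank percentile (ties kept), voxels not
confidently classified, air-class voxels (their reference LAC is ~0, so
the ratio carries no information), and everything within 10 mm of the
applicator (near-field metal streaks). Local filtration — the masked,
normalized 2-D convolution $r_f = (r f) * w \,/\, (f * w)$ with a
unit-sum Gaussian $w$ — interpolates the sparse samples into a smooth
field, and $\mathrm{CBCT}_{fc} = \mathrm{CBCT}_c \cdot r_f$. The
applicator is restored from a reference model by rigid alignment
(supplied transform, or centroid plus principal axis of the thresholded
point clouds).

## 2. Parameters, units, defaults

| Parameter | Default | Meaning / why |
|---|---|---|
| `muW` | 0.020 /mm | water LAC at ~60–70 keV effective energy; sets the HU scale |
| `objectRule` | 0.9 | object pixel: $I < 0.9 I_0$ |
| `scatterPercentile` | 0.10 | "90% of object signals larger" rule for $\bar s$ |
| `softCutEps` | 0.05 | soft-cut switch fraction |
| `floorFrac` | 1e-4 | first-pass intensity floor before the log; caps line integrals near the physical ceiling of a pelvis-with-applicator scan so collapsed pixels cannot ring through the reconstruction |
| `sBarCapFrac` | `Inf` (off) | optional positivity cap $\bar s \le c \cdot \min I_{obj}$; use when the scatter floor varies strongly between views (see §5) |
| `epsFloor` | 1e-4 /mm | ratio denominator floor |
| `maskPercentile` | 0.80 | Eq.-style cutoffs for $|r|$ and $|\nabla r|$ |
| `sigmaMm` | 10 mm | filtration Gaussian width; calibrated on the benchmark so the filtration reproduces the reference uniformity behaviour (kernel truncated at 3σ, unit sum) |
| `applicatorMarginMm` | 10 mm | metal exclusion margin in the mask |
| `denomFloor` / `fallback` | 1e-3 / global mean | unreachable voxels get the global mean of sampled $r$ |
| dwell plan | 10 × 5 mm × 30 s, strength 25 Gy·mm²/s | puts the target D90 at the clinical ~5.5 Gy prescription level |
| gamma | local, search 3·dta, subgrid dta/5 | pass = $\gamma \le 1$ |

Percentiles are nearest-rank throughout: element
$\lceil q\,n\rceil$ of the sorted sample. The $|r|$ and $|\nabla r|$
cutoffs are computed separately, over the *body* voxels — the
confidently classified non-air voxels. That pool choice matters: on
this phantom the unclassified muscle bulk has $r \approx 0$ (air
template), and pooling it would collapse the cutoffs; pooling the whole
image is worse still.

## 3. The synthetic study and what it emulates

The generator builds a digital stand-in for a physical pelvis
brachytherapy phantom: a 340 mm × 200 mm elliptical body of
muscle-equivalent material (130 HU — deliberately *outside* the muscle
window, as the dense polymer muscle substitutes of real phantoms are),
a peripheral adipose shell (−112 HU), organ inserts for bladder,
uterus, rectum and intestine at 191–199 HU, two small bone-mimicking
polymer cylinders (350 HU cortical ring, 950 HU core), and a 3 mm
titanium-like tandem channel at 2500 HU. Structures are analytic
ellipsoids and cylinders, so DVH structure volumes are exact. Texture
is seeded Gaussian noise (8 HU), the planning prior adds 5 HU of
white noise, and detector noise is scaled-Poisson at $10^5$ photons per
unattenuated pixel.

The bone inserts are sized so that the $>190$ HU histogram window of
the prior is *organ-dominated*: its mode lands at the organ level
(~191–195 HU), which is what the reference phantom census implies
(corrected organ values land at the organs' own HU). With large bone
volumes the mode would jump to the bone material and the template would
mis-assign every organ — worth knowing if you change the phantom.

Scatter is simulated per view as $S = \mathrm{spr}\cdot G_\sigma(I)$, a
constant-preserving Gaussian blur of the view itself. The defaults
(spr 0.15, σ 250 mm at the detector) were calibrated so the *raw*
reconstruction reproduces the published artifact pattern of such scans:
RMSE ≈ 590 HU with smooth, radially dominated cupping (small error at
the peripheral adipose, deepest at the central organs). Short blur
widths (tens of mm) instead make the scatter floor track the shadow
width and vary several-fold between views — an artifact pattern with
strong azimuthal structure that no scan-wide constant can address and
that physical measurements of pelvis scans do not show.

What the generator does *not* emulate: polychromatic spectra and beam
hardening, bowtie filtration, detector lag/glare, anatomical
deformation, and realistic scatter kernels (long-tailed, object-depth
dependent). Passing benchmarks here therefore shows the pipeline's
internal consistency under a severe but idealized additive-scatter
model, not clinical performance.

## 4. Numerical choices

* Ray marching: fixed 1 mm steps with trilinear interpolation,
  bounding-box clipped; dose rays use 0.75 mm.
* FDK: projections rescaled to the virtual detector at the isocenter;
  ramp filter $|f|$ (optional Hann) applied in frequency domain after
  zero-padding to the next power of two, which removes the
  circular-convolution bias the uniform-cylinder test would otherwise
  show; reconstruction restricted to the scanner's lateral FOV.
* Benchmark grids: phantom 256 × 192 × 96 at 1.5 mm; reconstruction on
  the same in-plane grid with z cropped to 80 slices (the cone-covered
  region at the 384 × 144 detector), so the prior maps to the CBCT grid
  by identity — the synthetic phantom does not deform. Detector rows
  were set to 144 (not 96) so the dose-analysis volume is fully inside
  the cone.
* Gamma: distance-sorted offsets allow early termination without
  changing the minimum. When *comparing* criteria (the benchmark's
  relaxation ordering) the interpolation subgrids are nested — one
  absolute step for all criteria — since otherwise the coarser subgrid
  of a relaxed criterion can miss minima the stricter one found and
  flip a fraction of a percent of voxels against the theoretical
  monotonicity.
* D90 is the nearest-rank 10th percentile of in-structure dose; D2cc
  interpolates linearly on the sorted dose–volume curve and refuses
  structures under 2 cm³.
* Determinism: every stochastic stage takes an explicit seed derived
  from the single run seed; repeated runs are bit-identical.

## 5. Design decisions that were genuinely open

* **Subtraction domain.** The uniform estimate is subtracted from
  *intensities* before the log: positivity ("soft-cut") only makes
  sense pre-log, and a constant in intensity matches a scatter floor.
* **Global constant vs per view.** One constant per scan, as the
  method prescribes.
* **Segmentation source.** Default is the prior (labels transfer by
  identity on the undeformed phantom); thresholding the first-pass
  volume is available (`segmentSource = "cbct"`) but inherits its HU
  bias.
* **Positivity cap.** The percentile rule assumes the low end of the
  object signal is scatter-dominated and similar across views. On
  scatter-free or strongly view-varying scans the rule over-subtracts:
  the darkest pixels collapse through the soft-cut and the first-pass
  LAC can cross zero, which a multiplicative ratio can never repair.
  `sBarCapFrac` bounds $\bar s$ by a fraction of the darkest object
  pixel; it is off by default (the pure rule performs best under the
  calibrated study conditions) and the scatter-free idempotence
  property is tested with the cap on, because on a clean scan the 10th
  percentile of object signals is not small.
* **Mask pool and air.** See §2; both choices keep the 80% rule
  meaningful on a phantom whose bulk tissue is gap-class.

## 6. Known limitations

The image-domain step assumes the first-pass error is *multiplicative*
and smooth. After a constant subtraction the residual is in fact
additive in LAC, so the ratio a voxel needs, $\mu/(\mu+e)$, depends on
its tissue and position. Where a tissue is sampled, its own samples
carry exactly the right ratio and the correction is accurate (the
benchmark's organ and adipose ROIs land within ~10–35 HU of truth).
Where the bulk tissue is gap-class — as with the 130 HU
muscle-substitute background here, and in the physical phantoms this
emulates — the filtration must interpolate the ratio across 30–50 mm
from the adipose shell and the central organs, and the residual
first-pass error bounds the achievable accuracy: on the default
benchmark the muscle ROIs retain errors up to ~300 HU while sampled
tissues are an order of magnitude better. Reaching the
published-quality soft-tissue accuracy (~15 HU everywhere) requires a
residual after uniform subtraction far smaller than this scatter model
leaves. Dose is much more forgiving than HU: the (2%, 2 mm) local
gamma pass rate at 3 Gy is 98.8% and the target D90 agrees within
0.4%, because the dose integrals average the remaining LAC errors
along short in-plane paths.

High-density bone is corrected toward the bone-window mode (an organ
level HU here) — the method trades bone accuracy for soft-tissue
accuracy by construction.

## 7. Problem sizes

Default study: 256 × 192 × 96 phantom voxels at 1.5 mm, 384 × 144
detector at 1.552 mm, 360 views, reconstruction 256 × 192 × 80, dose
grid 64 × 64 × 100 at 2.5 × 2.5 × 1 mm. The full benchmark runs in a
few minutes on one CPU; module tests use 3 mm / 180-view or smaller
configurations of the same physics.
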