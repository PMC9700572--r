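---
title: "Box-counting fractal dimension of the aortic annulus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Box-counting fractal dimension of the aortic annulus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annulusFD)
```

## The measurement problem

Paravalvular regurgitation (PVR) after transcatheter aortic valve
implantation depends in part on how irregular the prosthesis landing zone
is. Euclidean measures — area, diameters, eccentricity
$100\,(d_{max}-d_{min})/d_{max}$, LVOT non-tubularity
$(A_{annulus}-A_{LVOT})/A_{annulus}$ — capture size and asymmetry but not
fine-scale "roughness" of the endocardial border. The box-counting
(Minkowski) fractal dimension summarises that roughness in a single
dimensionless number: FD is 1 for a smooth rectifiable curve and grows
toward 2 as the curve becomes space-filling.

This package reimplements the full measurement chain on calibrated 2D
CT-slice images of the annulus and LVOT planes:

1. **Calibration** — a "compass" ring of known physical diameter burned
   into exported workstation images gives mm-per-pixel (circle fit to the
   near-maximal-intensity ring pixels, Kasa algebraic least squares).
2. **Suitability gate** — only images whose luminal attenuation exceeds
   300 HU are segmentable with an intensity-based detector; the gate
   reports the probe median and a verdict.
3. **Border detection** — the lumen is grown as the connected component of
   pixels at or above the threshold (default 300 HU) containing a seed
   point; very bright pixels (default ≥ 800 HU) are treated as calcium,
   not lumen, so calcium foci indent the border; the single external
   boundary is traced sub-pixel by marching squares. Incorrect or
   fragmented detections raise classed errors and can be replaced via a
   programmatic manual-override hook.
4. **Box counting** — a fixed grid of $s \times s$ boxes (one origin, no
   origin averaging) is laid over the contour for calibers
   $s \in [0.8, 6.75]$ mm; for each caliber the boxes intersected by the
   border are counted by exact segment–box geometry, and
   $\ln N(s)$ is regressed on $\ln s$ by ordinary least squares. FD is the
   absolute slope.
5. **Cohort statistics** — per plane×phase: group medians (IQR) and
   two-tailed Mann–Whitney U comparing none/trace PVR against mild or
   greater; ROC with AUC, Hanley–McNeil 95% CI and the Youden cutoff;
   Pearson correlation against conventional measures; Cronbach's alpha and
   ICC(A,1) for automatic-vs-manual agreement.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| caliber range | 0.8–6.75 | mm | protocol constant of the measurement method |
| number of calibers | 10, log-spaced | – | the protocol states only the range; log spacing weights scales evenly in $\ln s$ |
| grid origin | (0, 0) | mm | "fixed grid": one origin, deterministic; origin averaging available as a sensitivity mode |
| segmentation threshold | 300 | HU | the suitability gate doubles as the lumen/tissue decision boundary; configurable |
| calcium ceiling | 800 | HU | operationalises "border between lumen and tissue, or calcium": brighter pixels are excluded from the lumen so foci indent the border |
| trace level | midpoint | – | see "Numerical choices" |
| seed point | image center | mm | exported workstation slices center the annulus; overridable per image |

## The synthetic world

No patient imaging ships with this package. Every stage is instead
validated against a generator with known ground truth:

* **Analytic oracles.** A circle (FD $\to$ 1), the Koch snowflake boundary
  (similarity dimension $\ln 4 / \ln 3 \approx 1.2619$), and straight
  segments (FD 1) anchor the fractal estimator.
* **Fractal annulus contours.** A radial perturbation of a circle,
  $r(\theta) = R\,(1 + a\,f_H(\theta))$, where $f_H$ is a zero-mean,
  unit-RMS periodic profile synthesised from Fourier modes
  $k = 2 \dots \lfloor n/4 \rfloor$ with power-law amplitudes
  $|c_k| \propto k^{-H-1/2}$ and uniform random phases. Decreasing the
  Hurst exponent $H$ or increasing the amplitude $a$ raises the measured
  FD; $a = 0$ degenerates to the exact circle polygon. Self-intersecting
  draws are rejected and resampled (at most 10 times). Defaults
  ($R = 12$ mm, $n = 256$, $H = 0.4$) give FD values in the 1.03–1.11
  band, matching the range reported for real annuli.
* **Rendering.** Contours are rasterised with partial-volume pixels (4×4
  supersampled lumen coverage), an HU-like 16-bit scale (tissue 50, lumen
  400 by default), optional Gaussian noise, optional calcium disks clipped
  against the lumen, and an optional compass ring. Cohorts of
  plane×phase image sets with group labels, outcome grades, and a
  configurable missing-phase pattern are generated fully seeded.

What the generator does **not** emulate: beam hardening, motion artefact,
streaking, anisotropic resolution, true 3D plane extraction, or the
statistical texture of real annular tissue — the fractional-noise profile
is a stand-in with tunable roughness, not an anatomical claim. A green
test therefore establishes that the *pipeline measures what it claims on
images whose ground truth is known*, not that the clinical effect size of
the source study is reproduced.

## Numerical choices

* **Box occupancy.** A box counts when its closed square intersects the
  polyline in a set of positive length. This keeps the shared-edge rule (a
  segment lying exactly on a grid line counts for both adjacent boxes)
  deterministic while excluding bare endpoint or corner touches, and it
  reproduces the closed form $N = L/s$ for a grid-aligned segment. The
  same contract is implemented twice: an $O(\text{segments})$ hashed
  counter in C++ and an exhaustive all-boxes oracle in the test suite;
  they must agree exactly.
* **Trace level.** Region membership uses the 300-HU threshold, but the
  sub-pixel isoline is traced by default at the *midlevel* between the
  lumen and tissue medians. A fixed 300-HU isoline sits at 71% of the
  tissue→lumen intensity ramp and therefore displaces the border by a
  constant fraction of a pixel — a bias proportional to mm/px that breaks
  scale invariance of FD. The midlevel isoline localises a symmetric edge
  without bias; `trace_level = "threshold"` restores the literal
  behaviour for sensitivity analysis.
* **Trace smoothing.** Two passes of a circular 3-point moving average
  remove the residual half-pixel marching-squares staircase. The filter
  footprint (~1 px ≤ 0.2 mm) is far below the smallest caliber (0.8 mm),
  so it affects neither the box counts nor genuine roughness at measured
  scales; without it the staircase inflates perimeter by ~5%.
* **Degenerate fits.** Fewer than 3 calibers refuse to fit; constant
  counts yield FD 0 with a classed warning; FD outside [1, 2] warns but
  does not error (legitimate finite-range estimates of smooth curves land
  slightly below 1).
* **Youden ties** break toward the smallest cutoff; the positive class is
  predicted at scores at or above the cutoff.
* **Mann–Whitney** is exact by complete enumeration when
  $n_A + n_B \le 20$ without ties, otherwise normally approximated with
  tie and continuity corrections (the conventions of the original SPSS
  analysis cannot be reconstructed; these are documented defaults).
* **AUC confidence interval** uses the Hanley–McNeil standard error
  (an SPSS-style nonparametric default) rather than DeLong; one method is
  fixed so reports are comparable.
* **ICC** is two-way random effects, absolute agreement, single measures
  (ICC(A,1)), with the McGraw–Wong F-based 95% CI; absolute agreement
  deliberately penalises systematic offset between automatic and manual
  areas, which a consistency coefficient would hide.
* **Missing phases** are excluded listwise per contrast and never imputed;
  no multiple-testing correction is applied across the four plane×phase
  contrasts by default (Holm available via `p_adjust = "holm"`).

## Design decisions that were genuinely open

* The measurement protocol states the caliber *range* but not the count,
  spacing, grid anchoring, or whether counts came from rasterised pixels.
  We fixed 10 log-spaced calibers, a fixed grid at the physical origin,
  and exact segment–box geometry (a rasterised path would re-introduce
  pixelation bias); all are exposed in `fd_config()`.
* Minimal/maximal diameters are Feret-type (rotating calipers on the
  convex hull): rotation-invariant and deterministic. Whether clinical
  workstations use Feret or centroid-ray diameters is unknown; the choice
  is recorded here and in the output metadata.
* Negative non-tubularity (LVOT larger than annulus) is passed through
  unclamped — the formula as printed permits flaring.
* The straight-segment FD oracle uses a 540 mm segment: the $+O(1)$
  partial-box term biases the fitted slope of short segments (≈ 0.96 at
  54 mm); the oracle must sit deep inside its scaling regime.
* Cohort-level inference properties (type-I error, planted-difference
  power) run through generator → contour → FD → statistics. The image
  render/segment stage is excluded from those loops purely for compute
  budget; its fidelity is established separately by the round-trip and
  scale-invariance tests, and the demo pipeline exercises the full image
  path end to end.

## Worked example

```{r demo, eval = FALSE}
out <- make_demo("demo_cohort", seed = 1, n_per_group = 10)
print(out$report)
#> <cohort_report> grouping: pvr, primary contrast: annulus.diastole
#> [medians/IQR per plane x phase, Mann-Whitney p per cell, ROC on the
#>  planted diastolic-annulus contrast]
```

The demo plants a roughness contrast (amplitude 0.03 vs 0.09) that
separates the groups' diastolic annular FD; the rerun of the same seed
reproduces every CSV byte for byte.

## Known limitations

* Sub-pixel roughness cannot be recovered from an image that never
  resolved it: contours whose vertex spacing is below the pixel pitch
  lose perimeter (though FD at calibers ≥ 0.8 mm is barely affected).
  This is information loss at the sensor, not a segmentation defect.
* Fixed-grid box counting is translation-sensitive at the ±0.02 level in
  FD; the origin-averaging mode reduces but does not remove this.
* The clinical effect sizes of the source study (FD medians near 1.03 vs
  1.05, AUC 0.661) derive from patient data and are not reproduced here;
  the synthetic cohorts only mirror the *shape* of those analyses with a
  controllable ground-truth gap.
* One lumen per scene; boundaries touching the image frame are an error
  rather than silently clipped (clipped borders bias box counts).
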