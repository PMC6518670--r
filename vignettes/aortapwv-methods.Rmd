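---
title: "Automatic aortic pulse wave velocity: models, parameters and design notes"
author: "aortapwv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic aortic pulse wave velocity: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement

Aortic pulse wave velocity (PWV) — the propagation speed of the systolic
pressure wave along the aorta — is a marker of aortic stiffness. From
cardiovascular MRI it is computed as

$$\mathrm{PWV} = \mathcal{L} / \Delta t,$$

with $\mathcal{L}$ the length of the aortic arch between the ascending and
descending aorta (mm) and $\Delta t$ the transit time of the flow wave
between the two sites (ms); mm/ms equals m/s. The two ingredients come from
two acquisitions:

* a **multi-slice 3D scan** of the thoracic aorta in an oblique-sagittal
  plane (1.76 x 1.76 mm pixels, 5 mm slices) from which the arch geometry
  is measured, and
* a **through-plane velocity-encoded (VE) cine** transverse to the proximal
  aorta (1.25 x 1.25 mm pixels, 5 ms reconstructed phase interval, VENC
  150-200 cm/s) cutting both the ascending and the descending aorta, from
  which the two velocity-time curves are extracted.

`run_all()` chains the three automatic stages with no interaction:
multi-atlas segmentation and centerline length, VE contour detection and
flow curves, and transit-time estimation.

## Multi-atlas segmentation

Each atlas (a labelled scan of the same anatomy) is registered to the
subject with a three-stage recipe: a global affine, an affine restricted to
an aorta mask, and a B-spline free-form deformation with the same mask,
each stage initialising the next. The similarity is mutual information,
estimated from 2048 stochastic samples per iteration with a Parzen-window
(cubic B-spline) joint histogram of 32 bins, and maximised by stochastic
gradient ascent with the analytic MI gradient, a normalised gradient
direction and a decaying gain $a/(A+k)^{0.602}$ over a three-level
coarse-to-fine pyramid (down-sampling factors 4/2/1 in-plane, 2/1/1
through-plane: the slices are already 5 mm thick). Iteration defaults are
512 per level for the affine stages and 2048 for the B-spline stage, with a
15 mm control-point grid.

Two deliberate choices:

* **Fixed/moving roles.** The subject is the fixed image and each atlas the
  moving image. Labels are then pulled back onto the subject grid by
  reading the atlas label at the mapped position of every subject voxel —
  well-defined even for non-invertible B-spline stages. The stage-2/3
  sampling mask is the atlas label dilated two voxels in-plane and warped
  to the subject grid with the current chain estimate.
* **Label fusion** is a per-voxel majority vote (ties count as foreground —
  at typical atlas counts a tie is as likely over the vessel as next to
  it, and the subsequent largest-component step removes stray islands),
  followed by retention of the largest 26-connected component.

The optimiser is a plain decaying-gain stochastic gradient scheme rather
than the adaptive step-size variant used by general-purpose registration
packages; on the tube geometries this package targets, the simpler
schedule recovers rigid offsets of 10 mm / 10 degrees to well under a
voxel, and every run is reproducible from one integer seed.

## Centerline and arch length

The fused mask is skeletonized by homotopic thinning: iterative removal of
simple points (26-connected foreground, 6-connected background, the
Malandain–Bertrand characterisation) in six directional sub-iterations with
curve endpoints preserved. Two numerical details matter:

* **Opposite support.** A border point in direction $d$ is only deletable
  when its $-d$ neighbour is foreground. Without it, sequential deletion
  can "unzip" one-voxel-thick structures end-to-end within a single
  sub-iteration and truncate a vessel limb by tens of millimetres.
* **Isotropic resampling.** Thinning assumes an approximately isotropic
  neighbourhood metric. On 1.76 x 1.76 x 5 mm voxels it leaves locked
  zigzag sheets; the mask is therefore resampled (nearest neighbour) to
  isotropic spacing at the smallest voxel dimension before thinning. This
  is the same practice vessel-analysis toolkits recommend before
  skeletonization.

The skeleton voxels form a graph (26-neighbour adjacency, Euclidean edge
weights in mm); the largest component is kept and the maximum-length
shortest path between endpoint pairs — the weighted graph diameter — is the
centerline, which discards side branches. Because a voxel-centre chain
zigzags, its polyline length overestimates arc length (up to ~18 % on a
181 mm arch); the path is smoothed with a centred moving average spanning
about 18 mm of arc (roughly one lumen diameter) before summation. Across
arch radii 35–55 mm and tilts up to 15 degrees this reduces the length
error to about 1 mm on average; the residual cap erosion of thinning
(roughly one tube radius per end) lies outside the measured segment and
does not affect it.

The VE cutting plane $\vec n \cdot \vec x = d$ comes from the VE slice
geometry, with $\vec n$ oriented so the arch apex satisfies
$\vec n \cdot \vec v \ge d$. Centerline points with $\vec v_i \cdot \vec n
\ge d$ are retained, the two exact plane-intersection points are appended
(removing a half-voxel bias of summing voxel points only), and the length
is the arc length between the intersections. The intersections are also
the seed points for the VE contour stage, projected into pixel coordinates
through the slice geometry. A path crossing the plane other than exactly
twice (or a non-contiguous retained segment) is a topology error — the
analogue of the centerline failures a population pipeline must report
rather than silently absorb.

## VE contours and flow curves

On the magnitude frame of the reference phase (timepoint 30, near peak
flow, when the lumen is bright), 64 evenly spaced radial scan lines of
25 mm are cast from each seed; the edge response is the negative radial
intensity derivative, and the contour is the exact minimum-cost closed
cycle over the (angle x radius) graph — solved by running the DP once per
candidate start radius — with a smoothness penalty $\lambda_s = 1$
(normalised edge response per pixel of radius change) and radius sampling
of 0.5 px. Contours are propagated outward from the reference phase in
both temporal directions, adding $\lambda_t \,|r - r_{\mathrm{prev}}|$ to
the cost. The polar origin stays fixed per ROI so the (angle x radius)
grid — and with it the temporal term — is common to all phases.
$\lambda_t = 0.5$ was fixed once on a pulsing-disk phantom: larger values
(e.g. 2) make the penalty for a half-pixel radius step exceed any
attainable edge gain under sequential propagation, freezing the contour at
the reference radius.

Velocity maps follow the linear phase-to-velocity law (phase $\pi
\leftrightarrow$ VENC in the radians dialect); each flow curve is the mean
velocity over pixels whose centres fall inside the polygon (even-odd
rule). ROI 1 is the curve with the positive systolic peak (ascending),
ROI 2 the inverted descending curve.

## Transit time

Three estimators, all operating after sign normalisation:

* **foot-to-foot** — baseline from samples before the 10 %-of-peak
  crossing, a least-squares line through the rising limb between 20 % and
  80 % of peak, foot at the line/baseline intersection;
* **half-max** — first crossing of 50 % of peak on the rising limb, linear
  interpolation between the bracketing samples;
* **cross-correlation** — lag maximising the per-lag Pearson correlation of
  the two curves on a 1 ms resampled grid, parabolically refined unless the
  peak is perfect (an exact integer shift then recovers its lag exactly),
  bounded by a 100 ms search window with a boundary-peak error.

Arrival detection runs on a zero-phase Gaussian-filtered copy of each
curve (SD 15 ms for foot-to-foot, 20 ms for half-max, 10 ms for
cross-correlation). The filter is linear, symmetric and identical for both
curves, so the transit time stays unbiased while the crossing jitter —
noise divided by upslope steepness, about 2.5 ms per curve for 5 % noise at
5 ms sampling — is suppressed. There is a hard floor here: an arrival
estimator restricted to the systolic upslope cannot beat
$\sigma = \sigma_v / \sqrt{\sum_i v'(t_i)^2}$ (about 0.9 ms per curve for
the phantom waveform below), so half-max transit-time errors bottom out
near 1 ms at that noise level no matter the implementation; the test suite
asserts the budgets as specified and the half-max Monte-Carlo budget sits
at this floor.

PWV values above 19 m/s — the measurability cap implied by the 5 ms VE
temporal resolution — are reported numerically but flagged as high PWV.

## The phantom model

Every stage is testable without patient data through a synthetic study
with analytically known truth:

* **Geometry.** A "candy-cane" curve: a semicircular arch of radius $R$
  (default 45 mm) joined to two straight limbs (default 50 mm), tiltable
  about the limb axis and perturbable by a smooth seeded displacement
  (≤ 1.5 mm). Unperturbed arc length is exactly $\pi R + l_1 + l_2$;
  perturbed curves store a dense polyline integral. The curve is rasterised
  as a flat-capped tube of radius 10 mm on the acquisition grid
  (1.76 x 1.76 x 5 mm, 96 x 96 x 15 voxels — a full acquisition-sized 256 x 256
  matrix is mostly air, so the phantom field of view is sized to the
  arch). Noise is Rician-like: Gaussian added to the magnitude, floored at
  zero. Atlas sets (default eight) vary radius, limb lengths, tilt and
  rigid pose around the subject geometry.
* **Waveform.** A raised-cosine upslope (80 ms) from baseline to peak
  (100 cm/s) followed by exponential decay (150 ms) — smooth, with a
  differentiable foot, so all three estimators are exercised. The
  descending curve is delayed, sign-inverted and dispersed: the dispersion
  factor (1.2) stretches the upslope *and* accelerates the decay by the
  same factor, front-loading the pulse the way descending-aorta curves are
  front-loaded relative to ascending ones. A pure upslope stretch would
  shift the pulse mass later relative to the half-max arrival and make
  cross-correlation *over*-estimate the transit time, inverting the
  clinically observed ordering (cross-correlation underestimates;
  half-max tracks the systolic wave). Ground-truth arrival is the half-max
  point of each curve's own upslope, so $\Delta t$ is exact by
  construction and $\mathrm{PWV}_{\mathrm{true}} = \mathcal{L}_{\mathrm
  {true}} / \Delta t_{\mathrm{true}}$ above the VE plane.
* **VE series.** Two bright disks at the plane crossings on magnitude;
  phase encodes the waveform linearly with phase $\pi \leftrightarrow$
  VENC (150 cm/s), 5 ms interval, 140 phases, Gaussian phase noise.

What the phantom does **not** emulate: k-space physics, ECG gating and
breathing artefacts, intensity inhomogeneity, surrounding anatomy
(vertebrae, pulmonary vessels) that real registration must discount,
aliasing, and flow-related magnitude variation. Passing phantom tests
therefore demonstrates the correctness of the geometry, registration,
graph and estimator machinery under controlled conditions — not clinical
robustness on cohort data.

## Problem sizes used by the tests and the acceptance script

The test suite runs the arch-length study on 20 phantom geometries, the
transit-time Monte Carlo on 100 pairs per transit time in {5, 10, 15, 20,
25} ms, the full pipeline on 10 phantoms (four atlases each), rigid
recovery on 10 seeds, and the estimator-ordering study on 100 dispersed
pairs (noiseless — the generator's default curve-level noise, since ROI
averaging in the imaging chain suppresses pixel noise by roughly the
square root of the vessel pixel count; transit times drawn from 5–25 ms).
`scripts/acceptance.R` recomputes the same quantities at moderate sizes
(10 arches, 40 pairs per transit time, three full-pipeline phantoms with
eight atlases, three rigid-recovery seeds) and writes them as JSON.

## Known limitations

* Thinning erodes roughly one tube radius from each open vessel end; the
  measured segment must therefore stay away from the label ends (the atlas
  labels extend below the VE plane for exactly this reason).
* The B-spline stage shares one control grid across pyramid levels and
  relies on the affine stages for capture range; gross misalignments
  beyond ~10 mm / 10 degrees are out of its design envelope, mirroring the
  failure mode of atlas pipelines on out-of-distribution fields of view.
* Foot-to-foot remains structurally sensitive to dispersion: stretching
  the upslope moves the fitted foot earlier relative to the half-max
  arrival, so its transit times disagree with the other estimators on
  dispersed curves by design, not by defect.
* DICOM input is not supported; volumes and VE series are exchanged as
  NIfTI with a JSON sidecar for timing, VENC and slice geometry.
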