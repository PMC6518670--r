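# aortapwv

Fully automatic quantification of **aortic pulse wave velocity (PWV)** from
cardiovascular MRI, as used in large population studies. PWV — the speed at
which the systolic pressure wave travels along the aorta — is an established
marker of aortic stiffness, and is computed here as

```
PWV = L / Δt        [mm / ms  =  m/s]
```

where `L` is the 3D centerline length of the aortic arch between the
ascending and descending aorta, and `Δt` is the transit time of the flow
wave between those two sites. The package implements every stage of the
measurement, with no manual interaction between stages:

1. **Multi-atlas segmentation** of the aortic arch from a multi-slice 3D
   scan: three-stage registration of each labelled atlas to the subject
   (global affine → masked affine → masked B-spline free-form deformation;
   mutual-information similarity optimised by stochastic gradient ascent
   over a three-level pyramid), followed by majority-vote label fusion.
2. **Centerline length**: 3D homotopic thinning of the fused mask, graph
   pruning to the longest (diameter) path, clipping at the
   velocity-encoded (VE) slice plane `n·x = d` (points with `n·v ≥ d`
   retained, exact plane intersections appended) and arc-length summation.
3. **Flow curves**: minimum-cost closed-contour detection on radial scan
   lines around the two plane-crossing seed points of the VE magnitude
   series, temporally-continuous contour propagation over all cardiac
   phases, and mean through-plane velocity inside each contour (phase
   π ↔ VENC).
4. **Transit time and PWV** by three estimators — foot-to-foot, half-max
   and cross-correlation — with a high-PWV flag above the 19 m/s
   measurability cap of the 5 ms VE temporal resolution.

Because no patient data ship with the package, a first-class **phantom
module** generates synthetic studies — multi-slice tube volumes, atlas
sets, and 2D+t VE series — with analytically known arch length, arrival
times and PWV, so the whole pipeline is testable end to end. See the
methods vignette (`vignettes/aortapwv-methods.Rmd`) for the models,
parameter choices and design notes.

## Worked example

```r
library(aortapwv)

# a synthetic subject with known ground truth: arch + atlases + VE series
study <- make_phantom_study(seed = 42, pwv_m_s = 10, n_atlas = 4)
study$truth$L_true_mm   # 180.0 mm
study$truth$dt_ms       # 18.00 ms

report <- run_all(study$subject, study$ve, study$atlases,
                  pipeline_config(seed = 42))
print(report)
```

```
<subject_report>
  segmentation  ok
  centerline    ok
  flow          ok
  length_mm     179.5
  foot_to_foot      dt_ms 13.76  pwv_m_s 13.05
  half_max          dt_ms 17.70  pwv_m_s 10.14
  cross_correlation dt_ms 16.59  pwv_m_s 10.82
```

Reading the report: the measured arch length (179.5 mm) is within half a
millimetre of the analytic truth (180.0 mm). Half-max recovers the
18.0 ms transit time to 0.3 ms and the 10 m/s PWV to 0.14 m/s.
Cross-correlation sits slightly below half-max — the expected behaviour on
dispersed waveforms, where correlating the whole curve underestimates the
systolic-wave delay — and foot-to-foot deviates most, since dispersion
moves the fitted foot of the descending upslope; the same ranking of the
three estimators seen in clinical comparisons. A stage that fails (e.g. a
misaligned VE scan) is recorded in the report with its reason and all
downstream numbers are left absent.

A command-line driver wraps the same functions
(`inst/cli/aortapwv.R phantom | segment | centerline | flow | pwv |
run-all`), exchanging volumes as NIfTI and VE series as paired NIfTI plus
a JSON sidecar (trigger times, VENC, slice geometry).

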