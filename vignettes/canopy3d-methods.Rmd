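---
title: "Methods: 3D crop water stress mapping from thermal and binocular RGB imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D crop water stress mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopy3d)
```

## The problem

Canopy temperature is a surrogate for stomatal closure, and the crop water
stress index

$$\mathrm{CWSI} = \frac{T_c - T_{wet}}{T_{dry} - T_{wet}} \in [0, 1]$$

normalizes it between the temperature of a fully transpiring surface
($T_{wet}$, measured on a physical wet reference) and a non-transpiring one
($T_{dry}$, approximated as air temperature + 7 °C). A thermal camera sees
$T_c$ per pixel but at low resolution (384×288) and with no depth; a
binocular RGB pair (2×1280×720, 60 mm baseline) provides geometry and the
colour cues needed to separate canopy from soil. `canopy3d` fuses the two
into a 3D point cloud whose points carry XYZ (mm), RGB, temperature and
CWSI, so the *spatial distribution* of water stress over a plant canopy can
be analysed, not just its image-plane average.

## Pipeline

1. **Harmonization.** The colour image is resized (bicubic) and cropped so
   its pixel pitch and extent match the thermal image. The scale is the
   focal-length ratio $f_{thermal}/f_{colour}$ and the crop centres the
   thermal principal point — both read from the rig calibration, which is
   an input file, not something this package estimates.
2. **Coarse registration** (photogrammetric). Both harmonized colour views
   are Laplacian-sharpened (4-neighbour kernel, unsharp combination
   $I - \nabla^2 I$), the green canopy is extracted by an HSV interval
   test, and scale/rotation-invariant features are detected and matched
   under a nearest-neighbour ratio test (0.7). Matches violating the
   epipolar constraint of the rectified pair (row difference > 2 px, or
   negative disparity) are dropped. Survivors are triangulated
   ($Z = Bf/(x_l - x_r)$), back-projected into the thermal camera through
   its relative pose, and a thermal→colour homography is fitted by seeded
   RANSAC (3 px inlier threshold, up to 2000 iterations, confidence 0.995)
   with a least-squares refit on the consensus set.
3. **Fine registration.** The canopy is not a perfect plane and calibration
   carries error, so integer offsets $(\Delta x, \Delta y)$ applied to the
   back-projected thermal points are scanned on a grid; each offset
   re-estimates the homography, warps the thermal image, and scores the
   co-aligned crop with SSIM (7×7 Gaussian window, $\sigma = 1.5$,
   standard constants, computed on grayscale). The largest SSIM wins; ties
   go to the smallest offset norm, then lexicographic order. Because the
   grid contains (0, 0), the result never scores below the coarse
   solution. The temperature grid is warped with the winning homography
   using nearest-neighbour sampling, preserving the 0.1 °C quantization.
4. **Stereo reconstruction.** The pair is rectified (Bouguet-style rotation
   onto the baseline), disparity is computed by semi-global block matching
   (8 aggregation paths, block 5, $P_1 = 8\cdot3\cdot5^2$,
   $P_2 = 32\cdot3\cdot5^2$, uniqueness 10 %, left–right check ±1 px,
   parabolic subpixel refinement), then median-filtered (3×3,
   valid-aware) and hole-filled by multi-level mean filtering. Depth is
   $D = Bf/d$ and 3D points follow the pinhole relations
   $X = (x - x_0)D/f$, $Y = (y - y_0)D/f$, $Z = D$.
5. **Fusion and cleaning.** One point per pixel with valid depth *and*
   valid temperature. Three cleaning steps: the HSV canopy filter on point
   colours; statistical outlier removal (mean distance to k = 50 nearest
   neighbours, cut at $\mu + 0.5\sigma$, exact neighbour search); and 1-D
   k-means (k = 2) on temperature, keeping the larger cluster — hot-edge
   points created by residual misregistration pick up soil temperature and
   form the smaller, hotter cluster.
6. **CWSI.** $T_{wet}$ comes from a user-specified ROI on the warped
   temperature grid (or a 3D box on the cloud); $T_{dry} = T_{air} + 7$.
   Per-point CWSI is clamped to [0, 1] with the clamped fraction reported.
   Canopy means join environment records (air temperature, illumination)
   by nearest timestamp within 5 minutes to form diurnal series.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| hue bounds HL, HU | 35, 100 | 0–180 scale | bracket green canopy hues |
| saturation lower SL | 35 (direct sun) / 60 (shade) | 0–255 | sun washes out saturation; switch at 50 klx |
| ratio test | 0.7 | – | standard distance-ratio rejection |
| epipolar row tolerance | 2 | px | rectification residual allowance |
| RANSAC threshold | 3 | px | inlier gate for the homography |
| fine search range / step | ±10 / 1 | px | "small position difference" around the coarse solution |
| fill initial window | 4 | px | fills holes without over-smoothing; passes 4 → 3 |
| outlier k / ratio | 50 / 0.5 | – | statistical filter neighbourhood and cut |
| dry offset | 7 | °C | non-transpiring reference above air temperature |

The V channel is unconstrained by default (VL = 0, VU = 255) and SU = 255:
only the bounds with stated working values are active; the rest are
configurable but deliberately neutral.

## Design choices where the design was open

* **Hue scale.** The canopy thresholds are meaningful only on the 0–180
  half-degree hue scale; that convention is fixed package-wide.
* **Feature detector.** The registration contract needs a scale- and
  rotation-invariant detector with floating-point descriptors and subpixel
  localization; the package implements a compact difference-of-Gaussians
  detector with 4×4×8 gradient-orientation-histogram descriptors
  (SIFT-family). The detector name travels in the match-set metadata.
* **Homography direction.** Fixed as thermal → (harmonized) colour; the
  inverse is applied when looking temperatures up for colour pixels.
* **Window-halving arithmetic.** An initial 4×4 window would halve below
  3 immediately; the adopted schedule is integer halving with ceiling plus
  a mandatory final 3×3 pass, so 4 yields passes {4, 3} and the stated
  initial window is meaningful. Even windows anchor ⌊W/2⌋ pixels
  above/left. All passes read sum/count integral images of the fill
  *input*; later (smaller) passes overwrite earlier assignments, and
  originally valid pixels are never touched.
* **k-means initialization and ties.** Centres start at the 10th and 90th
  temperature percentiles and iterate (Lloyd) to 1e-6 — deterministic, so
  the `seed` argument is interface sugar only. Equal cluster sizes keep
  the cooler cluster (canopy is cooler than soil). A spread below 0.2 °C
  (two quantization steps) short-circuits to identity so a uniform canopy
  is never split.
* **Clamping.** Measurement noise can push CWSI outside [0, 1]; values are
  clamped and the clamped fraction is reported rather than hidden.
* **Wet reference.** No detector for the wet surface is invented: its
  location is a user-supplied ROI, and $T_{wet}$ is taken per frame
  (configurable).
* **SSIM input.** Whether similarity is scored on the pseudo-colour or a
  grayscale rendering is open; grayscale (luminance) is adopted and
  recorded here as a choice.
* **Tabular summary convention.** `batch_feature_count_stats()` reports
  both the exact percent increase of the column means and a
  `percent_increase_printed` derived from the means rounded half-up at the
  printed precision, which is how such benchmark tables derive their
  average row; the bundled 30-sample benchmark reproduces its printed
  summary (39.2, 58.0, 48.0 %) under that convention. The bundled
  control-point column averages 2.86 px at two decimals, which is why its
  one-decimal printed summary is not used as a machine check.

## The synthetic scene generator

Real greenhouse acquisitions are not redistributable, so validation runs on
fully ground-truthed synthetic scenes. Pseudo-leaves (textured ellipses,
hues inside 35–100) lie on a dominant fronto-parallel canopy plane,
optionally above a deeper soil plane; the three cameras render the plane by
exact pinhole projection. Planarity is deliberate: it makes the
thermal→colour mapping an exact plane-induced homography
$H = A\,K_l M (K_t[R_1\,R_2\,R_3 Z_0 + T])^{-1}$, the disparity field a
closed form $Bf/Z$, and the temperature field exactly invertible to its
planted CWSI field — so every stage has an analytic oracle. Temperatures
are planted through CWSI ($T = T_{wet} + \mathrm{CWSI}\,(T_{dry}-T_{wet})$,
smooth spatial variation, canopy ≈ 23–29 °C at the default references
$T_{air} = 29.5$, $T_{wet} = 21$), soil sits near $T_{air} + 6$; the
measured grid adds Gaussian noise (default σ = 0.1 °C) and 0.1 °C
quantization. Options plant hot-edge artefacts (leaf-boundary pixels at
soil-like temperature, the misregistration failure mode the k-means step
targets), per-leaf jitter between the colour and thermal exposures (wind),
and operator-style marking noise (0.5 px) on the leaf-centre landmarks used
as control points — without that noise a control-point error would not
upper-bound the optimized feature residual the way real operator-marked
points do.

What the generator does **not** emulate: non-planar canopy relief within a
leaf, occlusion parallax between the thermal and colour viewpoints,
radiometric leaf-angle effects, specularities, and soil/canopy temperature
overlap for stressed near-ground leaves. Passing tests therefore
demonstrate correctness of the algorithms under controlled geometry, not
field-grade accuracy on real plants; the k-means step in particular is
known to mis-segment leaves whose temperature approaches the soil's.

## Numerical notes and problem sizes

* Pixel coordinates are 0-based, origin top-left, x rightward, y downward;
  integer coordinates are pixel centres. One convention everywhere avoids
  off-by-one drift between modules.
* Invalid pixels are `NA` internally (disparity, depth, warped
  temperature); exports omit them.
* Bicubic resampling uses the Catmull–Rom kernel (a = −0.5) with edge
  clamping; warps sample colour bilinearly and temperature
  nearest-neighbour.
* SGBM subpixel refinement is a parabola through the aggregated costs;
  its residual quantization (~0.1–0.2 px) maps to millimetre-scale depth
  noise at the default geometry ($\Delta Z = Z^2 \Delta d / fB$, ≈ 3 mm
  per 0.1 px at $Z = 1.25$ m on the full-size rig), which bounds how flat
  a reconstructed plane can be.
* The test and acceptance suites run the study conditions on a 0.25-scale
  rig (320×180 colour, 96×72 thermal, same field of view and baseline):
  scene renders stay under a second and the full validation completes in
  minutes while exercising identical code paths; the scale factor is a
  parameter, not a different code path.

## Limitations

Planar-scene validation (above); a single homography cannot model
per-pixel parallax for deep canopies — that is intrinsic to the method,
which is why the fine registration exists; the statistical outlier filter
trims the boundary of uniformly sampled surfaces (a property of the
$\mu + 0.5\sigma$ rule, visible in the cleaning reports); and CWSI
accuracy is bounded by the wet-reference measurement and the fixed +7 °C
dry offset, both of which are inputs here.
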