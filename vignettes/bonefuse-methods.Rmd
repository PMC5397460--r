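---
title: "Methods: surface-projected 3D SPECT/CT fusion and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface-projected 3D SPECT/CT fusion and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonefuse)
```

## The display model

Bone SPECT voxels are 4–10 mm against 1–2 mm for CT, so a volume rendering
of the SPECT itself is blurred and swollen and spills uptake colour onto
soft tissue. `bonefuse` instead renders the CT bone surface opaquely and
paints SPECT information onto that surface:

1. **Bone extraction.** `extractBone()` thresholds the CT in Hounsfield
   units (voxels `>= boneThreshold` are kept — the boundary voxel is
   included by convention), applies a morphological closing with a
   discrete ball, and discards small 26-connected components.
   `closeHoles()` then re-fills every background region (6-connectivity)
   that cannot be reached from the volume border, turning the extracted
   cortical shell into solid bone including marrow. The complementary
   26/6 connectivity pairing for foreground/background is the standard
   choice that avoids topological paradoxes between an object and its
   complement.
2. **Urinary suppression.** Tracer pooled in the collecting system and
   bladder dominates the SPECT dynamic range and causes scatter artifacts
   (classically at the medial pubis). `removeUrinaryActivity()` zeroes
   every 26-connected component of voxels at or above
   `urinaryPercentile x max(SPECT)` that lies entirely outside the bone
   mask dilated by `urinaryMargin`. Voxels inside the dilated mask are
   never altered, so skeletal uptake is conserved exactly. Activity below
   the percentile contour is left in place; it is invisible in the fused
   render anyway because only surface values are displayed.
3. **Surface projection and blending.** Each image pixel casts an
   orthographic ray; the first sample inside the (clip-edited) bone mask,
   refined by one bisection, is the surface point *p*. With
   window-normalised uptake `w(s) = clamp((s - lo)/(hi - lo), 0, 1)` the
   pixel is `(1 - beta*w) * ctShaded(p) + beta*w * LUT(w)`. Uptake
   modulation makes cold bone render as plain CT; `uptakeModulated =
   FALSE` gives the constant-beta blend instead. Both are provided because
   the workstation tools that popularised this display do not document
   which convention they use.
4. **Clip-plane editing.** A plane removes the half-space `n.x > d`
   during marching. Rays whose refined hit lies within one step of the
   plane are on the cut face and are coloured by the fused CT/SPECT value
   of the interior tissue there, shaded with the plane normal, which
   exposes marrow-level structure and metabolism.

Assumptions: the SPECT-to-CT alignment of a hybrid scanner is treated as
exact (identity transform) unless a rigid transform is supplied;
registration is never estimated. All geometry is done in world
millimetres through the volumes' affines, so the CT/SPECT grid mismatch
is explicit and handled by trilinear resampling at render or resample
time, never implicitly.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `boneThreshold` | 150 | HU | diagnostic CT cortex is well above, marrow/soft tissue below; ~100 HU suits noisy low-dose attenuation-correction CT; in osteoporosis use `suggestThreshold()` (half the median cortical HU at user probes) |
| `closingRadius` | 2 | mm | bridges single-voxel cortical gaps at 1–2 mm CT spacing without thickening bone visibly |
| `minComponentVolume` | 200 | mm^3 | removes isolated noise specks; real bones are orders of magnitude larger |
| `urinaryPercentile` | 0.6 | fraction of max | urinary pooling is several-fold hotter than any skeletal uptake |
| `urinaryMargin` | 10 | mm | about one SPECT voxel: protects periosteal uptake smeared outward by the PSF |
| `stepSize` | half the min CT spacing | mm | sub-voxel surface accuracy after one bisection at ~2x ray cost |
| `blendWeight` (beta) | 0.5 | — | equal visual weight of anatomy and metabolism at full uptake |
| ambient / diffuse | 0.3 / 0.7 | — | conventional headlight Lambertian appearance |
| SPECT window | [0, 99.5th percentile in-mask] | counts | a handful of hottest voxels must not compress the colour scale |

## The digital phantom

`generatePhantom()` builds a skeleton from analytic solids on a 2 mm CT
grid (default 128^3): cylindrical vertebral bodies with an 800 HU cortical
shell and 100 HU marrow, capped tubular ribs, an ellipsoidal pelvic shell,
−50 HU soft tissue and −1000 HU air, plus Gaussian HU noise (default
sigma 20 HU). The activity map assigns a bone-turnover baseline of 1, a
faint soft-tissue background, lesion archetypes, and a hot bladder
(default 20x baseline). Lesions pair a CT change with an uptake change —
osteolytic metastasis −400 HU with moderate uptake, osteoblastic +400 HU
with high uptake, degenerative osteophyte ring at a disc space, thin
low-density fracture band with linear uptake — so that uptake alone
discriminates the classes poorly while CT morphology disambiguates them,
which is exactly the contrast the fused display is meant to exploit. The
PSF (isotropic Gaussian, default FWHM 10 mm) is applied in activity space
at CT resolution **before** integration onto the coarse SPECT grid
(default 32^3 at 8 mm, within the typical 4–10 mm range) and Poisson
sampling under the count budget (default 5e5); the order matters and is
fixed for reproducibility. Everything is a deterministic function of the
config seed.

What the phantom does **not** emulate: anatomically realistic shapes,
attenuation, scatter, collimator-distance-dependent resolution, patient
motion, or reconstruction artifacts. Tests passing on the phantom
therefore establish the correctness of the geometry, segmentation,
rendering and statistics code, not clinical performance on real
acquisitions.

`simulateReaders()` models ordinal confidence scoring as a latent signal
`discrimination x (+1 malignant / −1 benign) + N(0,1)` cut at fixed
thresholds (−1, 0, 1) into scores 1–4. It exists to exercise the
statistics end to end: AUC is monotone in discrimination, chance at 0,
and saturates to 1 — the parameter-recovery checks in the test suite.

## Numerical choices

- Voxel indices are 0-based with cell-centred samples; the affine maps
  index to world mm (NIfTI convention). Interpolation outside the grid
  returns 0 (air / no counts) rather than clamping — safe for both
  modalities and what makes "no extraosseous uptake" hold trivially at
  the volume border.
- Trilinear interpolation is exact for linear fields; the resampler is
  linear in its input and the identity on its own grid (both are tested
  properties, the former via a ramp fixture).
- Ray marching tests the mask at the nearest voxel; the single bisection
  step halves the bracketing interval and returns its midpoint, so the
  reported surface point is within `step/2` of the true face for
  axis-aligned geometry.
- Surface normals come from central differences of the CT field (half a
  voxel offset) at the hit point, negated so they point outward (down the
  HU gradient); a vanishing gradient falls back to facing the camera.
- Opaque-mode pixels depend only on values at and in front of the first
  hit (occlusion independence is asserted in the tests). Compositing
  mode accumulates front-to-back and terminates at alpha 0.995.
- Percentages are rounded half away from zero to integers, matching how
  such accuracy tables are conventionally printed; AUC is reported to 3
  decimals. Exact fractions are always returned alongside.
- Degenerate statistics (empty class, zero-variance differences, one-
  category margins) return flagged `NaN` values, never crash.

## Design choices where the field leaves the question open

- **Orthographic camera.** The projection used by commercial fusion
  workstations is unspecified; parallel projection keeps every geometric
  property analytically testable and costs nothing for the intended
  anatomy-overview use.
- **Kappa weights.** "Weighted kappa" on a 4-point ordinal scale most
  commonly means linear disagreement weights `|i−j|/3`; linear is the
  default and quadratic is available. Published kappas alone cannot
  adjudicate the choice because the underlying cross-tables are
  generally unpublished.
- **AUC comparison.** The classical reader-study comparison method is
  rarely named in clinical reports. Provided are an unpaired normal test
  with tie-corrected placement (DeLong-type) variances computed from the
  ordinal counts, and, for paired per-lesion scores, a seeded bootstrap
  over lesions; the method used is always reported with the p-value.
- **Urinary elimination.** Commercial implementations are proprietary;
  the high-activity-outside-dilated-bone component suppression defined
  above is this package's own explicit reinterpretation and is stated as
  such.
- **Hole filling.** Likewise defined explicitly: border-unreachable
  background (6-connectivity) becomes foreground; the operation is
  extensive and idempotent, and is tested against an independent
  flood-fill oracle.

## Problem sizes in the test suite

The property tests run the full study grid — 128^3 CT voxels at 2 mm,
32^3 SPECT voxels at 8 mm — for rendering and segmentation recovery
(Dice ≥ 0.98 noiseless, ≥ 0.95 at default noise), 1000 random count
tables for the AUC oracle, 1000 random 4x4 tables for the kappa oracle,
random 32^3 masks for the hole-filling oracle, and 20-seed ensembles of
500-lesion reader simulations for parameter recovery. Smaller analytic
fixtures (slabs, single voxels, hollow boxes) pin down exact values the
full phantom cannot.

## Known limitations

- Single rigid transform only; no deformable registration, so breathing
  misalignment in ribs is displayed as-is.
- No attenuation or scatter modelling anywhere; the phantom's Poisson
  model is idealised.
- The first-hit renderer assumes a binary bone mask; partial-volume
  cortex thinner than the CT spacing can alias at oblique angles.
- Reader simulation is a one-parameter signal-detection caricature; it
  validates statistical code, not human reading behaviour.
- Multi-reader multi-case variance modelling (Obuchowski–Rockette / DBM)
  is out of scope.
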