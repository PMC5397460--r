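# bonefuse

3D SPECT/CT fusion for skeletal scintigraphy: projection of bone-SPECT
uptake onto volume-rendered CT bone surfaces, with the full supporting
pipeline (CT bone segmentation, urinary-activity suppression, clip-plane
cross-sections, 2D fused slices), a digital skeleton phantom, and the
reader-study statistics used to evaluate such displays.

## The problem

Tc-99m diphosphonate bone SPECT maps skeletal metabolism, but its voxels
are coarse (4–10 mm) and its resolution poor, so volume rendering the
SPECT itself gives blurred, swollen surfaces and spills tracer colour onto
soft tissue. Readers therefore usually scroll 2D fused axial/coronal/
sagittal slices. The alternative implemented here renders the **CT** bone
surface at 100 % opacity and expresses the SPECT value **only at the
corresponding point on that surface**, blending it with the shaded CT
colour. The result reads like contrast-enhanced 3D CT: anatomy at CT
resolution, metabolism as surface colour, and no extraosseous uptake.

For a pixel whose ray first hits the bone surface at point *p*:

```
w      = clamp((S(p) − w_lo) / (w_hi − w_lo), 0, 1)        # windowed uptake
pixel  = (1 − β·w) · C_CT(p) + β·w · LUT(w)                # β ∈ [0,1]
```

where `S` is the (resampled, urinary-cleaned) SPECT field, `C_CT` the
Lambert-shaded CT transfer-function colour, and `LUT` a hot-metal colour
table. Cold bone (`w = 0`) renders as plain CT; a constant-β blend is
available as an option. Clip-plane editing removes the half-space
`n·x > d` and colours the cut face with the fused interior values,
exposing marrow-level metabolism.

The evaluation side implements the arithmetic of four-point confidence
reading (1 definitely benign … 4 definitely malignant, score ≥ 3 =
test-positive): sensitivity/specificity/PPV/NPV, the tie-corrected
empirical ROC area

```
AUC = [ Σ_{i>j} m_i b_j + ½ Σ_i m_i b_i ] / (M·B)
```

over score counts `m` (malignant) and `b` (benign), equivocal rates
(scores 2–3), linearly weighted kappa between readers, and paired t tests
with Bonferroni adjustment.

## Worked example

The package ships the four-point confidence counts of a published
two-reader study of 1746 hypermetabolic bone lesions (744 metastatic,
1002 benign) read as whole-body scintigraphy + SPECT, 2D SPECT/CT and 3D
SPECT/CT:

```r
library(bonefuse)
cc <- reader1ConfidenceCounts()
cc$wb_spect
#> OrdinalCounts (four-point confidence scale)
#>           def.benign pos.benign pos.malignant def.malignant
#> malignant         23        140           401           180
#> benign           245        527           182            48

confusionMetrics(cc$wb_spect)$percent
#> sensitivity specificity         ppv         npv
#>          78          77          72          83

empiricalAuc(cc$wb_spect)$auc
#> [1] 0.7996245

equivocalSummary(cc$spectct_3d)
#> $count
#> [1] 340
#> $percent
#> [1] 19
```

Planar + SPECT reading leaves 72 % of lesions equivocal (AUC 0.800);
either fused display drops that to 19 % with AUC 0.983 — morphology
resolves the uncertain middle scores.

The imaging pipeline runs end to end on the digital phantom:

```r
ph <- generatePhantom(phantomConfig())       # 128^3 CT, 32^3 SPECT
ph$ct
#> Volume [ct] 128 x 128 x 128, spacing 2 x 2 x 2 mm
#>   value range [-1098, 1153]

bone <- closeHoles(extractBone(ph$ct))       # threshold + close + fill
diceCoefficient(bone, ph$truth$skeleton)
#> [1] 0.9883485

sp  <- removeUrinaryActivity(resampleToGrid(ph$spect, ph$ct), bone)
cam <- cameraForVolume(ph$ct, viewDir = c(0, -1, 0), up = c(0, 0, 1))
img <- renderFusion3d(ph$ct, bone, sp, cam)  # [H, W, 3] in [0,1]
writeImagePNG(img, "fusion_anterior.png")
```

A thin command-line wrapper over the same functions lives at
`inst/cli/bonefuse.R` (subcommands `phantom`, `fuse3d`, `stats`).

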