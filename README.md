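# ddhscreen

Automated screening of infant hip ultrasound for developmental dysplasia
of the hip (DDH): standard-plane quality gating and Graf alpha-angle
measurement, with a synthetic B-mode phantom generator providing ground
truth for every stage.

## Who this is for

Researchers building or evaluating automated Graf-method measurement on
2D B-mode frames of the infant hip. Clinical frames — especially those
acquired by novice sonographers — suffer from reverberation ghosts below
bone, multiplicative speckle, soft-tissue distractors and plane rotation;
`ddhscreen` implements a staged pipeline that measures only what is
measurable and refuses the rest, plus the synthetic phantoms and
statistics needed to test such a pipeline without clinical data.

## The method

For a preprocessed 256×256 frame:

1. **Apex point** (the landmark where the inferior end of the ilium meets
   the iliac cortex) is estimated by a trainable heatmap model: Gaussian
   target maps (σ = 2 px), pixelwise binary cross-entropy, argmax decoding
   with quarter-pixel refinement. The reference backbone is a learned
   15×15 convolution filter + sigmoid (CPU-trainable in seconds); heavier
   backbones plug in via `predict_heatmap()`.
2. **Signal heterogeneity / quality gate.** In a 10-px-wide ROI above the
   estimated apex, local maxima are found by maximum-filter + equality
   masking, thinned to one ridge point per row, and fitted with an
   orthogonal least-squares ridge line (trimmed + subpixel-refined). The
   frame **qualifies** only if the iliac angle θ lies in **87–93°**
   (90° = vertical ilium = true coronal standard plane).
3. **Alpha angle.** The acetabular-roof edge is the topmost local maximum
   in a search rectangle infero-medial to the apex; roof points are the
   maxima in the closed sector between the horizontal and the
   45°-below-horizontal rays from that edge, thinned per column, screened
   by an edge-anchored consensus, and fitted the same way. The **alpha
   angle** is the folded difference of the two line orientations,
   α = fold₉₀(θ_ilium − θ_roof), and **DDH ⇔ α < 60°**.

Batch verdicts feed ROC/AUC, sensitivity/specificity at the 60° cutoff,
pooled-variance Student t tests, Benjamini–Hochberg FDR adjustment, and a
qualified-vs-disqualified rater-error comparison.

## Worked example

```r
library(ddhscreen)

# a dysplastic hip (alpha 55 < 60) on a perfect standard plane (ilium 90)
p  <- phantom_params(iliac_angle_deg = 90, alpha_deg = 55, seed = 42)
fr <- generate_phantom(p)
run_pipeline(fr$image, fr$truth$apex)     # oracle apex for illustration
#> frame verdict: ok
#>   eAP (128.00, 120.00), confidence 1.000
#>   iliac angle 90.02 deg (qualified)
#>   alpha 54.92 deg -> DDH

# a 100-frame screening cohort with speckle, reverberation, distractors
co  <- generate_cohort(100, ranges = list(alpha_deg = c(50, 70)), seed = 7)
res <- run_pipeline_batch(co$frames, apex = "oracle")
table(res$status)
#>               disqualified insufficient_ridge_support                      ok
#>                         39                         26                      35
ev <- evaluate_cohort(res, co$manifest)
sprintf("AUC %.3f  sensitivity %.3f  specificity %.3f", ev$auc, ev$sensitivity, ev$specificity)
#> "AUC 1.000  sensitivity 1.000  specificity 1.000"
```

The generated frame is rendered at iliac angle 90° and alpha 55°; the
pipeline re-measures 90.02° (qualified, inside the 87–93° gate) and
54.92° (< 60° ⇒ DDH). In the cohort, frames whose ilium is rotated off
the standard plane are *disqualified* (angle reported, no diagnosis) or
refused for insufficient ridge support; on the analyzable frames the
alpha-based score separates DDH from normal hips perfectly at this
cohort size.

Training the apex model instead of using the oracle:

```r
train <- generate_cohort(200, noise = FALSE,
                         ranges = list(iliac_angle_deg = c(85, 95)))$frames
model <- train_apex_estimator(train, apex_config(seed = 7))
evaluate_apex_estimator(model, generate_cohort(50, noise = FALSE, seed = 99)$frames)$mean
# ~0.2 px mean localization error held out
```

## Command line

```sh
ddhscreen phantom-generate --n 100 --out cohort/ --seed 1
ddhscreen pipeline-run     --manifest cohort/manifest.csv --out verdicts.csv
ddhscreen evaluate         --manifest cohort/manifest.csv --results verdicts.csv
ddhscreen apex-train       --manifest cohort/manifest.csv --model model.json
ddhscreen apex-predict     --model model.json --image cohort/phantom_0001.png
ddhscreen ridge-assess     --image f.png --eap-x 128 --eap-y 120
ddhscreen alpha-measure    --image f.png --eap-x 128 --eap-y 120
```

All verbs accept `--config config.yaml` (see `pipeline_config()`) and
`--seed`; results are JSON on stdout.

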