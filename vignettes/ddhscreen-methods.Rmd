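---
title: "Methods: automated quality gating and alpha-angle measurement for infant hip ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated quality gating and alpha-angle measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddhscreen)
```

## The problem

Graf-method screening for developmental dysplasia of the hip (DDH)
measures the **alpha angle** — the angle between the vertical cortex of
the ilium (the baseline) and the bony acetabular roof — on a coronal
standard-plane B-mode frame of the infant hip. An alpha angle below 60°
indicates a shallow, dysplastic socket. Two practical obstacles dominate
automated measurement:

1. **Artifacts.** Reverberation prints ghost copies of the bone deeper in
   the frame, speckle modulates every intensity multiplicatively, and
   soft-tissue interfaces mimic the bone lines.
2. **Plane validity.** The measurement is only defined on a true standard
   plane, recognisable by a near-vertical ilium. Frames acquired by novice
   sonographers are frequently rotated and must be rejected, not measured.

`ddhscreen` implements a staged pipeline that addresses both: a trainable
landmark model finds the **apex point** (where the inferior end of the
ilium meets the iliac cortex); the pattern of locally maximal intensities
("signal heterogeneity") inside a narrow region of interest above the apex
traces the ilium ridge; a ridge line fitted by orthogonal least squares
gives the **iliac angle**, gated at **87–93°** (inclusive) to accept only
standard planes; on accepted frames the acetabular-roof ridge is traced
from the roof edge and the alpha angle and DDH verdict follow.

## Coordinates and conventions

All coordinates are 0-based, origin at the top-left pixel centre, x
rightward, y downward; pixel `(x, y)` lives at `image[y + 1, x + 1]`.
Line orientations are degrees in `[0, 180)` from the image horizontal
with y down, so 90° is vertical and the angle *decreases* as a line tips
toward descending-right. The alpha angle is the absolute orientation
difference folded into `[0, 90]`. Frames are preprocessed by luminance
conversion and a bilinear stretch (not letterbox) to 256 × 256 — the
resize contract is literal, so anisotropic inputs use per-axis scale
factors, applied identically to annotations.

## Stage 1: apex-point estimation

Landmark estimation is cast as heatmap regression: the annotation becomes
a Gaussian target map (`sigma_px = 2`, peak 1 at the nearest pixel) and a
model scoring every pixel is trained with mean pixelwise binary
cross-entropy. The spread of 2 px was chosen to match the few-pixel
accuracy scale the task demands; the target is unnormalised so the loss
treats the peak as a positive class rather than a density.

The **reference backbone is convolutional logistic regression**: one
learned `15 × 15` filter plus bias passed through a sigmoid, trained by
minibatch Adam (defaults: 30 epochs, batch 1024, lr 0.05) on all pixels
with target > 0.01 plus 300 random background pixels per frame. No deep
learning framework is available in the target environment, and on
phantoms this model already localises the apex to ~0.2 px held out — far
inside the ≤ 6 px contract — because the apex is the unique point where a
bright vertical band terminates against a darker field with an oblique
band emanating beside it, a pattern one linear template separates well.
Heavier published keypoint architectures remain pluggable through the
`predict_heatmap()` generic; their value on clinical data lies in trained
weights that are not distributable here.

Decoding takes the heatmap argmax refined by a quarter-pixel shift toward
the larger neighbour on each axis — the standard heatmap decoding rule. A
peak below `min_confidence = 0.2` is declared "no apex signal"; the value
is a config default, separating the ~1 confidence of true apexes from the
near-zero response to blank or apex-free frames.

Augmentation for training reproduces a resize(0.875–1.2)/crop(224) plus
seven photometric effects (equalize, posterize 2–4 bits, solarize 156–256,
contrast ×1–4 and ×0.2–1, brightness ×1–3 and ×0.4–1), three per chain at
strengths 0.2–0.8, three chains mixed with Dirichlet(α = 1) weights.
Design choices the contract leaves open: three chains (the classical
mixing default); "strength" linearly interpolates each effect's parameter
toward its identity value (equalize, which is parameter-free, interpolates
its output); the 50 % equalize probability applies when the effect is
drawn into a chain; grayscale frames are treated as one colour channel.
The geometric transform is sampled once and shared by all chains, so
keypoint equivariance is exact by construction.

## Stage 2: signal heterogeneity and the quality gate

The ROI is 10 columns wide centred on the eAP's x, unbounded above, and
ends 5 rows below the eAP's y (half-open integer intervals; "width 10"
means exactly 10 columns). Local maxima are detected classically: a
square maximum filter (default 5 × 5) over the *whole image*, masked by
equality with the original, intensities > 0. Computing the filter over
the whole image matters: pixels just inside the ROI are judged against
their true neighbourhoods, which suppresses band edges clipped by the ROI
border. Plateaus survive equality masking by design and are thinned by
the selection stages.

Selection keeps one point per image row — the brightest local maximum,
ties toward smallest x — after two screens the measurement stages add:

* **Bone-intensity screen.** Maxima dimmer than 0.5 × the brightest
  maximum in the ROI are dropped. Speckle makes every neighbourhood
  produce *some* local maximum, and the fit must see the bone, not the
  background texture. One half is a deliberately blunt threshold: bone is
  brighter than soft tissue by integer factors in these frames.
* **Border-tie exclusion.** Rows whose winner lies on (or ties with a
  candidate on) the ROI's x border are dropped: when the ilium has
  drifted out of the narrow ROI its clipped flank still leaves plateau
  pixels at the border that would masquerade as ridge points.

Fewer than `k_min = 10` surviving rows disqualifies the frame
("insufficient ridge support"). The ridge line is fitted by **orthogonal
(total) least squares** — the ilium is near-vertical, where y-on-x
regression is ill-conditioned — then refined twice: a trimmed refit drops
points whose perpendicular residual exceeds 2.5 × the median (floored at
1.5 px, never removing more than half the points), and a subpixel pass
re-estimates each row's ridge position as the background-subtracted
intensity centroid in a ±2 px window about the line, using all rows in
the retained span above the apex (the roof begins just below it). The
trim absorbs structured outliers — distractor streaks, clipped flanks —
and the centroid averages the ±1.5 px speckle jitter of integer maxima.

The gate accepts iliac angles in `[87, 93]`, bounds inclusive, boundary
ties resolved toward qualified. Disqualified frames still report their
angle as feedback to the sonographer but carry no diagnosis.

## Stage 3: roof edge, sector, and the alpha angle

The roof search rectangle extends 40 px from the eAP toward the roof side
and 40 px deeper — the contract leaves the rectangle unspecified; these
extents comfortably cover the roof at the phantom's scale and are
configurable. Within it, after the same bone-intensity screen, the **roof
edge** is the local maximum with minimum numeric y (topmost; ties toward
the eAP's x). "Lowest Y-coordinate" is read as minimum numeric y because
the roof's edge abuts the apex region above and the selection sector then
sweeps downward.

Candidates for the roof fit must lie in the **closed sector** between the
horizontal ray and the 45°-below-horizontal ray from the edge, strictly
toward the roof side. Three screens make the fit robust to the artifact
classes the phantom generates:

* **Topmost-per-column thinning** — the roof is the superior boundary of
  the bone; reverberation echoes are copies displaced deeper, so only the
  minimum-y candidate per column can be roof (the 90°-rotated mirror of
  the ilium's per-row rule).
* **Edge-anchored consensus** — the roof line passes near its own edge,
  so each candidate defines a putative line through the edge and the
  candidate collecting the most perpendicular inliers (±2.5 px) wins;
  with a few dozen candidates the exhaustive search is exact and
  deterministic. This rejects echo bands that survive thinning in columns
  where speckle suppressed the true roof maxima.
* The same trimmed TLS + subpixel centroid refinement as the ilium, per
  column, with a ±3 px window (a 45° band crossed vertically is √2
  thicker than its profile) and a 3-px guard next to the apex column
  where the ilium band overlaps the rectangle.

Alpha is the folded orientation difference of the two ridge lines. DDH is
declared for alpha **strictly below 60°** — the diagnostic definition —
with the screening reading ("60° or less") available as
`rule = "inclusive"`; the two differ only on the measure-zero boundary.

## The phantom: what it emulates, and what it does not

`generate_phantom()` renders the geometry the pipeline consumes: an ilium
segment at a controlled orientation ending at a known apex, a roof
segment starting 3 px infero-medial to the apex at a controlled alpha,
and the artifact classes that defeat naive ridge tracing —

* **flat-top line profiles** (half-width `thickness/2`, Gaussian shoulder
  0.75 px): cortical bone under log compression is a saturated specular
  band, and a plateau ridge is precisely the regime equality-masking
  detection is designed for;
* **reverberation**: `reverb_count = 3` echo copies displaced deeper by
  12 px with geometric decay 0.5 — echoes appear below reflectors;
* **multiplicative speckle**: a unit-mean Rayleigh field blended at scale
  0.3, the first-order B-mode speckle approximation, plus additive
  Gaussian background noise (sd 2) and a 1 px blur;
* **distractor streaks**: two random moderate-intensity segments per
  frame standing in for soft-tissue interfaces.

Defaults were fixed once as a plausible screening world: iliac angle
Uniform(80, 100) (≈ 30 % of frames qualified), alpha Uniform(45, 75)
straddling the 60° threshold, apex uniform over the central frame.
Identical parameters and seed give bit-identical images.

The phantom makes no attempt at wave-propagation physics, device-specific
image chains (gain, TGC, log-compression curves), or pediatric anatomy
beyond the two landmarks the pipeline consumes. A green test on phantoms
establishes that the geometry pipeline recovers known angles through
these artifact classes; it does not establish clinical performance, which
in the source setting required a trained clinical-scale model and
expert-annotated frames. Simulated rater measurements (noise sd 1° on
qualified frames, 4° on disqualified) encode only the *assumption* the
reliability comparison tests — that rotated planes are harder to measure
consistently — and inherit its conclusion by construction; the
corresponding tests verify the statistical machinery (power, type-I
calibration), not a clinical fact.

## Numerical choices and degenerate inputs

* Bilinear, pixel-centre-aligned resize; resizing to the same size is the
  identity.
* TLS via the 2 × 2 eigen decomposition; coincident points are an error;
  the brute-force check minimises the orthogonal residual over
  orientation directly.
* Gate and sector boundaries are closed; DDH threshold strict.
* Max-filter padding is −Inf (borders never fabricate maxima); maxima
  require intensity > 0, so blank regions yield none.
* Stage failures map to verdict statuses (`no_apex_signal`,
  `insufficient_ridge_support`, `disqualified`, `roof_not_found`) and
  never crash batch runs; "insufficient roof support" folds into
  `roof_not_found` because the verdict enumeration is closed.
* All randomness is seed-threaded: per-frame seeds derive from the cohort
  seed, training and augmentation take explicit seeds, and global RNG
  state is restored after every call.

## Known limitations

* At extreme tilts (|iliac − 90°| ≈ 5°) under speckle, the narrow ROI can
  retain fewer than `k_min` ridge rows and the frame is refused
  (~2–3 % of frames at the tilt extremes); the ROI is one column
  asymmetric (integer half-open intervals), so refusals concentrate at
  95°.
* The left/right tie-break rules are chiral, so mirror symmetry of the
  measured alpha holds to ≈ 0.1° on phantoms, not to machine precision.
* The reference apex model saturates on the phantom world with ~25
  training frames; its learning curve is flat (≈ 0.22–0.25 px) above
  that, and on artifact-laden frames it is capacity-limited (≈ 5–7 px).
* The roof search rectangle and the intensity screens assume the roof is
  the dominant bright structure infero-medial to the apex; a frame whose
  roof is dimmer than a crossing artifact inside the rectangle can still
  be mis-measured (rare, visible as AUC < 1 on artifact cohorts).
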