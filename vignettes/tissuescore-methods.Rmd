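---
title: "Methods: digital PD-L1 (22C3) scoring and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital PD-L1 (22C3) scoring and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tissuescore)
```

This vignette is the package's account of its science: the model behind
each stage, the parameters that matter and why their defaults are what
they are, what the synthetic slides do and do not emulate, and the design
choices made where the design was genuinely open.

## The stain model

Brightfield IHC obeys Beer–Lambert absorption: stain amounts add linearly
in optical density, `OD = -log10((pixel + 1) / 256)` per 8-bit channel.
Both the synthetic renderer and `separate_stains()` use the same published
hematoxylin/DAB unit basis (`hdab_basis()`), so deconvolution is the exact
linear inverse of rendering. Negative hematoxylin/DAB loadings (possible
only through quantization noise) are clipped at zero; the third, residual
plane keeps its sign so that it absorbs the 8-bit quantization error. With
that convention, reconstructing the OD image from the planes is exact up
to the rare clipped loadings (mean error around 1e-5 OD on zero-noise
slides, asserted below 1e-3 in the tests); clipping the residual as well
would bound the round trip by the quantization step (~4e-3 OD) instead,
which is why the residual is left signed.

## Cytometry

Nuclei are detected on the hematoxylin plane: Gaussian smoothing
(`smooth_sigma`, default 1.5 px), a fixed OD threshold (`h_threshold`,
0.15 — comfortably below the palest rendered nuclei at ~0.35 OD and far
above background), hole filling, then a watershed on the smoothed
*intensity* with tolerance 0.05 OD. The intensity watershed, rather than
the classical distance-transform watershed, is deliberate: nuclei are
intensity domes (darker chromatin toward the centre), and in packed tumor
nests the distance transform of the merged mask has no waist to cut while
the intensity profile still has two peaks with a saddle. On default
synthetic slides this choice moves cell identification from roughly 85% to
roughly 97%. An area gate (12–600 px²) removes debris and merged clumps.

Each nucleus is expanded by `ring_width` (2 px) into a membrane ring and
by a further `cyto_width` (3 px) into a cytoplasm annulus. Expansion is a
label-constrained (Voronoi-style) propagation inside the dilated mask, so
neighbouring cells never share ring pixels. The per-cell feature vector
(`FEATURE_NAMES`, fixed order, hashed into every trained model) covers
nuclear morphology (area, equivalent diameter, eccentricity, solidity),
nuclear hematoxylin (mean, variance), DAB in the ring (mean and 90th
percentile) and cytoplasm (mean), ring completeness (fraction of 16
angular sectors containing stained ring pixels) and local cell density
(neighbours within 40 px). Membrane intensity is scored as the ring's
**p90** DAB OD rather than its mean: partial rings — common where
neighbours clip the annulus — should not dilute a genuinely stained
membrane. The mean-vs-quantile choice is an open point in the assay
definition; p90 is this package's documented convention.

## Positivity, TPS and binning

The ordinal staining grades have no published numeric definition. The
generator fixes mean membrane ODs of 0.05 / 0.30 / 0.60 / 0.90 for grades
0 / 1+ / 2+ / 3+, and the classifier cut points (`score_config()$od_cuts`
= 0.175, 0.45, 0.75) sit at the midpoints between consecutive anchors.
They were calibrated once against that intensity map and are frozen:
threshold parameters do not change per slide or per cohort, mirroring the
locked-threshold discipline of a clinical assay. Intervals are half-open
with the cut point belonging to the upper grade, so an OD exactly at t1 is
1+ (positive).

TPS is the printed formula: positive tumor-compartment cells over all
tumor-compartment cells, times 100. Two denominator policies exist:
`raw` counts every tumor-compartment cell; `immune_corrected` removes
cells predicted macrophage or lymphocyte, implementing the idea that
intratumoral immune cells do not belong in the denominator. With no
immune cells the policies coincide (tested). "Viable" is handled purely
by exclusion annotations (necrosis etc.), not per-cell viability calling.
Therapy bins cut exactly at 1 and 50, left-closed above.

Inference is deliberately free of randomness — seeds appear only in
training and simulation, and even random-forest vote ties are broken by a
fixed rule rather than the RNG — so scoring one slide three times yields
exactly zero TPS variance. That reproducibility claim is a headline
behaviour of a digital assay and is asserted bit-for-bit in the tests.

## Compartments

Tumor-vs-stroma separation is cell-level supervised learning from
analyst-circled regions: cells inside `train_tumor`/`train_stroma`
polygons form the labeled set (centroid test, even-odd rule, strictly
inside on the boundary; exclusion beats training beats inclusion). The
default family is a random forest over the full feature vector, with LDA
and logistic regression available behind the same interface — the family
switch exists because the immune stage reuses it for model selection.
Random-forest training uses stratified balanced sampling: compartments are
roughly balanced, but the immune classifiers below share this code path
and their positive classes are rare (5–15% of cells), which would
otherwise bias counts low at the vote threshold. Held-out accuracy (30%
stratified split) is recorded in the model object; training needs at
least 20 cells per class.

## Immune recognition from dual-IF ground truth

The training path emulates the restain/co-register workflow: a
two-channel IF image of the same cell population, offset by a small rigid
transform, is registered back to brightfield coordinates by blob
detection, a coarse translation from cross-correlation of density
rasters, and trimmed iterative-closest-point refinement with a
closed-form (Kabsch) update. The coarse search is restricted to shifts
under 15% of the image extent — serial-section mounting offsets are small,
and an unrestricted search can lock a sparse marker distribution onto an
unrelated dense region. Registration residuals land well under 1 px and
recorded transforms are recovered within 0.5 px / 0.005 rad.

Labels transfer by mutual-nearest-neighbour matching within 6 px: a cell
matched to a CD68 **or** CD163 blob is a macrophage, everything else is
not; CD3/CD20 analogously for lymphocytes. Both classifiers are trained
through this same IF path. (In the emulated study, lymphocyte labels came
from pathologist-supervised annotation rather than IF transfer; using one
label path for both classes is a recorded deviation, and the macrophage
tissue/alveolar subtype head is trained from annotation-style subtype
labels — in synthetic work, the generator truth — when provided.)

Model selection follows the verification-set pattern: each candidate
family is fitted on the training table and scored by the mean absolute
percent error of its predicted cell counts on disjoint verification
samples with known counts; the most accurate candidate is kept, and the
selection report stays in the model object. IF-side ground-truth counts
come from per-channel local-maximum blob detection with the two channels
de-duplicated by proximity (3 px), so double-positive cells count once.

## The synthetic slide generator

The generator defines the study conditions. Defaults: 640x640 px canvas
(0.5 um/px nominal), 250 tumor cells in nests inside a blobby tumor
region, 120 stromal fibroblast-like cells outside it, 25 macrophages
(60/40 tissue/alveolar, the alveolar ones in airspace pockets), 35
lymphocytes, diffuse DAB background at 10% of the 1+ OD, and Gaussian OD
noise of 0.02. Classes are morphologically separable by construction:
lymphocytes are small (3–4 px radius) and dark (0.95 OD), tumor nuclei
6–8 px at 0.65 OD and clustered, macrophages large and pale with granular
cytoplasmic DAB. The number of PD-L1-positive tumor cells is exactly
`round(true_tps/100 * n_tumor)`; immune cells carry their own positivity
(30% of macrophages, 15% of lymphocytes) so immune-corrected scoring has
something to correct. Placement is dart-throwing with a minimum
centre-distance of 0.9 x the radius sum — nuclei touch but do not engulf
each other — and an explicit density error when a request cannot fit.
Identical spec + seed is bit-identical; serial sections share one placed
population and one pixel-noise field, differing only by per-section
positional/intensity jitter, so zero jitter reproduces the section
exactly.

What the generator does **not** emulate: nuclear texture, chromatin
patterns, out-of-focus planes, stain spill between serial sections,
folds, necrosis, or the long-tailed TPS distribution of a clinical
cohort (no public distribution exists to copy; the validation sweeps a
uniform 0–95% grid instead). Passing the synthetic validation therefore
demonstrates that the pipeline is correct and self-consistent under the
assay's stated model of staining — not that it would meet the same
numbers on scanner images of patient tissue.

Simulated readers add a systematic bias, a persistent per-reader offset
and per-read noise to the true TPS, clipped to [0, 100] — enough
structure to exercise concordance and precision statistics, with defaults
(2 TPS points for both SDs) at the scale of careful human re-reads.

## Validation statistics

Cell-level metrics match predictions to truth by mutual nearest neighbour
within 5 px. Per sample: identification rate (matched truth fraction),
FPR (truly negative cells called positive) and FNR (truly positive cells
called negative); the criteria — >= 90% identification, FPR <= 10%,
FNR <= 20%, each in >= 90% of samples — are asserted on a 20-slide
default-condition cohort. Accuracy is the fraction of samples whose
digital and manual scores give the same treatment decision at the 1%
cut-off (>= 90% to pass).

Precision uses the random two-way decomposition (sample + repeat day +
residual) estimated by method of moments from the ANOVA mean squares,
negative components truncated at zero and proportions renormalized. The
scored ICC is `1 - (repeat + residual proportions)` — the inter-sample
share. The source assay's prose suggests the looser reading
`1 - repeat proportion`; both values are always reported and a `variant`
argument selects which drives the pass decision. The 95% CI comes from
parametric simulation at the observed design (same sample and repeat
counts, Gaussian components), refitting per replicate, percentile
2.5/97.5, >= 1000 replicates, deterministic given the seed; resampling at
the observed design (rather than a larger one) is the fixed convention
here. A method-of-moments cross-check against REML (`lme4`) agrees within
estimation error in the tests. An all-identical score table is degenerate:
ICC 1 by convention, flagged. Reliability categories: < 0.5 poor,
0.5–0.75 moderate, 0.75–0.9 good, > 0.9 excellent.

Pearson concordance reports r and two-sided p per pair with the
Bonferroni threshold `family_alpha / n_comparisons` (0.05/3 printed as
0.017; decisions use the unrounded value). Percent error is
`mean(100 * (predicted - truth) / truth)` — signed, so under-prediction is
negative — with zero-truth samples excluded under a warning.

## Problem sizes and numerical conventions

The shipped validation runs at desk scale: 20-slide cohorts, 30 immune
accuracy samples, 20 x 3 serial sections, 1000-replicate CIs — sizes at
which every criterion is measurable with comfortable margin while a full
run stays in the minutes range. Coordinates are 0-based, x right / y
down, pixel centres at integers; rasters are stored as 8-bit RGB
(height x width x 3). Images round-trip pixel-identically through PNG and
TIFF; IF pairs are 2-page TIFFs (16-bit); annotations are GeoJSON
polygons with a `role` property from {include, exclude, train_tumor,
train_stroma}; tables are CSV. Desk-scale rasters (up to ~4000 px on a
side) are the supported regime — a whole-slide (pyramidal) adapter is an
extension point, not a feature.

## Known limitations

- The feature vector is a documented stand-in for a proprietary,
  unpublished feature list; classifiers trained here do not transfer to
  other feature definitions (the feature-order hash enforces this).
- Tumor/stroma separation is cell-wise, not region-wise; a cell's
  compartment can disagree with its neighbourhood in thin stromal bands.
- The IF-to-brightfield registration assumes a rigid offset; it does not
  model tissue deformation between serial sections.
- QC thresholds (focus variance-of-Laplacian >= 1e-4, blank-tile fraction
  <= 0.30, saturation <= 0.25) are calibrated on synthetic degradations
  (sigma = 8 blur, painted-white areas) because the underlying quality
  criteria are qualitative; real scanner artifacts will need recalibration.
- CPS (combined positive score) is out of scope.
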