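---
title: "Semi-supervised MIL grading of whole-slide images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised MIL grading of whole-slide images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathomil)
```

## The problem

Colorectal biopsy slides are graded into three ordered diagnostic
classes: non-neoplastic (NNeo), low-grade dysplasia (LG) and high-grade
dysplasia including invasive carcinoma (HG). A digitised whole-slide
image (WSI) is far too large for a single model pass, so it is
decomposed into 512×512 tiles. Slide-level diagnoses are cheap to
obtain from pathology reports; spatial annotations are rare (roughly
one annotated slide in ten). `pathomil` implements a semi-supervised
multiple-instance-learning (MIL) pipeline for this setting: the slide
is a *bag* of tile *instances*, only the bag label is generally known,
and the bag label is assumed to be the **worst case** of its tiles,

$$C_s = \max_n \; C_{s,n}.$$

## The model, stage by stage

**Tissue segmentation and tiling.** The slide is 32× downsampled by
area averaging, converted to HSV, and Otsu's threshold is applied to
the saturation channel; stained tissue is far more saturated than the
whitish scanner background, giving a bimodal histogram. Tiles are laid
on a non-overlapping stride-512 grid at full resolution and kept only
when their entire 16×16 mask footprint is tissue (a 100% tissue
threshold). This drops ragged edge tiles and sharply reduces the tile
count at no measurable cost to slide-level performance. A
constant-saturation image (no tissue at all) yields an empty mask with
a warning rather than an error, since downstream stages treat an empty
bag as a valid "scant tissue" signal.

**Ordinal loss.** Tile classifiers are trained with a differentiable
loss built on the quadratic weighted kappa (QWK),

$$\kappa = 1 - \frac{\sum_{ij} w_{ij} x_{ij}}{\sum_{ij} w_{ij} m_{ij}},
\qquad w_{ij} = \frac{(i-j)^2}{(K-1)^2},$$

where \(x\) is the observed actual-by-predicted matrix and \(m\) the
expected matrix from the marginal products, normalised so
\(\sum m = \sum x\) (under this convention the published confusion
matrix reproduces its published kappa). The training loss is the ratio
\(\sum w\tilde x / \sum w\tilde m\) with a *soft* observed matrix
\(\tilde x_{ij} = \sum_{s: y_s = i} p_{sj}\); on one-hot probabilities
it equals \(1-\kappa\) exactly, which the test suite asserts. The
gradient treats the label marginals as constants; this is exact up to a
per-row constant that the softmax Jacobian annihilates, so gradient
checks are run through the logits. Whether the denominator should be
treated as a constant during differentiation is not derivable from the
published description; both variants are supported
(`detach_denominator`), the ratio's own gradient being the default.

**Supervised pre-training.** Tiles of the strongly annotated subset
carry per-tile labels; a tile overlapping several annotated regions
takes the worst overlapping grade (the worst-case rule again — the
published description does not define mixed-region tiles, so this is a
package decision), and tiles with no lesion pixels are NNeo. The tile
model is trained for 5 epochs, and the epoch with the best validation
QWK is kept. The validation split for this selection is not described
in the published work; we hold out a configurable fraction (default
0.15) of the annotated tiles. Ties on the validation trace resolve to
the later epoch, otherwise flat traces (common with desk-scale
validation sets) would freeze the epoch-1 model.

**Weakly supervised MIL.** Each weak epoch (i) runs inference over all
tiles of all training bags (batch 256, evaluation mode), (ii) ranks
each bag's tiles by the expected value of the predicted grade,
\(E = \sum_{i=1}^{K} i\,p_i\), (iii) keeps the top \(L = 5\) tiles per
bag, and (iv) optimises the model on the selected tiles against the
bag's slide label (batch 32). \(L=1\) is classical max-pooling MIL;
\(L>1\) both stabilises training and increases selected-tile turnover
across epochs, which the test suite verifies empirically. Ranking ties
break to the lower tile index so runs are bit-reproducible.

**Slide prediction and aggregation.** The max-pooling slide prediction
is the argmax of the top-1 tile's probabilities. For the aggregation
pathway, the classifier head is removed and the features of the
\(L_a = 7\) worst tiles are concatenated (reference backbone:
7 × 512 = 3584 values) to train slide-level classifiers: an RBF SVM
(C = 1), KNN (k = 5), a random forest (depth 4, Gini), AdaBoost (3000
stumps), XGBoost (5000 rounds), and two MLPs with hidden layers (75; 5)
and (300; 50) trained by SGD (momentum 0.9, batch 32, initial learning
rate 1e-3), plus two soft-voting ensembles (SVM+KNN and SVM+RF+KNN)
that average member probability vectors. Bags with fewer than \(L_a\)
tiles repeat the lowest-ranked tile's features — a package decision
that keeps the vector length fixed without zero-padding artefacts.
Argmax ties resolve to the lower grade purely for determinism; a
clinically conservative tie policy is a configuration matter, not a
default.

**Interpretability maps.** Every tile's argmax grade is painted as a
16×16 block at `(x/32, y/32)` on the 32×-downsampled canvas (green /
blue / yellow for NNeo / LG / HG, alpha-blended over the thumbnail at
0.45 — the published figures fix the hues but not the RGB values).
Maps reuse the probabilities already computed for slide prediction, so
they add no model passes; tiles excluded by the tissue threshold stay
unpainted.

## The backbone contract

The reference tile model in the published pipeline is a 34-layer
residual network producing 512-dimensional features — a GPU-scale
component. The method itself is architecture-agnostic, so `pathomil`
defines a backbone *contract* (features + head sharing one forward
state) with two configurations:

* `backbone_config("resnet34")` — the reference geometry (F = 512,
  K = 3). It carries no weights in this package and is used for
  analytic contracts such as the 3584-length slide vector.
* `backbone_config("tiny")` — the runnable CPU backbone: a fixed,
  deterministic trunk of 16 pooled texture descriptors per tile (mean
  RGB, saturation/value moments, dark-pixel fractions at three value
  cutoffs, low quantiles, edge energy, and 16-px block-minimum
  statistics) feeding a trainable dense head optimised with the QWK
  loss. Because the trunk is fixed, descriptors are computed once per
  tile and each weak epoch costs milliseconds, which is what makes the
  full three-stage pipeline testable end to end on one CPU.

The published training recipe (Adam, learning rate 6e-6, weight decay
3e-4, batch 32/256, 5 supervised + 30 weak epochs) is kept as the
`train_config()` default. The 6e-6 rate targets fine-tuning of a large
pretrained network; the tiny head trains from scratch and uses 0.01 in
the synthetic experiments.

## The synthetic slide generator

`generate_slide()` renders what the method *assumes* about its inputs:
a whitish background (RGB 245/245/245, saturation ≈ 0), saturated pink
tissue blobs (saturation ≈ 0.3, so the saturation histogram is
reliably bimodal and Otsu recovers tissue with IoU ≥ 0.95), and
elliptical lesion regions with a monotone ordinal texture — NNeo is
plain light pink, LG adds dark-purple spots at ~3% area coverage, HG
denser and larger spots at ~19%. Defaults are 2560×2560 slides whose
dominant tissue blob fully contains a 3×3 grid of interior tiles;
HG lesions occupy ~20% of the tissue so that they majority-cover a few
tiles per slide — consistent with the idea that \(L\) should not exceed
the number of lesion-bearing tiles. Slide labels are implied by the
lesion content through the worst-case rule; each slide draws its own
RNG stream from (dataset seed, slide index), so datasets can be
materialised slide-by-slide, in parallel, or re-materialised
identically from the manifest alone.

What the generator does **not** emulate: stain variability and
scanner colour shifts, tissue folds, pen marks and bubbles, glandular
morphology, pyramid file formats, and the sheer tile counts of real
WSIs (thousands per slide versus ~9 here). Passing the synthetic
recovery experiment therefore shows that the *pipeline machinery* —
segmentation, tiling, ordinal loss, ranking, selection, aggregation,
mapping — is correct and trainable; it says nothing about
histopathological performance on real slides.

## Numerical choices and degenerate inputs

* Otsu runs on a 256-bin histogram; ties in the between-class variance
  go to the lowest split. Degenerate (single-bin) histograms yield an
  empty mask plus a warning.
* Expected-score ranking is a stable sort (ties to the lower tile
  index); `topL` with `L` ≥ bag size returns the whole bag, which also
  makes weak training degenerate gracefully into full supervision by
  slide label.
* Single-class batches in the QWK loss fall back to the weighted-error
  numerator with a warning (the denominator is undefined); single-class
  *datasets* are an error.
* Downsampling by area averaging replicates the last row/column for
  non-multiple dimensions, so the mask always has `ceiling(dim/32)`
  cells and tile windows are clamped to the full-resolution bounds.
* The 8-bit quantisation of generated slides happens at generation
  time, so in-memory slides and TIFF round-trips produce identical
  descriptors.

## Problem sizes used by the test-suite experiments

The synthetic recovery experiment runs 60 slides (mix 0.3/0.4/0.3, 9%
annotated) per seed for seeds 1–3, with 5 supervised and 10 weak
epochs; it reports the held-out max-pooling QWK and the high-grade
localisation recall (fraction of majority-HG tiles predicted HG).
Module tests use smaller slides (1024–2048 px) and descriptor-space
bags with planted signals. The 30-epoch published default remains the
package default for real use.

## Known limitations

* The tiny backbone's fixed descriptors cannot represent morphology
  (gland architecture, nuclear atypia); on real H&E tiles a learned
  convolutional backbone behind the same contract is required.
* AdaBoost is a SAMME implementation over depth-1 `rpart` stumps;
  with thousands of estimators on wide inputs it is the slowest
  aggregator here, unlike optimised reference implementations.
* The SVM's probability estimates come from Platt-type scaling fitted
  by cross-validation inside `e1071`; on very small training sets they
  can disagree with the SVM's own decision rule, which is why the SVM's
  class prediction uses the decision rule directly and probabilities
  are reserved for soft voting.
* Network calibration of the tile model is deliberately out of scope;
  over-confidence on severe cases raises sensitivity, which is the
  clinically preferred failure mode for a screening aid.
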