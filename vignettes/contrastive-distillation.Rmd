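---
title: "Contrastive distillation for slice-based liver segmentation"
author: "cdseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive distillation for slice-based liver segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Liver segmentation of 3D tomographic scans must generalize to imaging
domains never seen in training: scanners, contrast phases and modalities
vary enormously, while labels are scarce. `cdseg` implements a pipeline
built around that constraint. A volume is processed as its ordered set of
2D axial slices (the first array axis of a `VolumeRecord` is the
cranio-caudal z axis, enforced by canonical RAS reorientation on load).
Three stages act on each slice:

1. **Frozen feature extraction.** A fixed dense feature extractor
   \(\mathcal F\) maps a preprocessed slice to a \(C \times H \times W\)
   feature grid. Freezing means no gradient ever reaches
   \(\mathcal F\) — its role is to supply a domain-stable similarity
   structure, and `parameterDigest()` certifies after any amount of
   training that it has not moved.
2. **Contrastive distillation.** A small trainable head \(\mathcal C\)
   (exactly two convolutions with a ReLU between) is trained so that the
   dense cosine-correspondence structure of its features reproduces —
   and sharpens — that of the frozen extractor. For two slices \(x, y\)
   the correspondence tensor is
   \(\mathcal X_{hwij}(\lambda,x,y) = \langle \lambda(x)_{:hw},
   \lambda(y)_{:ij}\rangle / (\lVert\lambda(x)_{:hw}\rVert\,
   \lVert\lambda(y)_{:ij}\rVert + \varepsilon)\), and the loss for a pair
   with bias \(b\) is
   \[
     \mathcal L_{cr}(x,y,b) = -\operatorname{mean}_{hwij}
     \bigl(\mathcal S(\mathcal X(\mathcal F,x,y))_{hwij} - b\bigr)\,
     \max\bigl(\mathcal X(\mathcal C\circ\mathcal F,x,y)_{hwij},\,0\bigr),
   \]
   where \(\mathcal S\) subtracts, per source position \((h,w)\), the
   mean over target positions (spatial centering). Teacher
   correspondences above the bias attract the student correspondence
   toward 1; those below push it to 0, where the ReLU gate closes. The
   full distillation term for an anchor slice combines a self pair, the
   neighbouring slices \(i\pm1\) as positives, and the circularly
   maximally distant slice as negative:
   \(\mathcal L_{cd}(x) = \mathcal L_{cr}(x,x,b_{self}) +
   \mathcal L_{cr}(x,x^+,b_+) + \mathcal L_{cr}(x,x^-,b_-)\).
3. **Learnable upsampling.** The head features are decoded by five
   upsampling-then-convolution stages (bilinear 2x, 3x3 convolution,
   batch norm, ReLU, dropout), a skip connection concatenating the
   original preprocessed slice, and three final convolutions producing
   per-pixel class logits. The supervised objective combines Focal,
   Tversky, log-IoU and entropy terms with the distillation loss.

## Slice-position sampling

Fixed-distance thresholds on anatomical position are unreliable across
patients, so positives and negatives are defined purely positionally:
positives are `i - 1` and `i + 1` (clamped at volume boundaries —
anatomical adjacency does not wrap), the negative is
`(i + floor(n/2)) mod n`. The printed offset `i + n/2` overruns the scan
for anchors in its upper half; modular wraparound is the only reading
that always yields a valid and (circularly) maximally distant slice, and
is what `sampleTriplet()` implements. Indices are 0-based throughout the
sampler so the arithmetic stays half-open and unambiguous. Volumes with
fewer than 4 slices cannot produce a triplet whose roles are disjoint;
they are flagged degenerate and contribute no contrastive term.

## Reductions and ranges

The correspondence loss uses a **mean** (not a sum) over
\((h,w,i,j)\), and the positive term averages over however many
positives the anchor has. A raw sum would scale with the feature-grid
resolution and could not stay inside the bounded range that the
distillation term is expected to occupy (about \([-1, 0]\) once
training has aligned correspondences); the mean keeps the term
resolution-independent. The entropy weight default 0.03 keeps the
weighted entropy term of a binary map inside \([0, 0.02)\) because the
per-pixel entropy is at most \(\ln 2\).

## Bias calibration

The three biases default to \(b_{self} = 0.15\), \(b_+ = 0.15\),
\(b_- = 0.75\) and are held fixed during training. What is actually
specified about them is an *outcome*: at the end of training the mean
head-feature similarity of a slice with itself should be about 0.05,
with its positives about 0.0, and with its negative about \(-0.05\).
The shipped defaults were calibrated on the phantom study against those
targets: with the tiny backbone, whose centered teacher similarities
have median \(\approx 0\) and upper decile \(\approx 0.3\), placing
\(b_{self}\) and \(b_+\) near the teacher's upper quartile attracts
only genuinely corresponding pairs and lands the end-of-training mean
self similarity at \(\approx 0.05\). A user pairing the loss with a
different backbone should recalibrate the same way.
`selfCorrespondenceHistogram()` is the diagnostic: successful
distillation drives the within-slice similarity distribution toward a
bi-modal shape peaking at alignment (1) and orthogonality (0).

Two implementation details matter for how fast that distribution
moves. First, cosine similarities reorganise at a rate inversely
proportional to the head-feature norm (cosine is scale invariant, so
only angular motion counts); the head's output layer is therefore
initialised at small scale (`initGain = 0.1` in [buildHead()]), which
the batch norm of the first decoder stage absorbs downstream. Second,
the ReLU gate freezes any correspondence that reaches zero, which is
what concentrates the repelled mass exactly at orthogonality.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `intensityWindow` | (-100, 400) | CT soft-tissue clamp before normalization (HU) |
| `normalization` | zscore | per-slice normalization; constant slices map to zeros |
| `targetSize` | 224 x 224 | network input; must be a multiple of the backbone stride (the phantom experiments use 64 x 64, the native phantom resolution) |
| `headChannels` | 32 | output channels of the two-conv head |
| `decoderChannels` | (64, 48, 32, 24, 16) | widths of the five decoder stages |
| `dropoutRate` | 0.1 | dropout inside decoder stages |
| `bSelf, bPos, bNeg` | 0.15, 0.15, 0.75 | correspondence biases (see calibration) |
| `initGain` (head) | 0.1 | initial scale of the head output layer |
| `wCd, wFocal, wTversky, wLogIou` | 1 | objective weights |
| `wEntropy` | 0.03 | entropy weight (see range note above) |
| `batchSize` | 8 | anchors per optimization step |
| `initialLr` | 1e-4 | RAdam learning rate |
| `weightDecay` | 1e-5 | L2 decay |
| `plateauPatience` | 10 | epochs without monitor improvement before lr x 0.1 |
| `maxEpochs` | 150 | training budget |

The preprocessing defaults are conventional liver-CT choices, declared
rather than inferred; every one of them is configurable. Focal
(\(\gamma = 2, \alpha = 0.25\)) and Tversky (\(\alpha = \beta = 0.5\),
i.e. soft Dice) parameters are the canonical ones.

## Design choices where the design was open

* **Decoder resolution schedule.** Five doubling stages overshoot any
  backbone stride below 32. By default the decoder stops doubling once
  the input resolution is reached and lets the remaining stages refine
  at constant resolution; convolving at 4-16x the useful resolution and
  then downsampling costs several times the entire rest of the pipeline
  without adding output information. The literal
  always-double-then-resize variant is available
  (`modelConfig(capUpsampling = FALSE)`) and is shape-tested; both
  undo the backbone stride exactly.
* **Decoder input.** The decoder consumes the head output rather than
  raw backbone features, so the distilled representation is the one
  decoded; this matches a pipeline in which contrastive distillation
  sits between feature extraction and upsampling.
* **Skip connection.** Channel concatenation of the decoded map with the
  preprocessed input slice, the U-Net convention.
* **Upsampling operator.** Non-learned bilinear interpolation followed
  by convolution ("upsampling-then-convolution"), avoiding the
  checkerboard artifacts of transposed convolutions.
* **Logit layer.** No normalization or activation after the last
  convolution.
* **Monitoring metric.** Mean volume DICE on the held-out monitoring set
  (5 scans per source dataset by default), evaluated once per epoch;
  volumes rather than slices, since the clinical quantity is volumetric
  overlap.
* **Epoch.** One pass over all training slices in randomized order.
* **Empty-mask conventions.** DICE of two empty masks is 1; empty vs
  non-empty is 0. Surface distances are undefined for empty masks and
  reported missing, never 0.
* **Surface definition.** A surface voxel is a foreground voxel with at
  least one background 6-neighbour; the array border counts as
  background. Distances are measured between voxel centres in
  millimetres using the header spacing.
* **Weight digests.** Frozenness is certified by an order-stable
  checksum over all parameters rather than by trusting the absence of
  an optimizer update path.

## Numerical choices

Cosine denominators carry \(\varepsilon = 10^{-8}\); zero feature
vectors are defined to have similarity 0 (and receive zero gradient).
Loss probabilities are clamped to \([10^{-6}, 1]\); the soft-count
denominators of Tversky and log-IoU carry the same \(\varepsilon\), so
disjoint predictions stay finite. Batch norm uses batch statistics in
training and running statistics (momentum 0.1) in evaluation, which is
why inference is deterministic. Argmax ties at exactly 0.5 resolve to
the foreground class. All randomness — initialisation, shuffling,
dropout, phantom geometry — flows from explicit seeds through R's RNG,
so training histories reproduce bitwise under a fixed seed on a fixed
BLAS.

## What the phantom generator emulates — and what it does not

`generatePhantom()` builds a deformed superellipsoid "liver" (sublevel
set of a superellipsoid field plus a low-frequency cosine perturbation;
threshold chosen by quantile so the volume fraction lands in the
configured range, with a connectivity repair keeping one 26-connected
component), distractor blobs in distinct intensity bands placed away
from the liver, a smooth background gradient, additive Gaussian noise,
and a monotone intensity remapping per modality style (`ct_like` is
HU-like; `mr_like` is a logistic remap of the same geometry). Defaults —
32 x 64 x 64 voxels at (3.0, 1.5, 1.5) mm, liver fraction 10-20%, three
distractors, noise sd 10 — are chosen once as a CPU-scale, anisotropic
stand-in for abdominal CT.

Two properties matter for the method and are tested: neighbouring axial
mask slices overlap heavily (mean adjacent-slice DICE at least 0.7)
while slices half a volume apart barely overlap — exactly the assumption
the positional sampler exploits — and the liver mean intensity stays at
least twice the noise sd away from the background mean, so the task is
learnable at desk scale.

What passing on phantoms does **not** show: robustness to real
inter-patient anatomy, pathology, contrast phases, acquisition
artifacts, or genuine cross-modality appearance shift. The phantom
study validates the machinery (losses, sampler, optimization, metrics),
not clinical performance.

## Problem sizes used in the shipped experiments

The end-to-end phantom study trains on 8 of 10 default phantoms with 2
held out, a tiny stride-8 / 32-channel frozen backbone at 64 x 64 input,
batch 8, lr 1e-4, and 16 epochs — sizes chosen so the full study runs
comfortably on a single CPU while still exercising every moving part,
including the plateau schedule and the bi-modality diagnostic. Unit
tests use smaller 8-16 slice phantoms at 16 x 16 with a stride-4
backbone.

## Known limitations

At the phantom study's scale (8 training volumes, at most 20 epochs,
640 optimization steps) the distillation visibly builds the expected
clustering — background patch pairs orthogonalize to similarity
\(\approx 0\), organ-vs-background pairs turn slightly negative, and
organ patch pairs climb (median \(\approx 0.5\), upper decile
\(\approx 0.85\) at the end of training) — but the aligned mode has
not fully sharpened into the \([0.9, 1]\) bin by the end of the
budget; only the exact self-correspondences sit there. Sharpening the
aligned peak the rest of the way needs one to two orders of magnitude
more optimization, which is what the full-scale setting (hundreds of
slices per scan, 150 epochs) provides.

* The 2D slice-wise decoder ignores inter-slice context at inference;
  the contrastive term injects it only through the latent space.
* Surface distances use brute-force nearest-point search, adequate for
  desk-scale masks but quadratic in surface size.
* The ViT adapter runs any weights supplied in its RDS format but the
  package ships no weights and no downloader; all shipped experiments
  use the tiny frozen conv pyramid.
* No post-processing (e.g. largest-component filtering) is applied by
  default; none is described for the pipeline the package implements.
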