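# cdseg — contrastive distillation for liver segmentation

`cdseg` is an R package for slice-based segmentation of the liver in 3D
tomographic volumes, built for the *in the wild* setting: models trained
on a handful of labelled scans from some imaging domains must still work
on domains never seen during training. It is aimed at researchers in
medical image analysis who want a fully reproducible, CPU-scale
implementation of a contrastive-distillation segmentation pipeline —
including a synthetic phantom generator so that every component can be
exercised end to end without downloading any imaging data.

## The method

A volume is processed as its ordered axial slices. Three stages act on
each preprocessed slice *x*:

1. **Frozen feature extraction.** A fixed extractor 𝓕 (a deterministic
   tiny conv pyramid, or a ViT variant loaded from user-supplied
   weights) produces a dense feature grid 𝓕(x) ∈ ℝ^(C×H×W). No gradient
   ever reaches 𝓕; `parameterDigest()` certifies this.
2. **Contrastive distillation.** A trainable two-conv head 𝓒 is fitted
   with the dense correspondence loss

   L_cr(x, y, b) = −mean_{hwij} ( S(𝓧(𝓕, x, y))_{hwij} − b ) · max( 𝓧(𝓒∘𝓕, x, y)_{hwij}, 0 )

   where 𝓧 is the pairwise cosine similarity between feature vectors at
   positions (h,w) of x and (i,j) of y, S is spatial centering (per
   (h,w), subtract the mean over (i,j)), and b a collapse-preventing
   bias. For anchor slice i, positives are the neighbouring slices
   i±1 and the negative is the circularly farthest slice
   (i + ⌊n/2⌋) mod n:

   L_cd(x) = L_cr(x, x, b_self) + L_cr(x, x⁺, b₊) + L_cr(x, x⁻, b₋).

3. **Learnable upsampling.** Five upsampling-then-convolution stages, a
   skip connection to the raw input slice, and three final convolutions
   produce per-pixel class probabilities, trained with
   w_cd·L_cd + Focal + Tversky + log-IoU + 0.03·Entropy under RAdam
   (batch 8, lr 1e-4, weight decay 1e-5, lr ÷ 10 after 10 epochs
   without improvement of the held-out volume DICE).

Evaluation reports DICE, average symmetric surface distance (ASSD, mm)
and maximum symmetric surface distance (MSSD, mm), with means and
across-scan standard deviations, plus paired t-tests for method
comparison (including a zero-standard-deviation comparator for methods
only published as a mean).

## Worked example

```r
library(cdseg)

# ten synthetic abdominal phantoms; 8 train / 2 held out
cfg   <- phantomConfig()                       # 32 x 64 x 64, (3, 1.5, 1.5) mm
vols  <- lapply(1:10, function(i) generatePhantom(cfg, 100 + i))
split <- holdoutSplit(vols, nTest = 2, seed = 1)

backbone <- tinyBackbone(seed = 1, channels = 32, stride = 8)
model <- buildSegmentationModel(backbone, modelConfig(),
                                preprocessConfig(targetSize = c(64, 64)),
                                seed = 1)
fit <- trainSegmentation(model, split$train, split$test,
                         config = trainConfig(maxEpochs = 16, seed = 1),
                         verbose = TRUE)
#> epoch   1  lr 1.00e-04  total 8.5792  cd 0.2990  train DICE 0.449  monitor DICE 0.505
#> ...
#> epoch  16  lr 1.00e-04  total 6.5234  cd 0.0447  train DICE 0.900  monitor DICE 0.916

preds <- lapply(split$test, function(v) inferVolume(fit$model, v))
evaluateSegmentations(preds, lapply(split$test, volMask),
                      lapply(split$test, spacingMm))
#> MetricReport over 2 volumes
#>   metric       mean           sd
#>     dice  0.9163077  0.007154848
#>  assd_mm  1.6333431  0.231010121
#>  mssd_mm 35.8524473 13.113124950
```

The `total` column is the weighted objective; `cd` is the (unweighted)
contrastive-distillation term, which shrinks as correspondences align.
The monitor DICE is the mean volume DICE on the held-out phantoms — the
quantity the plateau schedule watches. The held-out masks overlap the
ground truth at DICE 0.92 with sub-voxel-scale average surface error
(1.6 mm at 1.5–3 mm spacing); the maximum surface distance is dominated
by a single distant false-positive blob, which `surfaceDistances()`
reports honestly rather than filtering away (no post-processing is
applied by default). The run takes a few minutes on one CPU.
`selfCorrespondenceHistogram()` shows the characteristic bi-modal
similarity distribution (peaks at alignment 1 and orthogonality 0) after
distillation has worked.

A command-line interface wrapping the same functions ships in
`inst/cli/cdseg.R`:

```sh
Rscript inst/cli/cdseg.R synth --n 10 --seed 1 --out data/
Rscript inst/cli/cdseg.R train --config cfg.yaml --out run/
Rscript inst/cli/cdseg.R infer --checkpoint run/checkpoint.rds \
        --in data/vol_001.nii.gz --out pred_001.nii.gz
Rscript inst/cli/cdseg.R evaluate --pred preds/ --ref data/ --out metrics.csv
```

## Package layout

- `R/` — S4 classes (`VolumeRecord`, `FeatureExtractor`,
  `SegmentationModel`, `MetricReport`, configuration classes) and the
  pipeline: NIfTI IO, phantom generator, backbones, contrastive core,
  model, objectives, training loop, metrics, CLI commands.
- `src/` — Rcpp/RcppArmadillo kernels: convolution forward/backward,
  bilinear/nearest resizing with exact adjoints, surface-voxel
  extraction, nearest-surface distances, 26-connectivity labelling.
- `vignettes/contrastive-distillation.Rmd` — the model, its
  assumptions, parameter meanings and the package's design choices.
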