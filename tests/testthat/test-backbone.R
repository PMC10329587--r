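# Frozen feature extractors: shape contract, determinism, digests, and
# the ViT adapter (exercised with synthetic weights only; the package
# never downloads anything).

test_that("tiny backbone obeys the shape contract and is deterministic", {
  bb <- tinyBackbone(1L, channels = 32L, stride = 8L)
  x <- matrix(rnorm(64 * 64), 64, 64)
  f <- extractFeatures(bb, x)
  expect_length(f, 1L)
  expect_identical(dim(f[[1]]), c(32L, 8L, 8L))
  expect_true(all(is.finite(f[[1]])))
  expect_identical(extractFeatures(bb, x), f)

  # batch input: one map per slice
  xs <- array(rnorm(32 * 32 * 3), dim = c(32, 32, 3))
  fs <- extractFeatures(bb, xs)
  expect_length(fs, 3L)
  expect_identical(dim(fs[[1]]), c(32L, 4L, 4L))
})

test_that("backbone digests identify parameter sets", {
  expect_identical(parameterDigest(tinyBackbone(1L, 16L, 4L)),
                   parameterDigest(tinyBackbone(1L, 16L, 4L)))
  expect_false(identical(parameterDigest(tinyBackbone(1L, 16L, 4L)),
                         parameterDigest(tinyBackbone(2L, 16L, 4L))))
})

test_that("indivisible input sizes raise an error naming the multiple", {
  bb <- tinyBackbone(1L, 16L, 8L)
  err <- tryCatch(extractFeatures(bb, matrix(0, 60, 64)),
                  error = function(e) e)
  expect_s3_class(err, "cdseg_incompatible_size")
  expect_match(conditionMessage(err), "8")
})

test_that("non-power-of-two strides are rejected", {
  expect_error(tinyBackbone(1L, 16L, 6L), class = "cdseg_bad_argument")
})

test_that("features on a phantom slice are finite everywhere", {
  rec <- generatePhantom(tiny_phantom_cfg(), 6L)
  s <- preprocessSlice(extractAxialSlices(rec)$images[[4]],
                       preprocessConfig(targetSize = c(16L, 16L)))
  f <- extractFeatures(tinyBackbone(3L, 8L, 4L), s)
  expect_true(all(is.finite(f[[1]])))
})

make_vit_weights <- function(spec, seed = 1L) {
  set.seed(seed)
  D <- spec$dim
  g <- spec$patch
  ntok <- (224L %/% g)^2
  w <- list(
    "patch_embed.w" = array(rnorm(g * g * 1 * D, sd = 0.02),
                            dim = c(g, g, 1L, D)),
    "patch_embed.b" = numeric(D),
    "cls_token" = rnorm(D, sd = 0.02),
    "pos_embed" = matrix(rnorm((1 + ntok) * D, sd = 0.02), 1 + ntok, D),
    "norm.g" = rep(1, D), "norm.b" = numeric(D)
  )
  for (k in seq_len(spec$depth)) {
    w[[sprintf("block%d.norm1.g", k)]] <- rep(1, D)
    w[[sprintf("block%d.norm1.b", k)]] <- numeric(D)
    w[[sprintf("block%d.qkv.w", k)]] <- matrix(rnorm(D * 3 * D, sd = 0.02),
                                               D, 3 * D)
    w[[sprintf("block%d.qkv.b", k)]] <- numeric(3 * D)
    w[[sprintf("block%d.proj.w", k)]] <- matrix(rnorm(D * D, sd = 0.02),
                                                D, D)
    w[[sprintf("block%d.proj.b", k)]] <- numeric(D)
    w[[sprintf("block%d.norm2.g", k)]] <- rep(1, D)
    w[[sprintf("block%d.norm2.b", k)]] <- numeric(D)
    w[[sprintf("block%d.mlp1.w", k)]] <- matrix(
      rnorm(D * 4 * D, sd = 0.02), D, 4 * D)
    w[[sprintf("block%d.mlp1.b", k)]] <- numeric(4 * D)
    w[[sprintf("block%d.mlp2.w", k)]] <- matrix(
      rnorm(4 * D * D, sd = 0.02), 4 * D, D)
    w[[sprintf("block%d.mlp2.b", k)]] <- numeric(D)
  }
  w
}

test_that("ViT adapter maps 224x224 input to the patch grid (synthetic weights)", {
  spec <- cdseg:::vit_variant_spec("small/16")
  wp <- withr::local_tempfile(fileext = ".rds")
  saveRDS(make_vit_weights(spec), wp)
  bb <- vitBackbone("small/16", wp, featureLayer = 2L)
  expect_identical(bb@stride, 16L)
  expect_identical(bb@channels, 384L)
  f <- extractFeatures(bb, matrix(rnorm(224 * 224), 224, 224))
  expect_identical(dim(f[[1]]), c(384L, 14L, 14L))
  expect_true(all(is.finite(f[[1]])))
  # the extractor is frozen and deterministic
  expect_identical(parameterDigest(bb),
                   parameterDigest(vitBackbone("small/16", wp)))
})

test_that("ViT patch-grid arithmetic holds across variants", {
  expect_identical(cdseg:::vit_variant_spec("small/16")$patch, 16L)
  expect_identical(cdseg:::vit_variant_spec("base/8")$patch, 8L)
  expect_identical(224L %/% cdseg:::vit_variant_spec("small/16")$patch, 14L)
  expect_identical(224L %/% cdseg:::vit_variant_spec("base/8")$patch, 28L)
})

test_that("missing or mismatched ViT weights never silently fall back", {
  expect_error(vitBackbone("small/16", file.path(tempdir(), "no.rds")),
               class = "cdseg_weights_unavailable")
  spec <- cdseg:::vit_variant_spec("small/16")
  w <- make_vit_weights(spec)
  w[["patch_embed.w"]] <- array(0, dim = c(8, 8, 1, 384))  # wrong patch
  wp <- withr::local_tempfile(fileext = ".rds")
  saveRDS(w, wp)
  expect_error(vitBackbone("small/16", wp),
               class = "cdseg_weights_unavailable")
})
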