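test_that("zero irregularity draws an ellipse with the analytic area", {
  set.seed(19)
  cfg <- synth_config(height = 128, width = 128, boundary_irregularity = 0)
  for (i in 1:5) {
    mk <- generate_mask(cfg)
    geo <- attr(mk, "geometry")
    analytic <- pi * geo$radii[1] * geo$radii[2]
    expect_equal(sum(mk), analytic, tolerance = 0.02)
  }
})

test_that("masks are single connected components inside the frame", {
  set.seed(23)
  cfg <- synth_config(height = 64, width = 64, boundary_irregularity = 0.4)
  for (i in 1:10) {
    mk <- generate_mask(cfg)
    labels <- EBImage::bwlabel(mk)
    expect_equal(max(labels), 1)
    # fully inside: no foreground on the border
    expect_equal(sum(mk[c(1, nrow(mk)), ]) + sum(mk[, c(1, ncol(mk))]), 0)
    frac <- mean(mk)
    expect_gte(frac, cfg$lesion_area_fraction[1])
    expect_lte(frac, cfg$lesion_area_fraction[2])
  }
})

test_that("mask generation is deterministic under a fixed stream", {
  cfg <- small_synth_cfg()
  set.seed(99); a <- generate_mask(cfg)
  set.seed(99); b <- generate_mask(cfg)
  expect_identical(a, b)
})

test_that("an infeasible area range is rejected", {
  expect_error(synth_config(height = 64, width = 64,
                            lesion_area_fraction = c(0.5, 1.2)))
  cfg <- synth_config(height = 64, width = 64,
                      lesion_area_fraction = c(0.9, 0.95))
  set.seed(1)
  expect_error(generate_mask(cfg), "infeasible|could not place")
})

test_that("rendered images are darker inside the lesion and clipped", {
  set.seed(41)
  cfg <- small_synth_cfg()
  for (i in 1:20) {
    mk <- generate_mask(cfg)
    im <- render_image(mk, cfg)
    expect_true(all(im >= 0 & im <= 1))
    sel <- as.logical(mk)
    inside <- mean(c(im[, , 1][sel], im[, , 2][sel], im[, , 3][sel]))
    outside <- mean(c(im[, , 1][!sel], im[, , 2][!sel], im[, , 3][!sel]))
    expect_lt(inside, outside)
  }
})

test_that("hair-free, vignette-free configuration is a two-region field", {
  cfg <- synth_config(height = 64, width = 64, hair_count = c(0, 0),
                      vignette = FALSE)
  set.seed(51)
  mk <- generate_mask(cfg)
  im <- render_image(mk, cfg)
  expect_equal(attr(im, "hair_count"), 0)
  # without hairs or vignette the background is a smooth multiplicative
  # field: its per-channel spread stays small
  bg <- im[, , 1][!as.logical(mk)]
  expect_lt(stats::sd(bg) / mean(bg), 0.1)
})

test_that("datasets are reproducible with manifests describing each sample", {
  cfg <- small_synth_cfg(seed = 7)
  d1 <- generate_dataset(12, cfg)
  d2 <- generate_dataset(12, cfg)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$pairs, d2$pairs)
  expect_equal(nrow(d1$manifest), 12)
  expect_true(all(d1$manifest$area_fraction >= cfg$lesion_area_fraction[1] &
                    d1$manifest$area_fraction <= cfg$lesion_area_fraction[2]))
  expect_equal(sum(d1$manifest$class_label == "melanoma"), round(0.2 * 12))
  # manifest area fractions match the delivered masks
  expect_equal(d1$manifest$area_fraction,
               vapply(d1$pairs, function(p) mean(p$mask), numeric(1)))
})

test_that("the oracle segmenter scores perfectly on any generated dataset", {
  ds <- generate_dataset(6, small_synth_cfg(seed = 77))
  oracle <- function(img) {
    for (p in ds$pairs) if (identical(p$image, img)) return(p$mask)
    stop("unknown image")
  }
  m <- evaluate_split(ds$pairs, oracle, aggregation = "global_pixels")
  expect_equal(m$jaccard, 100)
  expect_equal(m$dice, 100)
  expect_equal(m$accuracy, 100)
})

test_that("boundary irregularity raises the perimeter-to-area compactness", {
  compactness <- function(irr, seeds) {
    vals <- numeric(length(seeds))
    for (i in seq_along(seeds)) {
      set.seed(seeds[i])
      mk <- generate_mask(synth_config(height = 96, width = 96,
                                       boundary_irregularity = irr,
                                       lesion_area_fraction = c(0.1, 0.2)))
      # perimeter: foreground pixels with a 4-neighbour background
      inner <- mk[2:95, 2:95]
      nb <- mk[1:94, 2:95] + mk[3:96, 2:95] + mk[2:95, 1:94] + mk[2:95, 3:96]
      per <- sum(inner == 1 & nb < 4)
      vals[i] <- per^2 / sum(mk)
    }
    mean(vals)
  }
  seeds <- 1:12
  c0 <- compactness(0, seeds)
  c1 <- compactness(0.35, seeds)
  c2 <- compactness(0.7, seeds)
  expect_lt(c0, c1)
  expect_lt(c1, c2)
})
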