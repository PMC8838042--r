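# The published per-layer parameter cells of the reference architecture,
# conv and batch-norm rows in network order (the independent hand-transcribed
# oracle the accountant is checked against).
published_conv_cells <- c(
  1792, 36928, 73856, 147584, 295168, 590080, 590080, 1180160,
  2359808, 2359808, 2359808, 2359808, 2359808,
  4719104, 2359808, 2359808, 2359808, 2359808, 1179904,
  590080, 590080, 295040, 147584, 73792, 36928, 577)
published_bn_cells <- c(
  256, 256, 512, 512, 1024, 1024, 1024, 2048, 2048, 2048, 2048, 2048, 2048,
  2048, 2048, 2048, 2048, 2048, 1024, 1024, 1024, 512, 512, 256, 256, 4)

test_that("the reference spec reproduces the published ladder", {
  spec <- modified_unet_spec()
  ly <- spec$layers

  expect_equal(sum(ly$kind == "conv"), 26)
  expect_equal(sum(ly$kind == "batch_norm"), 26)
  expect_equal(sum(ly$kind == "max_pool"), 5)
  expect_equal(sum(ly$kind == "upsample"), 5)
  expect_equal(sum(ly$kind == "concat_skip"), 1)

  first_conv <- ly[ly$kind == "conv", ][1, ]
  expect_equal(first_conv$in_channels, 3)
  expect_equal(first_conv$out_channels, 64)
  expect_true(all(ly$kernel[ly$kind == "conv"] == 3))

  # encoder spatial ladder halves five times: 192x256 down to 6x8
  pools <- ly[ly$kind == "max_pool", ]
  expect_equal(pools$in_height, c(192, 96, 48, 24, 12))
  expect_equal(pools$out_height, c(96, 48, 24, 12, 6))
  expect_equal(pools$out_width[5], 8)

  # the single concatenation sits at the 12x16 level and yields 1024 channels
  cat_row <- ly[ly$kind == "concat_skip", ]
  expect_equal(nrow(cat_row), 1)
  expect_equal(c(cat_row$in_height, cat_row$in_width), c(12, 16))
  expect_equal(cat_row$out_channels, 1024)

  # final layer restores the input frame with one sigmoid channel
  last <- ly[nrow(ly), ]
  expect_equal(c(last$out_height, last$out_width, last$out_channels),
               c(192, 256, 1))
  final_conv <- ly[ly$kind == "conv", ][26, ]
  expect_equal(final_conv$activation, "sigmoid")
})

test_that("count_layer_params reproduces every published cell", {
  spec <- modified_unet_spec()
  ly <- spec$layers
  conv_counts <- vapply(which(ly$kind == "conv"),
                        function(i) count_layer_params(ly[i, ]), integer(1))
  bn_counts <- vapply(which(ly$kind == "batch_norm"),
                      function(i) count_layer_params(ly[i, ]), integer(1))
  expect_equal(conv_counts, published_conv_cells)
  expect_equal(bn_counts, published_bn_cells)

  # closed-form spot checks
  expect_equal(count_layer_params(list(kind = "conv", kernel = 1,
                                       in_channels = 1, out_channels = 1)), 2)
  expect_equal(count_layer_params(list(kind = "batch_norm",
                                       out_channels = 64)), 256)
  expect_equal(count_layer_params(list(kind = "max_pool")), 0)
  expect_error(count_layer_params(list(kind = "wavelet")), "wavelet")
})

test_that("model totals match the published bookkeeping", {
  pc <- count_model_params(modified_unet_spec())
  expect_equal(pc$non_trainable_total, 15874)
  expect_equal(pc$grand_total, sum(published_conv_cells, published_bn_cells))
  expect_equal(pc$grand_total, 31818757)
  expect_equal(pc$grand_total, sum(pc$per_layer$count))
  expect_equal(pc$trainable_total + pc$non_trainable_total, pc$grand_total)
})

test_that("a spec without batch norm has zero non-trainable parameters", {
  layers <- tibble::tibble(
    index = 1:2, kind = "conv", kernel = 3L,
    in_channels = c(3L, 4L), out_channels = c(4L, 1L),
    in_height = 32L, in_width = 32L, out_height = 32L, out_width = 32L,
    activation = c("relu", "sigmoid"), skip_from = NA_integer_)
  spec <- structure(list(layers = layers, input_shape = c(32L, 32L, 3L),
                         skip = "single", width_multiplier = 1, dropout = 0),
                    class = "unet_spec")
  pc <- count_model_params(spec)
  expect_equal(pc$non_trainable_total, 0)
  expect_equal(pc$grand_total, (27 * 4 + 4) + (9 * 4 + 1))
  expect_equal(pc$trainable_total, pc$grand_total)
})

test_that("self-check reports the footer discrepancy without reconciling it", {
  sc <- spec_self_check(modified_unet_spec())
  expect_true(all(sc$rows$match))
  expect_equal(nrow(sc$rows), 52)
  expect_equal(sc$computed_non_trainable_total,
               sc$published_non_trainable_total)
  expect_equal(sc$published_grand_total, 33393669)
  expect_equal(sc$computed_grand_total, 31818757)
  expect_equal(sc$footer_discrepancy, 33393669 - 31818757)
})

test_that("width multiplier scales channels with the exact per-layer formula", {
  for (m in c(1 / 2, 1 / 4)) {
    sp <- modified_unet_spec(width_multiplier = m)
    ly <- sp$layers
    full <- modified_unet_spec()$layers
    scaled <- pmax(1, round(full$out_channels[full$kind == "conv"] * m))
    scaled[length(scaled)] <- 1   # head stays single-channel
    expect_equal(ly$out_channels[ly$kind == "conv"], scaled)
    # every conv still obeys k^2*cin*cout + cout exactly
    convs <- ly[ly$kind == "conv", ]
    expect_equal(vapply(seq_len(nrow(convs)),
                        function(i) count_layer_params(convs[i, ]),
                        integer(1)),
                 as.integer(9 * convs$in_channels * convs$out_channels +
                              convs$out_channels))
  }
})

test_that("full skip wiring concatenates at every decoder level", {
  sp <- modified_unet_spec(skip = "full", width_multiplier = 1 / 8)
  expect_equal(sum(sp$layers$kind == "concat_skip"), 5)
  expect_silent(lesionseg:::validate_unet_spec(sp))
})

test_that("invalid input geometry is rejected with the divisibility rule", {
  expect_error(modified_unet_spec(input_shape = c(100, 256, 3)),
               "divisible by 2\\^5")
})

test_that("architecture YAML round-trips exactly", {
  sp <- modified_unet_spec(width_multiplier = 1 / 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_architecture(sp, path)
  sp2 <- read_architecture(path)
  expect_equal(sp2$layers, sp$layers)
  expect_equal(sp2$input_shape, sp$input_shape)
  expect_equal(sp2$width_multiplier, sp$width_multiplier)
  # a second export is byte-identical (deterministic writes)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_architecture(sp2, path2)
  expect_identical(readLines(path), readLines(path2))
})
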