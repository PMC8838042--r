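test_that("forward pass maps images to probability maps of equal size", {
  net <- build_network(tiny_spec(), seed = 1)
  set.seed(2)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  out <- lesionseg:::unet_forward(net, x)$out
  expect_equal(dim(out), c(32, 32, 1, 2))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("builder and accountant agree exactly on parameter counts", {
  for (m in c(1, 1 / 4)) {
    sp <- modified_unet_spec(width_multiplier = m)
    net <- build_network(sp, seed = 1)
    measured <- network_param_count(net)
    declared <- count_model_params(sp)
    expect_identical(measured$trainable, declared$trainable_total)
    expect_identical(measured$non_trainable, declared$non_trainable_total)
    expect_identical(measured$total, declared$grand_total)
  }
})

test_that("equal seeds build identical networks; different seeds differ", {
  sp <- tiny_spec()
  set.seed(123)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  a <- lesionseg:::unet_forward(build_network(sp, seed = 5), x)$out
  b <- lesionseg:::unet_forward(build_network(sp, seed = 5), x)$out
  c <- lesionseg:::unet_forward(build_network(sp, seed = 6), x)$out
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("inputs with indivisible geometry are rejected", {
  net <- build_network(tiny_spec(), seed = 1)
  x <- array(0.5, c(64, 64, 3, 1))
  expect_error(lesionseg:::unet_forward(net, x), "does not match")
  sp <- modified_unet_spec(input_shape = c(64, 64, 3),
                          width_multiplier = 1 / 16)
  bad <- array(0.5, c(33, 33, 3, 1))
  expect_error(lesionseg:::unet_forward(build_network(sp, 1), bad),
               "divisible by 2\\^5")
})

test_that("backpropagation matches finite-difference gradients", {
  sp <- tiny_spec()
  net <- build_network(sp, seed = 3)
  set.seed(9)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  y <- array(rbinom(32 * 32 * 2, 1, 0.3), c(32, 32, 1, 2))
  fw <- lesionseg:::unet_forward(net, x, training = TRUE)
  dz <- (fw$out - y) / length(fw$out)
  grads <- lesionseg:::unet_backward(fw$net, x, fw, dz)
  lossfn <- function(net2) {
    f <- lesionseg:::unet_forward(net2, x, training = TRUE)
    lesionseg:::bce_loss(f$out, y)
  }
  eps <- 1e-5
  ly <- sp$layers
  convs <- which(ly$kind == "conv"); bns <- which(ly$kind == "batch_norm")
  # conv weights in encoder, post-concat decoder, and head; batch-norm
  # scale/shift mid-network and at the head
  cases <- list(list(convs[2], "w", 7), list(convs[14], "w", 3),
                list(convs[26], "w", 2), list(bns[5], "gamma", 2),
                list(bns[5], "beta", 1), list(bns[26], "gamma", 1))
  for (cs in cases) {
    i <- cs[[1]]; nm <- cs[[2]]; j <- cs[[3]]
    n2 <- net
    n2$params[[i]][[nm]][j] <- n2$params[[i]][[nm]][j] + eps
    lp <- lossfn(n2)
    n2$params[[i]][[nm]][j] <- n2$params[[i]][[nm]][j] - 2 * eps
    lm <- lossfn(n2)
    num <- (lp - lm) / (2 * eps)
    ana <- grads[[i]][[nm]][j]
    expect_equal(ana, num, tolerance = 5e-3)
  }
})

test_that("convolution kernels match a direct dense computation", {
  # 3x3 same-padded conv on a small input, against an explicit loop
  set.seed(17)
  h <- 5L; w <- 4L; cin <- 2L; cout <- 3L
  x <- array(rnorm(h * w * cin), c(h, w, cin, 1))
  wt <- matrix(rnorm(9 * cin * cout), 9 * cin, cout)
  b <- rnorm(cout)
  got <- lesionseg:::cpp_conv_fwd(x, wt, b, 3L)
  warr <- array(wt, c(3, 3, cin, cout))
  want <- array(0, c(h, w, cout, 1))
  for (co in 1:cout) for (i in 1:h) for (j in 1:w) {
    acc <- b[co]
    for (ci in 1:cin) for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
        acc <- acc + x[ii, jj, ci, 1] * warr[di + 2, dj + 2, ci, co]
    }
    want[i, j, co, 1] <- acc
  }
  expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("pooling and upsampling kernels are exact inverses in shape", {
  set.seed(21)
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  mp <- lesionseg:::cpp_maxpool_fwd(x)
  expect_equal(dim(mp$y), c(4, 4, 2, 2))
  # every pooled value is the max of its 2x2 block
  for (n in 1:2) for (c in 1:2) for (i in 1:4) for (j in 1:4)
    expect_equal(mp$y[i, j, c, n],
                 max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, n]))
  up <- lesionseg:::cpp_upsample_fwd(mp$y)
  expect_equal(dim(up), c(8, 8, 2, 2))
  expect_equal(up[1, 1, 1, 1], mp$y[1, 1, 1, 1])
  expect_equal(up[2, 2, 1, 1], mp$y[1, 1, 1, 1])
  # upsample backward sums each 2x2 block
  g <- array(1, c(8, 8, 2, 2))
  expect_true(all(lesionseg:::cpp_upsample_bwd(g) == 4))
})

test_that("predict handles lists, batching, and stays deterministic", {
  sp <- modified_unet_spec(input_shape = c(64, 64, 3),
                          width_multiplier = 1 / 16)
  net <- build_network(sp, seed = 2)
  ds <- generate_dataset(5, small_synth_cfg(seed = 3))
  p_all <- predict(net, ds$pairs, batch_size = 2)
  expect_length(p_all, 5)
  expect_equal(dim(p_all[[1]]), c(64, 64))
  single <- predict(net, ds$pairs[[3]]$image)
  expect_equal(single, p_all[[3]], tolerance = 1e-12)
})
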