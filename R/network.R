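#' Build an executable network from an architecture description
#'
#' Instantiates seeded weights for every layer of a `unet_spec` and returns a
#' network object whose forward pass maps batches of `[0,1]` RGB images to
#' per-pixel lesion probabilities of the same spatial size. Convolution
#' weights use He-uniform initialization (`U(-sqrt(6/fan_in), sqrt(6/fan_in))`,
#' `fan_in = kernel^2 * in_channels`), biases start at zero, and batch
#' normalization starts at scale 1 / shift 0 with running mean 0 / variance 1.
#' Convolutions are computed linearly, then batch-normalized, then activated,
#' so the sigmoid head emits probabilities.
#'
#' The network's own parameter count ([network_param_count()]) is obtained by
#' measuring the stored arrays, independently of the declarative accountant
#' [count_model_params()]; the two are cross-checked in the test suite.
#'
#' @param spec A `unet_spec` (see [modified_unet_spec()]).
#' @param seed Integer seed fixing the weight initialization.
#' @return An object of class `unet_network`.
#' @examples
#' spec <- modified_unet_spec(input_shape = c(32, 32, 3), width_multiplier = 1 / 16)
#' net <- build_network(spec, seed = 1)
#' p <- predict(net, array(runif(32 * 32 * 3), c(32, 32, 3)))
#' range(p)
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  validate_unet_spec(spec)
  ly <- spec$layers
  L <- nrow(ly)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  params <- vector("list", L)
  for (i in seq_len(L)) {
    if (ly$kind[i] == "conv") {
      k <- ly$kernel[i]; cin <- ly$in_channels[i]; cout <- ly$out_channels[i]
      fan_in <- k * k * cin
      lim <- sqrt(6 / fan_in)
      w <- matrix(runif(fan_in * cout, -lim, lim), fan_in, cout)
      params[[i]] <- list(w = w, b = numeric(cout))
    } else if (ly$kind[i] == "batch_norm") {
      c <- ly$out_channels[i]
      params[[i]] <- list(gamma = rep(1, c), beta = numeric(c),
                          running_mean = numeric(c), running_var = rep(1, c))
    }
  }
  # activation placement: a conv immediately followed by its batch_norm layer
  # defers its activation until after normalization
  act_at <- rep("none", L)
  for (i in seq_len(L)) {
    if (ly$kind[i] != "conv" || ly$activation[i] == "none") next
    if (i < L && ly$kind[i + 1L] == "batch_norm") {
      act_at[i + 1L] <- ly$activation[i]
    } else {
      act_at[i] <- ly$activation[i]
    }
  }
  first_up <- match("upsample", ly$kind)
  encoder_layer <- seq_len(L) < (first_up %||% (L + 1L))
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 act_at = act_at, encoder_layer = encoder_layer,
                 bn_eps = 1e-5, bn_momentum = 0.9),
            class = "unet_network")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.unet_network <- function(x, ...) {
  pc <- network_param_count(x)
  cat("<unet_network> seed ", x$seed, ", ",
      format(pc$total, big.mark = ","), " parameters (",
      format(pc$trainable, big.mark = ","), " trainable)\n", sep = "")
  invisible(x)
}

#' Measured parameter count of a built network
#'
#' Counts the elements of the arrays actually stored in the network:
#' convolution weights and biases plus batch-norm scale/shift are trainable;
#' batch-norm running statistics are non-trainable. This is the executable
#' side of the dual counting paths (the declarative side is
#' [count_model_params()]).
#'
#' @param network A `unet_network`.
#' @return A list with `trainable`, `non_trainable` and `total`.
#' @export
network_param_count <- function(network) {
  stopifnot(inherits(network, "unet_network"))
  tr <- 0; ntr <- 0
  for (p in network$params) {
    if (is.null(p)) next
    if (!is.null(p$w)) tr <- tr + length(p$w) + length(p$b)
    if (!is.null(p$gamma)) {
      tr <- tr + length(p$gamma) + length(p$beta)
      ntr <- ntr + length(p$running_mean) + length(p$running_var)
    }
  }
  list(trainable = as.integer(tr), non_trainable = as.integer(ntr),
       total = as.integer(tr + ntr))
}

# ---- channel-wise helpers (arrays are (H, W, C, N)) ----

ch_sum_sq <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  s1 <- .colSums(m, nrow(m), ncol(m))
  s2 <- .colSums(m * m, nrow(m), ncol(m))
  list(sum = rowSums(matrix(s1, d[3], d[4])),
       sumsq = rowSums(matrix(s2, d[3], d[4])),
       m = d[1] * d[2] * d[4])
}

ch_sums2 <- function(a, b) {
  d <- dim(a)
  m1 <- matrix(a, d[1] * d[2], d[3] * d[4])
  m2 <- matrix(b, d[1] * d[2], d[3] * d[4])
  s1 <- .colSums(m1, nrow(m1), ncol(m1))
  s2 <- .colSums(m1 * m2, nrow(m1), ncol(m1))
  list(sum_a = rowSums(matrix(s1, d[3], d[4])),
       sum_ab = rowSums(matrix(s2, d[3], d[4])))
}

# broadcast a length-C vector over an (H, W, C, N) array
ch_vec <- function(x, v) {
  d <- dim(x)
  rep(v, each = d[1] * d[2])   # recycled across N by R arithmetic
}

apply_activation <- function(x, act) {
  switch(act,
    relu = { x[x < 0] <- 0; x },
    sigmoid = plogis(x),
    none = x,
    stop("unknown activation: '", act, "'", call. = FALSE))
}

# ---- forward ----

# Returns list(out, outs, caches). In training mode every layer output and
# the backward caches are retained; in eval mode only outputs still needed as
# skip sources are kept.
unet_forward <- function(net, x, training = FALSE) {
  ly <- net$spec$layers
  L <- nrow(ly)
  d <- dim(x)
  if (length(d) != 4)
    stop("expected a 4-d batch array (H, W, C, N)", call. = FALSE)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input height and width must be divisible by 2^5 = 32; got ",
         d[1], "x", d[2], call. = FALSE)
  if (d[1] != net$spec$input_shape[1] || d[2] != net$spec$input_shape[2] ||
      d[3] != net$spec$input_shape[3])
    stop("input shape ", d[1], "x", d[2], "x", d[3],
         " does not match the architecture input ",
         paste(net$spec$input_shape, collapse = "x"), call. = FALSE)
  skip_src <- ly$skip_from[!is.na(ly$skip_from)]
  outs <- vector("list", L)
  caches <- if (training) vector("list", L) else NULL
  cur <- x
  prev <- x
  drop_rate <- net$spec$dropout
  for (i in seq_len(L)) {
    kind <- ly$kind[i]
    cache <- NULL
    if (kind == "conv") {
      p <- net$params[[i]]
      cur <- cpp_conv_fwd(prev, p$w, p$b, ly$kernel[i])
      if (training) cache <- list(x = prev)
    } else if (kind == "batch_norm") {
      p <- net$params[[i]]
      if (training) {
        st <- ch_sum_sq(prev)
        mu <- st$sum / st$m
        va <- st$sumsq / st$m - mu^2
        va[va < 0] <- 0
        invstd <- 1 / sqrt(va + net$bn_eps)
        xhat <- (prev - ch_vec(prev, mu)) * ch_vec(prev, invstd)
        cur <- xhat * ch_vec(prev, p$gamma) + ch_vec(prev, p$beta)
        mom <- net$bn_momentum
        net$params[[i]]$running_mean <- mom * p$running_mean + (1 - mom) * mu
        net$params[[i]]$running_var <- mom * p$running_var + (1 - mom) * va
        cache <- list(xhat = xhat, invstd = invstd, m = st$m)
      } else {
        invstd <- 1 / sqrt(p$running_var + net$bn_eps)
        cur <- (prev - ch_vec(prev, p$running_mean)) *
          ch_vec(prev, invstd * p$gamma) + ch_vec(prev, p$beta)
      }
    } else if (kind == "max_pool") {
      mp <- cpp_maxpool_fwd(prev)
      cur <- mp$y
      if (training) cache <- list(idx = mp$idx, in_dim = dim(prev))
    } else if (kind == "upsample") {
      cur <- cpp_upsample_fwd(prev)
    } else if (kind == "concat_skip") {
      src <- outs[[ly$skip_from[i]]]
      if (is.null(src)) stop("skip source activation was not retained",
                             call. = FALSE)
      d1 <- dim(prev); d2 <- dim(src)
      cur <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
      cur[, , seq_len(d1[3]), ] <- prev
      cur[, , d1[3] + seq_len(d2[3]), ] <- src
      if (training) cache <- list(n_main = d1[3], n_skip = d2[3])
    } else {
      stop("unknown layer kind: '", kind, "'", call. = FALSE)
    }
    act <- net$act_at[i]
    if (act != "none") cur <- apply_activation(cur, act)
    if (training && drop_rate > 0 && net$encoder_layer[i] &&
        kind == "batch_norm") {
      mask <- array(runif(length(cur)) >= drop_rate, dim(cur)) / (1 - drop_rate)
      cur <- cur * mask
      cache$drop_mask <- mask
    }
    if (training || i %in% skip_src) outs[[i]] <- cur
    if (training) caches[[i]] <- cache
    prev <- cur
  }
  list(out = cur, outs = outs, caches = caches, net = net)
}

# ---- backward ----

# d_last is the loss gradient with respect to the PRE-activation of the final
# layer (the sigmoid head is folded into the cross-entropy gradient). Returns
# per-layer parameter gradients.
unet_backward <- function(net, x, fw, d_last) {
  ly <- net$spec$layers
  L <- nrow(ly)
  outs <- fw$outs
  caches <- fw$caches
  grads <- vector("list", L)
  gout <- vector("list", L)
  gout[[L]] <- d_last
  acc <- function(slot, g) {
    if (is.null(gout[[slot]])) gout[[slot]] <<- g else gout[[slot]] <<- gout[[slot]] + g
  }
  for (i in rev(seq_len(L))) {
    g <- gout[[i]]
    if (is.null(g)) stop("no gradient reached layer ", i, call. = FALSE)
    gout[[i]] <- NULL
    cache <- caches[[i]]
    if (!is.null(cache$drop_mask)) g <- g * cache$drop_mask
    act <- net$act_at[i]
    if (act != "none" && i < L) {
      y <- outs[[i]]
      if (act == "relu") g <- g * (y > 0)
      else if (act == "sigmoid") g <- g * y * (1 - y)
    }
    kind <- ly$kind[i]
    input <- if (i == 1L) x else outs[[i - 1L]]
    if (kind == "conv") {
      p <- net$params[[i]]
      bw <- cpp_conv_bwd(cache$x, p$w, g, ly$kernel[i])
      grads[[i]] <- list(w = bw$dw, b = bw$db)
      gprev <- bw$dx
    } else if (kind == "batch_norm") {
      p <- net$params[[i]]
      xhat <- cache$xhat
      s <- ch_sums2(g, xhat)
      grads[[i]] <- list(gamma = s$sum_ab, beta = s$sum_a)
      m <- cache$m
      coef <- p$gamma * cache$invstd / m
      gprev <- ch_vec(g, coef) *
        (m * g - ch_vec(g, s$sum_a) - xhat * ch_vec(g, s$sum_ab))
    } else if (kind == "max_pool") {
      gprev <- cpp_maxpool_bwd(cache$idx, g, cache$in_dim)
    } else if (kind == "upsample") {
      gprev <- cpp_upsample_bwd(g)
    } else if (kind == "concat_skip") {
      nm <- cache$n_main
      gprev <- g[, , seq_len(nm), , drop = FALSE]
      acc(ly$skip_from[i], g[, , nm + seq_len(cache$n_skip), , drop = FALSE])
    }
    if (i > 1L) acc(i - 1L, gprev)
  }
  grads
}

#' Predict lesion probability maps
#'
#' Runs the network in inference mode (batch normalization uses running
#' statistics). Accepts a single `H x W x 3` image, a list of images, or a
#' list of [sample_pair] objects.
#'
#' @param object A `unet_network`.
#' @param images A single image array, a list of image arrays, or a list of
#'   `sample_pair`s.
#' @param batch_size Images per forward pass.
#' @param ... Unused.
#' @return A single `H x W` probability matrix, or a list of them.
#' @export
predict.unet_network <- function(object, images, batch_size = 8L, ...) {
  single <- is.array(images) && length(dim(images)) == 3
  if (single) images <- list(images)
  images <- lapply(images, function(im) {
    if (inherits(im, "sample_pair")) im$image else im
  })
  n <- length(images)
  out <- vector("list", n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    x <- stack_images(images[idx])
    p <- unet_forward(object, x, training = FALSE)$out
    for (j in seq_along(idx)) out[[idx[j]]] <- p[, , 1L, j]
  }
  if (single) out[[1L]] else out
}

stack_images <- function(images) {
  d <- dim(images[[1L]])
  x <- array(0, c(d[1], d[2], d[3], length(images)))
  for (j in seq_along(images)) x[, , , j] <- images[[j]]
  x
}

stack_masks <- function(masks) {
  d <- dim(masks[[1L]])
  x <- array(0, c(d[1], d[2], 1L, length(masks)))
  for (j in seq_along(masks)) x[, , 1L, j] <- masks[[j]]
  x
}
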