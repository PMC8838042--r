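#' Training configuration
#'
#' Collects every knob of a training run. Learning rates default to the
#' conventional per-optimizer values (Adam 1e-3, SGD 1e-2, Adadelta 1.0) and
#' are recorded in every result row of a sweep.
#'
#' @param optimizer One of `"adam"`, `"sgd"`, `"adadelta"`.
#' @param learning_rate Step size; `NULL` picks the optimizer default.
#' @param batch_size Images per gradient step (>= 1).
#' @param epochs Full passes over the training split (>= 1).
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @param split `(train, test, validation)` fractions summing to 1.
#' @param threshold Binarization threshold for predicted probabilities.
#' @param width_multiplier Channel scale passed to [modified_unet_spec()].
#' @param augment_recipe Character vector of augmentation names applied to
#'   the training split only (see [expand_dataset()]); `character()` disables
#'   augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = c("adam", "sgd", "adadelta"),
                         learning_rate = NULL,
                         batch_size = 8L,
                         epochs = 10L,
                         seed = 1L,
                         split = c(0.70, 0.15, 0.15),
                         threshold = 0.5,
                         width_multiplier = 1,
                         augment_recipe = c("flip_h", "rot90")) {
  optimizer <- rlang::arg_match(optimizer)
  stopifnot(batch_size >= 1, epochs >= 1, threshold > 0, threshold < 1,
            length(split) == 3, abs(sum(split) - 1) < 1e-8,
            width_multiplier > 0)
  if (is.null(learning_rate))
    learning_rate <- switch(optimizer, adam = 1e-3, sgd = 1e-2, adadelta = 1.0)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 split = split, threshold = threshold,
                 width_multiplier = width_multiplier,
                 augment_recipe = augment_recipe),
            class = "train_config")
}

# ---- optimizers ----
# State and update rules operate on the flat list-of-arrays gradient
# structure produced by unet_backward().

opt_init <- function(optimizer) {
  list(name = optimizer, t = 0L, slots = list())
}

opt_step <- function(state, net, grads, lr) {
  state$t <- state$t + 1L
  for (i in seq_along(grads)) {
    gl <- grads[[i]]
    if (is.null(gl)) next
    for (nm in names(gl)) {
      key <- paste0(i, ".", nm)
      g <- gl[[nm]]
      p <- net$params[[i]][[nm]]
      if (state$name == "sgd") {
        p <- p - lr * g
      } else if (state$name == "adam") {
        s <- state$slots[[key]]
        if (is.null(s)) s <- list(m = g * 0, v = g * 0)
        s$m <- 0.9 * s$m + 0.1 * g
        s$v <- 0.999 * s$v + 0.001 * g * g
        mhat <- s$m / (1 - 0.9^state$t)
        vhat <- s$v / (1 - 0.999^state$t)
        p <- p - lr * mhat / (sqrt(vhat) + 1e-8)
        state$slots[[key]] <- s
      } else if (state$name == "adadelta") {
        s <- state$slots[[key]]
        if (is.null(s)) s <- list(eg = g * 0, ed = g * 0)
        rho <- 0.95; eps <- 1e-6
        s$eg <- rho * s$eg + (1 - rho) * g * g
        dx <- -sqrt(s$ed + eps) / sqrt(s$eg + eps) * g
        s$ed <- rho * s$ed + (1 - rho) * dx * dx
        p <- p + lr * dx
        state$slots[[key]] <- s
      }
      net$params[[i]][[nm]] <- p
    }
  }
  list(state = state, net = net)
}

# mean binary cross-entropy in nats, probabilities clipped for stability
bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a modified U-Net on image/mask pairs
#'
#' Minimizes per-pixel binary cross-entropy with the configured optimizer,
#' recording training loss and pixel accuracy per epoch. Batches are
#' reshuffled each epoch; initialization and shuffling are both fixed by
#' `config$seed`, so runs are reproducible. The returned model is the
#' final-epoch network (best-model selection across a sweep is done on
#' validation accuracy by [sweep_architectures()]).
#'
#' @param train_pairs,val_pairs Lists of [sample_pair] objects; `val_pairs`
#'   (optional) is evaluated once after training.
#' @param spec A `unet_spec`; its input shape must match the pairs.
#' @param config A [train_config()].
#' @param verbose Print one log line per epoch.
#' @return An object of class `unet_fit`: list with `network`, `history`
#'   (tibble `epoch`, `loss`, `accuracy`), `config`, `val_metrics` (a
#'   [evaluate_split()] row or `NULL`).
#' @export
train_unet <- function(train_pairs, val_pairs = NULL, spec, config,
                       verbose = FALSE) {
  stopifnot(inherits(spec, "unet_spec"), inherits(config, "train_config"))
  n <- length(train_pairs)
  if (n == 0) stop("empty training split", call. = FALSE)
  if (config$batch_size > n)
    stop("batch size (", config$batch_size,
         ") exceeds training-set size (", n, ")", call. = FALSE)
  net <- build_network(spec, seed = config$seed)
  state <- opt_init(config$optimizer)
  lr <- config$learning_rate
  imgs <- lapply(train_pairs, `[[`, "image")
  msks <- lapply(train_pairs, `[[`, "mask")
  history <- vector("list", config$epochs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_acc <- 0; ep_n <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(n, start + config$batch_size - 1L)]
      x <- stack_images(imgs[idx])
      y <- stack_masks(msks[idx])
      fw <- unet_forward(net, x, training = TRUE)
      net <- fw$net   # adopt updated batch-norm running statistics
      p <- fw$out
      loss <- bce_loss(p, y)
      acc <- mean((p >= config$threshold) == (y > 0.5))
      dz <- (p - y) / length(p)
      grads <- unet_backward(net, x, fw, dz)
      st <- opt_step(state, net, grads, lr)
      state <- st$state; net <- st$net
      w <- length(idx)
      ep_loss <- ep_loss + loss * w; ep_acc <- ep_acc + acc * w; ep_n <- ep_n + w
    }
    history[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss / ep_n,
                                    accuracy = ep_acc / ep_n)
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  accuracy %.4f",
                      ep, ep_loss / ep_n, ep_acc / ep_n))
  }
  fit <- structure(list(network = net,
                        history = dplyr::bind_rows(history),
                        config = config,
                        n_train = n,
                        val_metrics = NULL),
                   class = "unet_fit")
  if (!is.null(val_pairs) && length(val_pairs) > 0)
    fit$val_metrics <- evaluate_split(val_pairs, net,
                                      threshold = config$threshold)
  fit
}

#' @export
print.unet_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat("<unet_fit> ", x$config$optimizer, ", batch ", x$config$batch_size,
      ", ", x$config$epochs, " epochs; final training loss ",
      sprintf("%.4f", h$loss), ", accuracy ", sprintf("%.4f", h$accuracy),
      "\n", sep = "")
  invisible(x)
}

#' @rdname train_unet
#' @param x A `unet_fit`.
#' @export
tidy.unet_fit <- function(x, ...) x$history

#' @rdname train_unet
#' @export
glance.unet_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  pc <- network_param_count(x$network)
  tibble::tibble(optimizer = x$config$optimizer,
                 learning_rate = x$config$learning_rate,
                 batch_size = x$config$batch_size,
                 epochs = x$config$epochs,
                 seed = x$config$seed,
                 n_train = x$n_train,
                 trainable_params = pc$trainable,
                 final_loss = h$loss,
                 final_accuracy = h$accuracy)
}
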