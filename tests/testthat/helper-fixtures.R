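# Shared fixtures, built in code at test time.

# a tiny deterministic pair with a square lesion
square_pair <- function(h = 32L, w = 32L, id = "sq") {
  mask <- matrix(0, h, w)
  mask[(h / 4):(h / 2), (w / 4):(w / 2)] <- 1
  img <- array(0.7, c(h, w, 3))
  img[, , 1] <- img[, , 1] - 0.3 * mask
  img[, , 2] <- img[, , 2] - 0.35 * mask
  img[, , 3] <- img[, , 3] - 0.35 * mask
  sample_pair(img, mask, sample_id = id)
}

random_mask <- function(h = 16L, w = 16L, p = 0.5) {
  matrix(rbinom(h * w, 1, p), h, w)
}

# independent per-pixel confusion oracle: explicit loop, no vectorization
brute_confusion <- function(pred, truth) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
      else if (pred[i, j] == 1) fp <- fp + 1
      else if (truth[i, j] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

small_synth_cfg <- function(seed = 1L, ...) {
  synth_config(height = 64L, width = 64L, seed = seed, ...)
}

tiny_spec <- function() {
  modified_unet_spec(input_shape = c(32L, 32L, 3L), width_multiplier = 1 / 16)
}
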