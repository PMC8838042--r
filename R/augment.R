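#' Paired dermoscopy image and lesion mask
#'
#' The unit record of every pipeline stage: an `H x W x 3` image with values
#' in `[0, 1]`, its binary `H x W` lesion mask (1 = lesion, row-major, origin
#' top-left), an identifier, and a provenance tag recording which (if any)
#' augmentation produced it.
#'
#' @param image Numeric `H x W x 3` array in `[0, 1]`.
#' @param mask Numeric `H x W` matrix with values in `{0, 1}`.
#' @param sample_id Character identifier.
#' @param provenance One of `"original"`, `"flipped_h"`, `"flipped_v"`,
#'   `"rotated_k90"`, `"rotated_angle"`.
#' @return An object of class `sample_pair`.
#' @export
sample_pair <- function(image, mask, sample_id = "sample",
                        provenance = "original") {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3,
            is.matrix(mask))
  if (!all(dim(image)[1:2] == dim(mask)))
    stop("image and mask spatial sizes differ: ",
         paste(dim(image)[1:2], collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"), call. = FALSE)
  if (any(mask != 0 & mask != 1))
    stop("mask is not binary", call. = FALSE)
  provenance <- rlang::arg_match(provenance,
    c("original", "flipped_h", "flipped_v", "rotated_k90", "rotated_angle"))
  structure(list(image = image, mask = mask, sample_id = sample_id,
                 provenance = provenance),
            class = "sample_pair")
}

#' @export
print.sample_pair <- function(x, ...) {
  cat("<sample_pair> ", x$sample_id, " (", x$provenance, "), ",
      dim(x$mask)[1], "x", dim(x$mask)[2], ", lesion fraction ",
      sprintf("%.3f", mean(x$mask)), "\n", sep = "")
  invisible(x)
}

flip_matrix <- function(m, axis) {
  if (axis == "horizontal") m[, ncol(m):1, drop = FALSE]
  else m[nrow(m):1, , drop = FALSE]
}

rot90_matrix <- function(m, k) {
  for (i in seq_len(k %% 4L)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

apply_channels <- function(image, f) {
  chs <- lapply(seq_len(dim(image)[3]), function(c) f(image[, , c]))
  array(unlist(chs), c(dim(chs[[1]]), length(chs)))
}

#' Flip an image/mask pair
#'
#' Mirrors image and mask identically: `"horizontal"` reverses columns
#' (mirror across the vertical axis), `"vertical"` reverses rows. Flipping is
#' a pixel permutation, so the mask stays binary and its lesion pixel count
#' is preserved; applying the same flip twice restores the original.
#'
#' @param pair A [sample_pair].
#' @param axis `"horizontal"` or `"vertical"`.
#' @return A flipped `sample_pair` with provenance `flipped_h` / `flipped_v`.
#' @export
flip_pair <- function(pair, axis = c("horizontal", "vertical")) {
  axis <- rlang::arg_match(axis)
  sample_pair(apply_channels(pair$image, function(m) flip_matrix(m, axis)),
              flip_matrix(pair$mask, axis),
              sample_id = paste0(pair$sample_id, "_f",
                                 substr(axis, 1, 1)),
              provenance = if (axis == "horizontal") "flipped_h" else "flipped_v")
}

#' Rotate an image/mask pair by a multiple of 90 degrees
#'
#' Rotates image and mask identically and exactly (pure index permutation, no
#' interpolation, so the mask stays binary). Odd `k` swaps height and width.
#'
#' @param pair A [sample_pair].
#' @param k Number of counter-clockwise quarter turns, in `{1, 2, 3}`.
#' @return A rotated `sample_pair` with provenance `rotated_k90`.
#' @export
rotate90_pair <- function(pair, k = 1L) {
  if (!k %in% 1:3)
    stop("k must be 1, 2 or 3 quarter turns; got ", k, call. = FALSE)
  sample_pair(apply_channels(pair$image, function(m) rot90_matrix(m, k)),
              rot90_matrix(pair$mask, k),
              sample_id = paste0(pair$sample_id, "_r", 90L * k),
              provenance = "rotated_k90")
}

#' Rotate an image/mask pair by an arbitrary angle
#'
#' Rotates about the frame centre keeping the frame size: the image is
#' resampled bilinearly, the mask with nearest neighbour so it stays strictly
#' binary. Pixels rotated in from outside the frame are filled with 0 in the
#' mask and with the image's median border intensity. Unlike the exact
#' 90-degree rotations, arbitrary angles resample the lesion boundary and do
#' not conserve the foreground pixel count exactly.
#'
#' @param pair A [sample_pair].
#' @param angle Rotation angle in degrees (counter-clockwise).
#' @return A rotated `sample_pair` with provenance `rotated_angle`.
#' @export
rotate_pair <- function(pair, angle) {
  h <- nrow(pair$mask); w <- ncol(pair$mask)
  th <- angle * pi / 180
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  # inverse map: for each output pixel, source coordinates in the input
  rg <- matrix(seq_len(h), h, w)
  cg <- matrix(seq_len(w), h, w, byrow = TRUE)
  dr <- rg - cr; dc <- cg - cc
  src_r <- cos(th) * dr - sin(th) * dc + cr
  src_c <- sin(th) * dr + cos(th) * dc + cc
  inb <- src_r >= 1 & src_r <= h & src_c >= 1 & src_c <= w
  nn_r <- pmin(pmax(round(src_r), 1L), h)
  nn_c <- pmin(pmax(round(src_c), 1L), w)
  nn_idx <- cbind(as.vector(nn_r), as.vector(nn_c))
  mask <- matrix(0, h, w)
  mask[as.vector(inb)] <- pair$mask[nn_idx[as.vector(inb), , drop = FALSE]]
  r0 <- pmin(pmax(floor(src_r), 1L), h); r1 <- pmin(r0 + 1L, h)
  c0 <- pmin(pmax(floor(src_c), 1L), w); c1 <- pmin(c0 + 1L, w)
  fr <- src_r - r0; fc <- src_c - c0
  border_fill <- stats::median(pair$image[c(1, h), , ])
  bilinear <- function(m) {
    v <- (1 - fr) * (1 - fc) * m[cbind(as.vector(r0), as.vector(c0))] +
      (1 - fr) * fc * m[cbind(as.vector(r0), as.vector(c1))] +
      fr * (1 - fc) * m[cbind(as.vector(r1), as.vector(c0))] +
      fr * fc * m[cbind(as.vector(r1), as.vector(c1))]
    out <- matrix(v, h, w)
    out[!inb] <- border_fill
    out
  }
  sample_pair(apply_channels(pair$image, bilinear), mask,
              sample_id = paste0(pair$sample_id, "_ra"),
              provenance = "rotated_angle")
}

augmentation_fns <- function() {
  list(
    flip_h = function(p, rng) flip_pair(p, "horizontal"),
    flip_v = function(p, rng) flip_pair(p, "vertical"),
    rot90 = function(p, rng) rotate90_pair(p, 1L),
    rot180 = function(p, rng) rotate90_pair(p, 2L),
    rot270 = function(p, rng) rotate90_pair(p, 3L),
    rot_angle = function(p, rng) rotate_pair(p, rng))
}

#' Expand a dataset by offline augmentation
#'
#' Applies each named augmentation to every input pair and returns the
#' originals plus all augmented copies, so the output size is
#' `length(pairs) * (1 + length(recipe))`. Recognized names: `flip_h`,
#' `flip_v`, `rot90`, `rot180`, `rot270`, and `rot_angle` (a random angle in
#' (-45, 45) degrees, drawn per pair from `seed`). Deterministic under a
#' fixed seed; provenance is recorded on every output pair.
#'
#' @param pairs Non-empty list of [sample_pair] objects.
#' @param recipe Non-empty character vector of augmentation names. The
#'   default `c("flip_h", "rot90")` triples the dataset with mask-exact
#'   transforms only.
#' @param seed Integer seed (used by `rot_angle`).
#' @return A list of `sample_pair`s, originals first.
#' @export
expand_dataset <- function(pairs, recipe = c("flip_h", "rot90"), seed = 1L) {
  if (length(pairs) == 0) stop("empty pair list", call. = FALSE)
  if (length(recipe) == 0) stop("empty augmentation recipe", call. = FALSE)
  fns <- augmentation_fns()
  unknown <- setdiff(recipe, names(fns))
  if (length(unknown) > 0)
    stop("unknown augmentation name: '", unknown[1], "'", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  angles <- matrix(runif(length(pairs) * length(recipe), -45, 45),
                   length(pairs), length(recipe))
  out <- pairs
  for (j in seq_along(recipe)) {
    f <- fns[[recipe[j]]]
    out <- c(out, lapply(seq_along(pairs),
                         function(i) f(pairs[[i]], angles[i, j])))
  }
  out
}
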