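#' Configuration of the synthetic dermoscopy generator
#'
#' The generator emulates the statistics of a dermoscopic lesion dataset:
#' skin-toned frames of a fixed size carrying exactly one irregular, darker
#' lesion region with an exact binary ground-truth mask, optional dark hair
#' strokes and an optional corner vignette. It exists so every stage of the
#' segmentation pipeline is testable end-to-end with no external download.
#'
#' @param height,width Frame size in pixels (defaults 192 x 256); both must
#'   be divisible by 2^5 = 32, the network's pooling requirement.
#' @param lesion_area_fraction Length-2 range in (0, 1) for the lesion's area
#'   as a fraction of the frame (default 0.05-0.35).
#' @param boundary_irregularity Non-negative scalar scaling the radial
#'   harmonic perturbation of the lesion boundary; 0 gives an exact ellipse.
#' @param hair_count Length-2 integer range for the number of simulated hair
#'   strokes per frame.
#' @param vignette Add a radial corner darkening, as dermatoscope optics do.
#' @param melanoma_fraction Fraction of samples labelled `melanoma` in the
#'   manifest (labels are bookkeeping only; appearance is not conditioned on
#'   them).
#' @param seed Integer seed for [generate_dataset()].
#' @return A `synth_config` list.
#' @export
synth_config <- function(height = 192L, width = 256L,
                         lesion_area_fraction = c(0.05, 0.35),
                         boundary_irregularity = 0.25,
                         hair_count = c(0L, 4L),
                         vignette = TRUE,
                         melanoma_fraction = 0.2,
                         seed = 1L) {
  stopifnot(height %% 32L == 0L, width %% 32L == 0L,
            length(lesion_area_fraction) == 2,
            lesion_area_fraction[1] > 0, lesion_area_fraction[2] < 1,
            lesion_area_fraction[1] <= lesion_area_fraction[2],
            boundary_irregularity >= 0,
            length(hair_count) == 2, hair_count[1] >= 0,
            hair_count[1] <= hair_count[2],
            melanoma_fraction >= 0, melanoma_fraction <= 1)
  structure(list(height = as.integer(height), width = as.integer(width),
                 lesion_area_fraction = lesion_area_fraction,
                 boundary_irregularity = boundary_irregularity,
                 hair_count = as.integer(hair_count),
                 vignette = vignette,
                 melanoma_fraction = melanoma_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate one synthetic lesion mask
#'
#' Draws a single connected, star-convex lesion region: in polar coordinates
#' about a random centre the boundary radius is
#' `r(theta) = r0 * (1 + sum_j a_j sin(j theta + phi_j))` on an elliptical
#' base, with harmonic amplitudes `a_j` scaled by
#' `cfg$boundary_irregularity` (0 gives an exact ellipse). Radii are rescaled
#' until the measured area fraction falls inside
#' `cfg$lesion_area_fraction`, and the region is kept fully inside the frame.
#' Consumes the current R random stream; seed the session (or use
#' [generate_dataset()]) for reproducibility.
#'
#' @param cfg A [synth_config()].
#' @return An `height x width` binary matrix (1 = lesion) with a `geometry`
#'   attribute recording the drawn centre, elliptical radii, harmonic
#'   amplitudes and phases.
#' @export
generate_mask <- function(cfg) {
  h <- cfg$height; w <- cfg$width
  rng <- cfg$lesion_area_fraction
  a_target <- runif(1, rng[1], rng[2])
  q <- runif(1, 0.75, 1.3)
  jh <- 2:6
  aj <- cfg$boundary_irregularity * runif(5, 0.2, 1) / jh
  if (sum(aj) > 0.85) aj <- aj * 0.85 / sum(aj)
  phij <- runif(5, 0, 2 * pi)
  smax <- sum(aj)
  r0 <- sqrt(a_target * h * w / pi)
  ry <- r0 / sqrt(q); rx <- r0 * sqrt(q)
  # shrink to fit the frame with a 2 px margin
  fit <- min((h / 2 - 2) / (ry * (1 + smax)), (w / 2 - 2) / (rx * (1 + smax)), 1)
  ry <- ry * fit; rx <- rx * fit
  if (pi * rx * ry * (1 + sum(aj^2) / 2) < rng[1] * h * w * 0.98)
    stop("infeasible lesion area range for a ", h, "x", w, " frame",
         call. = FALSE)
  rg <- matrix(seq_len(h), h, w)
  cg <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (attempt in 1:6) {
    my <- ry * (1 + smax) + 2; mx <- rx * (1 + smax) + 2
    cr <- runif(1, my, h - my); cc <- runif(1, mx, w - mx)
    u <- (rg - cr) / ry; v <- (cg - cc) / rx
    e <- sqrt(u^2 + v^2)
    th <- atan2(u, v)
    s <- matrix(0, h, w)
    for (j in seq_along(jh)) s <- s + aj[j] * sin(jh[j] * th + phij[j])
    mask <- 1 * (e <= 1 + s)
    frac <- mean(mask)
    if (frac >= rng[1] && frac <= rng[2]) {
      attr(mask, "geometry") <- list(center = c(cr, cc), radii = c(ry, rx),
                                     amplitudes = aj, phases = phij)
      return(mask)
    }
    scale <- sqrt(a_target / max(frac, 1e-6))
    fit <- min((h / 2 - 2) / (ry * scale * (1 + smax)),
               (w / 2 - 2) / (rx * scale * (1 + smax)), scale)
    ry <- ry * fit; rx <- rx * fit
  }
  stop("could not place a lesion with area fraction in [",
       rng[1], ", ", rng[2], "] inside a ", h, "x", w, " frame",
       call. = FALSE)
}

low_freq_field <- function(h, w, n_waves = 3, amp = 0.04) {
  rg <- matrix(seq_len(h) / h, h, w)
  cg <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
  f <- matrix(0, h, w)
  for (i in seq_len(n_waves)) {
    fr <- runif(1, 0.5, 2.5); fc <- runif(1, 0.5, 2.5)
    ph <- runif(1, 0, 2 * pi)
    f <- f + cos(2 * pi * (fr * rg + fc * cg) + ph)
  }
  1 + amp * f / n_waves
}

draw_hairs <- function(h, w, n) {
  hm <- matrix(0, h, w)
  if (n == 0) return(hm)
  for (i in seq_len(n)) {
    side <- sample(1:4, 2)
    pt <- function(s) switch(s,
      c(1, runif(1, 1, w)), c(h, runif(1, 1, w)),
      c(runif(1, 1, h), 1), c(runif(1, 1, h), w))
    p0 <- pt(side[1]); p2 <- pt(side[2])
    p1 <- c(runif(1, h * 0.2, h * 0.8), runif(1, w * 0.2, w * 0.8))
    t <- seq(0, 1, length.out = 2L * (h + w))
    r <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1]
    c_ <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
    ri <- round(r); ci <- round(c_)
    keep <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    hm[cbind(ri[keep], ci[keep])] <- 1
  }
  hm
}

#' Render a dermoscopy-like image over a lesion mask
#'
#' Composites a skin-toned background carrying a low-frequency multiplicative
#' texture with a darker, brown-shifted lesion whose edge is smoothed by a
#' Gaussian transition, then optionally overlays dark hair strokes (random
#' quadratic curves crossing the frame) and a corner vignette. Construction
#' guarantees the mean intensity inside the mask is below the mean outside,
#' and all values are clipped to `[0, 1]`. Consumes the current R random
#' stream.
#'
#' @param mask Binary lesion mask from [generate_mask()].
#' @param cfg A [synth_config()].
#' @return An `H x W x 3` image array in `[0, 1]`.
#' @export
render_image <- function(mask, cfg) {
  h <- nrow(mask); w <- ncol(mask)
  base <- c(0.82, 0.61, 0.55) * (1 + runif(1, -0.06, 0.06)) +
    runif(3, -0.03, 0.03)
  lesion_mul <- runif(1, 0.38, 0.55) * c(1, 0.82, 0.72)
  tex_bg <- low_freq_field(h, w, amp = 0.04)
  tex_le <- low_freq_field(h, w, amp = 0.07)
  sigma <- max(1, min(h, w) / 64)
  alpha <- EBImage::gblur(mask, sigma = sigma)
  alpha <- pmin(pmax(alpha, 0), 1)
  nh <- sample(seq(cfg$hair_count[1], cfg$hair_count[2]), 1)
  hair_alpha <- if (nh > 0) {
    pmin(EBImage::gblur(draw_hairs(h, w, nh), sigma = 0.7) * 1.4, 1) * 0.75
  } else matrix(0, h, w)
  hair_col <- runif(1, 0.10, 0.20)
  vg <- if (cfg$vignette) {
    rg <- matrix(seq_len(h), h, w); cg <- matrix(seq_len(w), h, w, byrow = TRUE)
    d2 <- ((rg - (h + 1) / 2) / (h / 2))^2 + ((cg - (w + 1) / 2) / (w / 2))^2
    1 - 0.22 * d2 / 2
  } else matrix(1, h, w)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    bg <- base[ch] * tex_bg
    le <- base[ch] * lesion_mul[ch] * tex_le
    plane <- bg * (1 - alpha) + le * alpha
    plane <- plane * (1 - hair_alpha) + hair_col * hair_alpha
    img[, , ch] <- pmin(pmax(plane * vg, 0), 1)
  }
  attr(img, "hair_count") <- nh
  img
}

#' Generate a reproducible synthetic dermoscopy dataset
#'
#' Draws `n` image/mask pairs under `cfg`, recording one manifest row per
#' sample (identifier, per-sample seed, measured lesion area fraction, hair
#' count, diagnostic class label). With `dir` set, pairs are also written to
#' disk in the per-case folder layout `<dir>/<id>/<id>_Dermoscopic_Image/
#' <id>.png` + `<dir>/<id>/<id>_lesion/<id>_lesion.png`, with the manifest at
#' `<dir>/manifest.csv` — the same layout [scan_lesion_layout()] reads.
#' Identical `cfg$seed` reproduces the dataset and manifest exactly.
#'
#' @param n Number of samples (>= 1).
#' @param cfg A [synth_config()].
#' @param dir Optional output directory.
#' @return A list with `pairs` (list of [sample_pair]) and `manifest`
#'   (tibble).
#' @examples
#' ds <- generate_dataset(2, synth_config(height = 64, width = 64, seed = 7))
#' ds$manifest
#' @export
generate_dataset <- function(n, cfg = synth_config(), dir = NULL) {
  stopifnot(n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  n_mel <- round(cfg$melanoma_fraction * n)
  labels <- rep("non-melanoma", n)
  if (n_mel > 0) labels[sample.int(n, n_mel)] <- "melanoma"
  pairs <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    mask <- generate_mask(cfg)
    img <- render_image(mask, cfg)
    id <- sprintf("IMD%03d", i)
    pairs[[i]] <- sample_pair(array(as.numeric(img), dim(img)),
                              matrix(as.numeric(mask), nrow(mask)),
                              sample_id = id)
    rows[[i]] <- tibble::tibble(
      sample_id = id, seed = sub_seeds[i],
      height = cfg$height, width = cfg$width,
      area_fraction = mean(mask),
      hair_count = attr(img, "hair_count"),
      class_label = labels[i], provenance = "original")
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    paths <- write_pair_layout(pairs, dir)
    manifest$image_path <- paths$image_path
    manifest$mask_path <- paths$mask_path
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  }
  list(pairs = pairs, manifest = manifest)
}
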