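#' Read a paired image and mask from disk
#'
#' Reads PNG or BMP (chosen by extension), scales the image to `[0, 1]`,
#' replicates grayscale images to 3 channels, binarizes the mask at half its
#' value range, and optionally resizes to an exact target (image bilinearly,
#' mask nearest-neighbour so it stays binary) — the route by which
#' approximately-sized source frames are normalized to the network's
#' 32-divisible geometry.
#'
#' @param image_path,mask_path Paths to PNG or BMP files.
#' @param target_size Optional `(height, width)` to resize to.
#' @return A [sample_pair].
#' @export
read_pair <- function(image_path, mask_path, target_size = NULL) {
  img <- read_image_file(image_path)
  msk <- read_image_file(mask_path)
  if (length(dim(msk)) == 3) msk <- msk[, , 1]
  rng <- range(msk)
  thr <- if (rng[2] > rng[1]) mean(rng) else 0.5
  msk <- 1 * (msk >= thr)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (!is.null(target_size)) {
    img <- resize_image(img, target_size[1], target_size[2], bilinear = TRUE)
    msk <- resize_image(msk, target_size[1], target_size[2], bilinear = FALSE)
  }
  if (!all(dim(img)[1:2] == dim(msk)))
    stop("image and mask sizes differ after reading: ",
         paste(dim(img)[1:2], collapse = "x"), " vs ",
         paste(dim(msk), collapse = "x"), call. = FALSE)
  sample_pair(img, msk,
              sample_id = sub("\\.[^.]+$", "", basename(image_path)))
}

#' Write a paired image and mask as PNG
#'
#' Deterministic output: pixel content only, no timestamps.
#'
#' @param pair A [sample_pair].
#' @param image_path,mask_path Output PNG paths.
#' @return A list of the two paths, invisibly.
#' @export
write_pair <- function(pair, image_path, mask_path) {
  png::writePNG(pair$image, image_path)
  png::writePNG(pair$mask, mask_path)
  invisible(list(image_path = image_path, mask_path = mask_path))
}

# write pairs in the per-case folder layout; returns path tibble
write_pair_layout <- function(pairs, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(pairs, function(p) {
    id <- p$sample_id
    d_img <- file.path(root, id, paste0(id, "_Dermoscopic_Image"))
    d_msk <- file.path(root, id, paste0(id, "_lesion"))
    dir.create(d_img, recursive = TRUE, showWarnings = FALSE)
    dir.create(d_msk, recursive = TRUE, showWarnings = FALSE)
    ip <- file.path(d_img, paste0(id, ".png"))
    mp <- file.path(d_msk, paste0(id, "_lesion.png"))
    write_pair(p, ip, mp)
    tibble::tibble(sample_id = id, image_path = ip, mask_path = mp)
  })
  dplyr::bind_rows(rows)
}

read_image_file <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") png::readPNG(path)
  else if (ext == "bmp") read_bmp(path)
  else stop("unsupported image format '.", ext, "' for ", path, call. = FALSE)
}

resize_image <- function(x, h, w, bilinear = TRUE) {
  f <- if (bilinear) "bilinear" else "none"
  if (length(dim(x)) == 2) {
    matrix(as.numeric(EBImage::resize(x, w = h, h = w, filter = f)), h, w)
  } else {
    chs <- lapply(seq_len(dim(x)[3]), function(c)
      matrix(as.numeric(EBImage::resize(x[, , c], w = h, h = w, filter = f)),
             h, w))
    array(unlist(chs), c(h, w, length(chs)))
  }
}

# ---- minimal BMP support (uncompressed BI_RGB; the source format of
# dermoscopy archives). No installed R package reads BMP, so 24-bit and
# 8-bit-palette reading plus 24-bit writing are implemented directly. ----

#' Read / write uncompressed BMP images
#'
#' `read_bmp()` handles uncompressed (BI_RGB) 24-bit and 8-bit palette
#' files, returning an `H x W x 3` (or `H x W` for grayscale palettes) array
#' in `[0, 1]`; `write_bmp()` writes 24-bit BI_RGB.
#'
#' @param path File path.
#' @param x For `write_bmp()`: an `H x W x 3` array or `H x W` matrix in
#'   `[0, 1]`.
#' @return `read_bmp()` returns the image array; `write_bmp()` returns
#'   `path` invisibly.
#' @export
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(as.integer(magic), c(66L, 77L)))
    stop("not a BMP file: ", path, call. = FALSE)
  readBin(con, "integer", 2, size = 4)            # file size, reserved
  offset <- readBin(con, "integer", 1, size = 4)
  hdr_size <- readBin(con, "integer", 1, size = 4)
  w <- readBin(con, "integer", 1, size = 4)
  h <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 2)            # planes
  bpp <- readBin(con, "integer", 1, size = 2)
  compression <- readBin(con, "integer", 1, size = 4)
  if (compression != 0)
    stop("only uncompressed BI_RGB BMP is supported: ", path, call. = FALSE)
  if (!bpp %in% c(8L, 24L))
    stop("only 8-bit and 24-bit BMP are supported (got ", bpp, "-bit): ",
         path, call. = FALSE)
  readBin(con, "integer", 5, size = 4)            # rest of info header
  palette <- NULL
  if (bpp == 8L) {
    n_col <- (offset - 14L - hdr_size) / 4L
    pal_raw <- readBin(con, "raw", n_col * 4L)
    pal <- matrix(as.integer(pal_raw), 4L, n_col)  # B, G, R, reserved
    palette <- t(pal[3:1, , drop = FALSE]) / 255   # n x RGB
  }
  seek(con, offset)
  bottom_up <- h > 0
  h <- abs(h)
  bytes_pp <- bpp / 8L
  stride <- ((w * bytes_pp + 3L) %/% 4L) * 4L
  data <- readBin(con, "raw", stride * h)
  rows_idx <- if (bottom_up) h:1 else 1:h
  if (bpp == 24L) {
    out <- array(0, c(h, w, 3))
    for (r in seq_len(h)) {
      line <- as.integer(data[((r - 1L) * stride + 1L):((r - 1L) * stride + w * 3L)])
      m <- matrix(line, 3L, w)                     # B, G, R per pixel
      out[rows_idx[r], , ] <- t(m[3:1, , drop = FALSE]) / 255
    }
    out
  } else {
    idx <- matrix(0L, h, w)
    for (r in seq_len(h)) {
      line <- as.integer(data[((r - 1L) * stride + 1L):((r - 1L) * stride + w)])
      idx[rows_idx[r], ] <- line + 1L
    }
    cols <- palette[as.vector(idx), , drop = FALSE]
    if (all(cols[, 1] == cols[, 2] & cols[, 2] == cols[, 3]))
      matrix(cols[, 1], h, w)
    else array(cols, c(h, w, 3))
  }
}

#' @rdname read_bmp
#' @export
write_bmp <- function(x, path) {
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  h <- dim(x)[1]; w <- dim(x)[2]
  stride <- ((w * 3L + 3L) %/% 4L) * 4L
  img_bytes <- stride * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(66L, 77L)), con)
  writeBin(as.integer(14L + 40L + img_bytes), con, size = 4)
  writeBin(0L, con, size = 4)
  writeBin(54L, con, size = 4)
  writeBin(40L, con, size = 4)
  writeBin(as.integer(w), con, size = 4)
  writeBin(as.integer(h), con, size = 4)          # bottom-up
  writeBin(1L, con, size = 2)
  writeBin(24L, con, size = 2)
  writeBin(0L, con, size = 4)
  writeBin(as.integer(img_bytes), con, size = 4)
  writeBin(c(2835L, 2835L, 0L, 0L), con, size = 4)
  q <- function(v) as.integer(pmin(pmax(round(v * 255), 0), 255))
  pad <- as.raw(rep(0L, stride - w * 3L))
  for (r in h:1) {
    line <- rbind(q(x[r, , 3]), q(x[r, , 2]), q(x[r, , 1]))
    writeBin(c(as.raw(line), pad), con)
  }
  invisible(path)
}

#' Scan a per-case dermoscopy folder layout into a manifest
#'
#' Walks a root directory whose immediate subdirectories are cases, pairing
#' each case's dermoscopic image (`<id>_Dermoscopic_Image/`) with its lesion
#' mask (`<id>_lesion/`) — the layout of the public PH2 archive and of
#' [generate_dataset()]'s on-disk output. Cases lacking either file are
#' collected in a `skipped` attribute rather than failing the scan.
#'
#' @param root Directory to scan.
#' @return A tibble with `sample_id`, `image_path`, `mask_path`,
#'   `class_label` (`NA` unless a manifest.csv provides it), `provenance`;
#'   attribute `skipped` lists incomplete cases. An empty root returns an
#'   empty manifest with a warning.
#' @export
scan_lesion_layout <- function(root) {
  if (!dir.exists(root)) stop("root does not exist: ", root, call. = FALSE)
  cases <- list.dirs(root, recursive = FALSE)
  rows <- list(); skipped <- character()
  for (cs in cases) {
    id <- basename(cs)
    imgs <- list.files(file.path(cs, paste0(id, "_Dermoscopic_Image")),
                       pattern = "\\.(png|bmp)$", ignore.case = TRUE,
                       full.names = TRUE)
    msks <- list.files(file.path(cs, paste0(id, "_lesion")),
                       pattern = "\\.(png|bmp)$", ignore.case = TRUE,
                       full.names = TRUE)
    if (length(imgs) < 1 || length(msks) < 1) {
      skipped <- c(skipped, id)
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = id, image_path = imgs[1], mask_path = msks[1],
      class_label = NA_character_, provenance = "original")
  }
  if (length(rows) == 0) {
    warning("no complete cases found under ", root, call. = FALSE)
    manifest <- tibble::tibble(sample_id = character(),
                               image_path = character(),
                               mask_path = character(),
                               class_label = character(),
                               provenance = character())
  } else {
    manifest <- dplyr::bind_rows(rows)
    mpath <- file.path(root, "manifest.csv")
    if (file.exists(mpath)) {
      meta <- readr::read_csv(mpath, show_col_types = FALSE)
      if ("class_label" %in% names(meta))
        manifest$class_label <-
          meta$class_label[match(manifest$sample_id, meta$sample_id)]
    }
  }
  attr(manifest, "skipped") <- skipped
  manifest
}

#' Load every pair of a manifest
#'
#' @param manifest A manifest tibble from [scan_lesion_layout()].
#' @param target_size Optional `(height, width)` passed to [read_pair()].
#' @return A list of [sample_pair]s.
#' @export
read_manifest_pairs <- function(manifest, target_size = NULL) {
  lapply(seq_len(nrow(manifest)), function(i)
    read_pair(manifest$image_path[i], manifest$mask_path[i],
              target_size = target_size))
}
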