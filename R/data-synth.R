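# Patch extraction and stitching for large tissue images, the 0/255 binary
# mask PNG convention, dihedral + colour-jitter augmentation, and a seeded
# synthetic generator producing H&E-like textured patches with blob-shaped
# lesions so the whole pipeline is testable without any dataset download.

#' Patch record
#'
#' A single training/evaluation unit: an RGB patch, its binary mask, the
#' image-level lesion label (1 iff the mask has any foreground pixel) and the
#' 0-based (row, col) origin of the patch in its source image.
#'
#' @param image numeric (H, W, 3) array with values in `[0, 1]` (8-bit scale).
#' @param mask binary (H, W) matrix.
#' @param origin integer (row, col) of the top-left pixel, 0-based.
#' @return a `patch_record` list with fields `image`, `mask`, `label`,
#'   `origin`.
#' @export
patch_record <- function(image, mask, origin = c(0L, 0L)) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
  if (!identical(dim(image)[1:2], dim(mask))) {
    stop("image and mask shapes disagree: ",
         paste(dim(image)[1:2], collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"))
  }
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  r <- list(image = image, mask = mask,
            label = as.integer(any(mask > 0)),
            origin = as.integer(origin))
  class(r) <- "patch_record"
  r
}

#' Dense cropping of a large image into fixed-size patches
#'
#' Slides a `patch_size` window at the given stride over the image; a final
#' row/column of patches anchored at the image edge guarantees that every
#' source pixel is covered (no padding, no dropped margins).
#'
#' @param image (H, W, 3) array (or (H, W) matrix, promoted to gray RGB).
#' @param mask optional binary (H, W) mask, cropped identically.
#' @param patch_size patch side length.
#' @param stride crop stride (<= patch_size for full coverage).
#' @return list of [patch_record()]s with recorded origins.
#' @export
dense_crop <- function(image, mask = NULL, patch_size = 512L,
                       stride = 512L) {
  if (length(dim(image)) == 2L) {
    image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  }
  H <- dim(image)[1L]; W <- dim(image)[2L]
  if (H < patch_size || W < patch_size) {
    stop("image (", H, "x", W, ") is smaller than patch_size ", patch_size)
  }
  starts <- function(n) {
    s <- seq.int(0L, n - patch_size, by = stride)
    if (s[length(s)] != n - patch_size) s <- c(s, n - patch_size)
    s
  }
  out <- list()
  for (r0 in starts(H)) {
    for (c0 in starts(W)) {
      ri <- (r0 + 1L):(r0 + patch_size)
      ci <- (c0 + 1L):(c0 + patch_size)
      m <- if (is.null(mask)) {
        matrix(0L, patch_size, patch_size)
      } else {
        mask[ri, ci, drop = FALSE]
      }
      out[[length(out) + 1L]] <- patch_record(
        image[ri, ci, , drop = FALSE], m, origin = c(r0, c0))
    }
  }
  out
}

#' Stitch patch predictions back to full resolution
#'
#' Inverse of [dense_crop()] for whole-image prediction.  Overlapping pixels
#' are resolved by logical OR of the binary patch masks (`rule = "or"`,
#' recall-preserving) or by averaging (`rule = "mean"`, for probability
#' maps).  Every pixel of `full_shape` must be covered by at least one patch.
#'
#' @param patches list of [patch_record()]s (their `mask` fields are
#'   stitched).
#' @param full_shape integer (H, W) of the source image.
#' @param rule overlap resolution rule.
#' @return (H, W) matrix: binary for `"or"`, averaged values for `"mean"`.
#' @export
stitch <- function(patches, full_shape, rule = c("or", "mean")) {
  rule <- match.arg(rule)
  H <- full_shape[1L]; W <- full_shape[2L]
  acc <- matrix(0, H, W)
  cnt <- matrix(0L, H, W)
  for (p in patches) {
    ph <- dim(p$mask)[1L]; pw <- dim(p$mask)[2L]
    ri <- (p$origin[1L] + 1L):(p$origin[1L] + ph)
    ci <- (p$origin[2L] + 1L):(p$origin[2L] + pw)
    if (max(ri) > H || max(ci) > W) {
      stop("patch at origin (", p$origin[1L], ",", p$origin[2L],
           ") exceeds the full shape ", H, "x", W)
    }
    if (rule == "or") {
      acc[ri, ci] <- pmax(acc[ri, ci], p$mask)
    } else {
      acc[ri, ci] <- acc[ri, ci] + p$mask
    }
    cnt[ri, ci] <- cnt[ri, ci] + 1L
  }
  if (any(cnt == 0L)) {
    miss <- which(cnt == 0L, arr.ind = TRUE)[1L, ]
    stop("coverage gap: pixel (", miss[1L] - 1L, ",", miss[2L] - 1L,
         ") is not covered by any patch")
  }
  if (rule == "mean") acc / cnt else acc
}

#' Parameters of the synthetic H&E-like patch generator
#'
#' The generator emulates what the network sees in stained-tissue patches:
#' an eosin-pink textured background and darker purple blob-shaped lesion
#' regions (unions of random ellipses) with a paired binary mask and
#' image-level label.  Everything is deterministic in `(seed, index)`.
#'
#' @param size canvas side length in pixels.
#' @param lesion_prob probability that a sample carries lesions.
#' @param blob_count integer range (min, max) of blobs per positive sample.
#' @param blob_radius radius range in pixels (default `size/16 .. size/4`).
#' @param bg_color,fg_color RGB means in `[0, 1]` of background / lesion
#'   tissue.
#' @param noise_sd per-pixel Gaussian noise level.
#' @param texture_block block size of the coarse texture field, pixels.
#' @param seed integer master seed.
#' @return a `synth_params` list.
#' @export
synth_params <- function(size = 512L, lesion_prob = 0.5,
                         blob_count = c(1L, 4L), blob_radius = NULL,
                         bg_color = c(0.91, 0.76, 0.85),
                         fg_color = c(0.55, 0.36, 0.62),
                         noise_sd = 0.04, texture_block = 8L, seed = 1L) {
  if (is.null(blob_radius)) blob_radius <- c(max(2, size / 16), size / 4)
  stopifnot(size >= 16L, blob_count[1L] >= 1L,
            blob_count[2L] >= blob_count[1L],
            blob_radius[1L] >= 2, blob_radius[2L] >= blob_radius[1L],
            lesion_prob >= 0, lesion_prob <= 1)
  p <- list(size = as.integer(size), lesion_prob = lesion_prob,
            blob_count = as.integer(blob_count), blob_radius = blob_radius,
            bg_color = bg_color, fg_color = fg_color, noise_sd = noise_sd,
            texture_block = as.integer(texture_block),
            seed = as.integer(seed))
  class(p) <- "synth_params"
  p
}

texture_field <- function(size, block, amplitude) {
  nb <- ceiling(size / block) + 1L
  coarse <- matrix(rnorm(nb * nb), nb, nb)
  up <- kronecker(coarse, matrix(1, block, block))
  amplitude * up[seq_len(size), seq_len(size)]
}

blob_mask <- function(size, n_blobs, radius_range) {
  m <- matrix(0L, size, size)
  xs <- matrix(rep(seq_len(size), size), size, size)        # row coordinate
  ys <- matrix(rep(seq_len(size), each = size), size, size) # col coordinate
  for (b in seq_len(n_blobs)) {
    cx <- runif(1, 1, size); cy <- runif(1, 1, size)
    a <- runif(1, radius_range[1L], radius_range[2L])
    bb <- runif(1, radius_range[1L], radius_range[2L])
    th <- runif(1, 0, pi)
    dx <- xs - cx; dy <- ys - cy
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / bb
    m[u * u + v * v <= 1] <- 1L
  }
  m
}

#' Synthesize one patch
#'
#' Deterministic in `(params$seed, index)`: the same pair always yields a
#' bit-identical sample, independent of the caller's RNG state.
#'
#' @param params a [synth_params()].
#' @param index sample index (>= 1).
#' @return a [patch_record()].
#' @export
synthesize_sample <- function(params, index) {
  stopifnot(inherits(params, "synth_params"))
  sample_seed <- (as.numeric(params$seed) * 48271 + index * 9973) %% 2147483647
  with_local_seed(sample_seed, {
    size <- params$size
    positive <- runif(1) < params$lesion_prob
    mask <- if (positive) {
      nb <- if (params$blob_count[1L] == params$blob_count[2L]) {
        params$blob_count[1L]
      } else {
        sample(params$blob_count[1L]:params$blob_count[2L], 1L)
      }
      blob_mask(size, nb, params$blob_radius)
    } else {
      matrix(0L, size, size)
    }
    img <- array(0, dim = c(size, size, 3L))
    tex_bg <- texture_field(size, params$texture_block, 0.035)
    tex_fg <- texture_field(size, params$texture_block, 0.035)
    for (ch in 1:3) {
      plane <- params$bg_color[ch] + tex_bg
      plane[mask == 1L] <- params$fg_color[ch] + tex_fg[mask == 1L]
      img[, , ch] <- plane + rnorm(size * size, sd = params$noise_sd)
    }
    img <- round(pmin(pmax(img, 0), 1) * 255) / 255  # quantize to 8-bit scale
    patch_record(img, mask)
  })
}

#' Synthesize a dataset
#'
#' @param params a [synth_params()].
#' @param n number of samples.
#' @param dir optional directory; when given, writes `images/`, `masks/` and
#'   a `manifest.tsv` (image path, mask path, label).
#' @param offset index offset (sample `i` uses generator index `offset + i`),
#'   so disjoint train/val/test splits can be drawn from one seed.
#' @return list of [patch_record()]s (invisibly when writing to `dir`).
#' @export
synthesize_dataset <- function(params, n, dir = NULL, offset = 0L) {
  records <- lapply(seq_len(n), function(i) {
    synthesize_sample(params, offset + i)
  })
  if (!is.null(dir)) {
    write_dataset(records, dir)
    return(invisible(records))
  }
  records
}

#' Write / load a dataset directory
#'
#' `write_dataset` stores each record as a PNG image plus a 0/255 PNG mask
#' and writes a tab-separated manifest (columns `image`, `mask`, `label`);
#' `load_dataset` reads such a manifest back into records.
#'
#' @param records list of [patch_record()]s.
#' @param dir dataset directory.
#' @return the manifest path (`write_dataset`) or a list of records
#'   (`load_dataset`).
#' @export
write_dataset <- function(records, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- data.frame(image = character(0), mask = character(0),
                     label = integer(0))
  for (i in seq_along(records)) {
    r <- records[[i]]
    img_rel <- file.path("images", sprintf("sample_%04d.png", i))
    msk_rel <- file.path("masks", sprintf("sample_%04d.png", i))
    png::writePNG(r$image, file.path(dir, img_rel))
    write_mask(r$mask, file.path(dir, msk_rel))
    rows <- rbind(rows, data.frame(image = img_rel, mask = msk_rel,
                                   label = r$label))
  }
  manifest <- file.path(dir, "manifest.tsv")
  write.table(rows, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' @rdname write_dataset
#' @param manifest path to a `manifest.tsv` (or the directory containing it).
#' @export
load_dataset <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.tsv")
  base <- dirname(manifest)
  tab <- read.delim(manifest, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    img <- read_image(file.path(base, tab$image[i]))
    msk <- read_mask(file.path(base, tab$mask[i]))
    r <- patch_record(img, msk)
    if (r$label != tab$label[i]) {
      stop("manifest label for row ", i, " (", tab$label[i],
           ") disagrees with the mask")
    }
    r
  })
}

## ---- augmentation -------------------------------------------------------------

rot90_ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

#' Dihedral transform of a matrix or image
#'
#' Element `k` of the dihedral group of the square: `k %% 4` counter-clockwise
#' quarter turns, preceded by a horizontal flip when `k >= 4`.  `k = 0` is the
#' identity; applying `k = 4` twice recovers the original.
#'
#' @param x (H, W) matrix or (H, W, C) array.
#' @param k integer 0..7.
#' @return transformed matrix/array.
#' @export
dihedral_transform <- function(x, k) {
  stopifnot(k %in% 0:7)
  tf <- function(m) {
    if (k >= 4L) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    for (i in seq_len(k %% 4L)) m <- rot90_ccw(m)
    m
  }
  if (length(dim(x)) == 2L) return(tf(x))
  planes <- lapply(seq_len(dim(x)[3L]), function(ch) tf(x[, , ch]))
  array(unlist(planes), dim = c(dim(planes[[1L]]), dim(x)[3L]))
}

#' Augment a patch record
#'
#' A seeded draw from the dihedral group (flips and 90-degree rotations,
#' applied identically to image and mask) plus mild colour jitter applied to
#' the image only; the mask stays binary and the image-level label is
#' unchanged.
#'
#' @param record a [patch_record()].
#' @param seed integer; fully determines the draw.
#' @param ops optional explicit operations bypassing the draw: a list with
#'   `dihedral` (0..7), `brightness` (additive) and `contrast`
#'   (multiplicative).  `list(dihedral = 0, brightness = 0, contrast = 1)` is
#'   the identity.
#' @return an augmented [patch_record()].
#' @export
augment <- function(record, seed = 1L, ops = NULL) {
  stopifnot(inherits(record, "patch_record"))
  if (is.null(ops)) {
    ops <- with_local_seed(seed, list(
      dihedral = sample(0:7, 1L),
      brightness = runif(1, -0.05, 0.05),
      contrast = runif(1, 0.9, 1.1)
    ))
  }
  img <- dihedral_transform(record$image, ops$dihedral)
  msk <- dihedral_transform(record$mask, ops$dihedral)
  img <- pmin(pmax(img * ops$contrast + ops$brightness, 0), 1)
  patch_record(img, msk, origin = record$origin)
}

## ---- mask and image I/O --------------------------------------------------------

#' Binary mask I/O in the 0/255 PNG convention
#'
#' Masks are single-channel 8-bit PNGs where 0 is background and 255 is
#' foreground.  `read_mask` maps pixel values >= 128 to 1 (warning when a
#' value other than 0/255 is present); `write_mask` writes 0/1 as 0/255.
#' `read_mask(write_mask(m))` round-trips any binary mask exactly.
#'
#' @param path PNG file path.
#' @param mask binary (H, W) matrix.
#' @return `read_mask`: binary integer matrix; `write_mask`: `path`,
#'   invisibly.
#' @export
read_mask <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) {
    stop("mask must be single-channel; ", path, " has ", dim(v)[3L],
         " channels")
  }
  raw255 <- round(v * 255)
  if (!all(raw255 %in% c(0, 255))) {
    warning("mask ", path,
            " contains values other than 0/255; applying the >=128 rule")
  }
  m <- matrix(0L, nrow(v), ncol(v))
  m[raw255 >= 128] <- 1L
  m
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read an RGB image (PNG or TIFF)
#'
#' @param path image path; `.png` always supported, `.tif`/`.tiff` when the
#'   `tiff` package is installed.
#' @return (H, W, 3) array in `[0, 1]` (alpha dropped, gray replicated).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  v <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(v)) == 2L) v <- array(rep(v, 3L), dim = c(dim(v), 3L))
  if (dim(v)[3L] > 3L) v <- v[, , 1:3, drop = FALSE]
  v
}
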