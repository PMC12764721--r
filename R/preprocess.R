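# Pixel screening, histogram enhancement, and affine augmentation.

#' Screen unreliable pixels
#'
#' Pixel-reliability testing: each pixel is compared with the median of its
#' 3x3 neighborhood (edges replicated); pixels deviating by more than
#' `k` times the neighborhood median absolute deviation are treated as
#' unreliable and replaced by that median.  Shape and `[0, 1]` range are
#' preserved.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param k outlier threshold in MAD units.
#' @return screened matrix.
#' @export
screen_pixels <- function(image, k = 3) {
  if (any(!is.finite(image))) stop("screen_pixels: image must be finite")
  n <- nrow(image); m <- ncol(image)
  pad <- rbind(image[1, , drop = FALSE], image, image[n, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, m, drop = FALSE])
  neigh <- matrix(0, n * m, 9L)
  idx <- 0L
  for (dj in 0:2) for (di in 0:2) {
    idx <- idx + 1L
    neigh[, idx] <- as.vector(pad[(1 + di):(n + di), (1 + dj):(m + dj)])
  }
  sorted <- t(apply(neigh, 1, sort))
  med <- sorted[, 5]
  mad9 <- apply(abs(neigh - med), 1, stats::median)
  x <- as.vector(image)
  bad <- abs(x - med) > k * mad9
  x[bad] <- med[bad]
  matrix(x, n, m)
}

#' Contrast-limited adaptive histogram equalization
#'
#' CLAHE over a grid of tiles; output stays in `[0, 1]` and the intensity
#' rank order within each tile is preserved (the per-tile mapping is
#' monotone).  A constant image is returned unchanged.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param tiles tile grid edge count (tiles x tiles).
#' @param clip clip limit (contrast ceiling).
#' @return enhanced matrix.
#' @export
enhance_histogram <- function(image, tiles = 8, clip = 2) {
  if (any(!is.finite(image)) || min(image) < 0 || max(image) > 1)
    stop("enhance_histogram: image must be finite and in [0, 1]")
  if (diff(range(image)) < 1e-12) return(image)
  out <- EBImage::clahe(image, nx = tiles, ny = tiles, limit = clip,
                        keep.range = TRUE)
  pmin(pmax(as.matrix(out), 0), 1)
}

#' Affine augmentation specification
#'
#' @param max_translation maximum |shift| as a fraction of the image edge,
#'   in `[0, 0.5]`.
#' @param scale_range multiplicative scale interval around 1, within
#'   `(0, 2]`.
#' @param max_rotation_deg maximum |rotation| in degrees.
#' @param copies_per_image augmented copies generated per record.
#' @param seed integer seed; augmentation is deterministic under it.
#' @return an `augment_spec` list.
#' @export
augment_spec <- function(max_translation = 0.1, scale_range = c(0.9, 1.1),
                         max_rotation_deg = 15, copies_per_image = 2,
                         seed = 1) {
  if (max_translation < 0 || max_translation > 0.5)
    stop("augment_spec: max_translation must be in [0, 0.5]")
  if (length(scale_range) != 2 || scale_range[1] <= 0 || scale_range[2] > 2 ||
      scale_range[1] > scale_range[2])
    stop("augment_spec: scale_range must be an interval within (0, 2]")
  if (copies_per_image < 0)
    stop("augment_spec: copies_per_image must be >= 0")
  structure(list(max_translation = max_translation,
                 scale_range = scale_range,
                 max_rotation_deg = max_rotation_deg,
                 copies_per_image = as.integer(copies_per_image),
                 seed = as.integer(seed)),
            class = "augment_spec")
}

#' Apply an affine warp (rotation-scale matrix + translation about center)
#'
#' Inverse-mapping warp: each output pixel samples the input at
#' `A^{-1} ((p - center) - shift) + center`, bilinearly for images and by
#' nearest neighbor for masks (so masks stay binary).  Out-of-frame samples
#' take the value 0.
#'
#' @param img numeric matrix.
#' @param A 2x2 linear part (rotation/scale).
#' @param shift length-2 translation in pixels (rows, cols).
#' @param filter `"bilinear"` or `"nearest"`.
#' @return warped matrix of the same shape.
#' @export
warp_affine <- function(img, A, shift = c(0, 0),
                        filter = c("bilinear", "nearest")) {
  filter <- match.arg(filter)
  n <- nrow(img); m <- ncol(img)
  cr <- (n + 1) / 2; cc <- (m + 1) / 2
  Ainv <- solve(A)
  rows <- rep(seq_len(n), times = m) - cr - shift[1]
  cols <- rep(seq_len(m), each = n) - cc - shift[2]
  sr <- Ainv[1, 1] * rows + Ainv[1, 2] * cols + cr
  sc <- Ainv[2, 1] * rows + Ainv[2, 2] * cols + cc
  if (filter == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= m
    out <- numeric(n * m)
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    return(matrix(out, n, m))
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  getpix <- function(r, c) {
    ok <- r >= 1 & r <= n & c >= 1 & c <= m
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * getpix(r0, c0) +
         (1 - fr) * fc       * getpix(r0, c0 + 1) +
         fr       * (1 - fc) * getpix(r0 + 1, c0) +
         fr       * fc       * getpix(r0 + 1, c0 + 1)
  matrix(out, n, m)
}

.rot_scale_mat <- function(angle_deg, s) {
  th <- angle_deg * pi / 180
  s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Affine data augmentation of one record
#'
#' Draws `copies_per_image` affine transforms (uniform translation, scale
#' and rotation over the spec's ranges) and applies each identically to the
#' image (bilinear) and the mask (nearest neighbor, so it stays binary).
#' Transforms that push more than half of the mask foreground out of frame
#' are resampled (bounded retries).  The original record is untouched; the
#' applied transform is stored on each copy as `$transform` (elements `A`
#' and `shift`).
#'
#' @param record a [thermogram_record()].
#' @param spec an [augment_spec()].
#' @param .rng_local set the RNG from `spec$seed` (set `FALSE` when the
#'   caller manages seeding across many records).
#' @return list of `copies_per_image` new records.
#' @export
augment <- function(record, spec, .rng_local = TRUE) {
  if (!inherits(spec, "augment_spec")) spec <- do.call(augment_spec, spec)
  if (.rng_local) {
    rs <- .save_rng(); on.exit(.restore_rng(rs))
    set.seed(spec$seed)
  }
  n <- nrow(record$image)
  fg <- if (is.null(record$mask)) 0 else sum(record$mask)
  out <- vector("list", spec$copies_per_image)
  for (i in seq_len(spec$copies_per_image)) {
    for (try in seq_len(10L)) {
      A <- .rot_scale_mat(stats::runif(1, -spec$max_rotation_deg,
                                       spec$max_rotation_deg),
                          stats::runif(1, spec$scale_range[1],
                                       spec$scale_range[2]))
      shift <- stats::runif(2, -spec$max_translation, spec$max_translation) * n
      img <- pmin(pmax(warp_affine(record$image, A, shift, "bilinear"), 0), 1)
      msk <- if (is.null(record$mask)) NULL else
        warp_affine(record$mask, A, shift, "nearest")
      if (fg > 0 && sum(msk) < 0.5 * fg) {
        if (try == 10L)
          stop("augment: transform repeatedly lost >50% of mask foreground")
        next
      }
      rec <- thermogram_record(record$meta, img, msk, record$label)
      rec$transform <- list(A = A, shift = shift)
      out[[i]] <- rec
      break
    }
  }
  out
}

#' Standard preprocessing applied to a record's image
#'
#' Pixel screening followed by CLAHE; mask and metadata pass through.
#'
#' @param record a [thermogram_record()].
#' @param k screening threshold in MAD units.
#' @param tiles,clip CLAHE parameters.
#' @return the record with its image preprocessed.
#' @export
preprocess_record <- function(record, k = 3, tiles = 8, clip = 2) {
  img <- enhance_histogram(screen_pixels(record$image, k = k),
                           tiles = tiles, clip = clip)
  rec <- thermogram_record(record$meta, img, record$mask, record$label)
  rec$transform <- record$transform
  rec
}
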