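# Synthetic plantar thermogram generation and on-disk dataset layout.
#
# A cohort emulates the two study groups: CG (control) feet carry a smooth
# plantar temperature field only; DM (diabetic) feet additionally carry one
# or more Gaussian-profile hyperthermic lesions, recorded in a binary
# ground-truth mask.  Images are written as 16-bit grayscale TIFF, masks as
# 8-bit PNG, with a CSV manifest tying them together.

#' Synthetic cohort configuration
#'
#' @param n_dm number of diabetic (DM) subjects; the study composition is
#'   122 DM / 45 CG.
#' @param n_cg number of control (CG) subjects.
#' @param image_size square image edge in pixels.
#' @param lesion_count_range integer interval for lesions per DM foot.
#' @param lesion_radius_range pixel interval for lesion half-max radius.
#' @param lesion_contrast relative temperature elevation of a lesion peak
#'   over its local background (must be > 0).
#' @param noise_sd additive Gaussian noise, relative units.
#' @param seed integer seed; identical configs regenerate bit-identically.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_dm = 122, n_cg = 45, image_size = 64,
                         lesion_count_range = c(1, 3),
                         lesion_radius_range = c(3, 6),
                         lesion_contrast = 0.35, noise_sd = 0.02, seed = 1) {
  chk <- function(ok, field, msg)
    if (!ok) stop("synth_config: invalid `", field, "`: ", msg)
  chk(is.numeric(n_dm) && n_dm >= 0, "n_dm", "must be a count >= 0")
  chk(is.numeric(n_cg) && n_cg >= 0, "n_cg", "must be a count >= 0")
  chk(is.numeric(image_size) && image_size >= 16, "image_size",
      "must be >= 16 pixels")
  chk(length(lesion_count_range) == 2 && all(lesion_count_range >= 1) &&
        lesion_count_range[1] <= lesion_count_range[2],
      "lesion_count_range", "must be an increasing integer interval >= 1")
  chk(length(lesion_radius_range) == 2 && all(lesion_radius_range > 0) &&
        lesion_radius_range[1] <= lesion_radius_range[2],
      "lesion_radius_range", "must be a positive increasing interval")
  chk(is.numeric(lesion_contrast) && lesion_contrast > 0, "lesion_contrast",
      "must be > 0")
  chk(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  structure(list(n_dm = as.integer(n_dm), n_cg = as.integer(n_cg),
                 image_size = as.integer(image_size),
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_range = lesion_radius_range,
                 lesion_contrast = lesion_contrast, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' One subject-foot thermogram record
#'
#' @param meta list with `subject_code` (three-digit string), `group`
#'   (`"CG"` or `"DM"`), `gender` (`"M"`/`"F"`), `side`
#'   (`"left"`/`"right"`).
#' @param image numeric matrix in `[0, 1]`.
#' @param mask binary matrix of the same shape, or `NULL`.
#' @param label integer class index (CG = 0, DM = 1).
#' @return a `thermogram_record`.
#' @export
thermogram_record <- function(meta, image, mask = NULL, label = NULL) {
  if (!grepl("^[0-9]{3}$", meta$subject_code))
    stop("subject_code must match [0-9]{3}")
  if (!meta$group %in% c("CG", "DM")) stop("group must be CG or DM")
  if (!meta$gender %in% c("M", "F")) stop("gender must be M or F")
  if (!meta$side %in% c("left", "right")) stop("side must be left or right")
  if (any(!is.finite(image)) || min(image) < 0 || max(image) > 1)
    stop("image must be finite and in [0, 1]")
  if (!is.null(mask)) {
    if (!identical(dim(image), dim(mask)))
      stop("image and mask shapes differ")
    if (!all(mask %in% c(0, 1))) stop("mask values must be in {0, 1}")
  }
  if (is.null(label)) label <- if (meta$group == "DM") 1L else 0L
  structure(list(meta = meta, image = image, mask = mask,
                 label = as.integer(label)), class = "thermogram_record")
}

# plantar support: two overlapping ellipses (forefoot, hindfoot) + toe discs
.foot_support <- function(n) {
  xs <- matrix(rep(seq(0, 1, length.out = n), each = n), n)   # column coord
  ys <- matrix(rep(seq(0, 1, length.out = n), times = n), n)  # row coord
  inside <- ((xs - 0.50)^2 / 0.21^2 + (ys - 0.42)^2 / 0.20^2 <= 1) |
            ((xs - 0.50)^2 / 0.16^2 + (ys - 0.68)^2 / 0.22^2 <= 1)
  toe_x <- c(0.30, 0.41, 0.52, 0.63, 0.72)
  toe_y <- c(0.215, 0.170, 0.150, 0.165, 0.205)
  toe_r <- c(0.055, 0.048, 0.046, 0.042, 0.040)
  for (i in seq_along(toe_x))
    inside <- inside | ((xs - toe_x[i])^2 + (ys - toe_y[i])^2 <= toe_r[i]^2)
  list(inside = inside, xs = xs, ys = ys)
}

# binary erosion with a 3x3 structuring element, k times
.erode <- function(mask, k) {
  n <- nrow(mask); m <- ncol(mask)
  for (it in seq_len(k)) {
    pad <- matrix(FALSE, n + 2, m + 2)
    pad[2:(n + 1), 2:(m + 1)] <- mask
    acc <- matrix(TRUE, n, m)
    for (dj in 0:2) for (di in 0:2)
      acc <- acc & pad[(1 + di):(n + di), (1 + dj):(m + dj)]
    mask <- acc
  }
  mask
}

.gen_record <- function(group, code, n, cfg) {
  sup <- .foot_support(n)
  xs <- sup$xs; ys <- sup$ys
  gender <- sample(c("M", "F"), 1)
  side <- sample(c("left", "right"), 1)
  # smooth low-frequency temperature field over the sole
  a <- stats::runif(3, -1, 1)
  base <- 0.45 + 0.10 * cos(pi * (ys - 0.5)) +
    0.05 * (a[1] * sin(2 * pi * xs + a[2]) + a[3] * (xs - 0.5))
  img <- ifelse(sup$inside, base, 0.06)
  mask <- matrix(0, n, n)
  if (group == "DM") {
    lcr <- cfg$lesion_count_range
    k <- lcr[1] + sample.int(lcr[2] - lcr[1] + 1L, 1) - 1L
    placed <- matrix(numeric(0), 0, 3)   # row, col, radius (pixels)
    # candidate centers: support eroded so the half-max disc fits inside
    ero_cache <- list()
    eligible <- function(rr) {
      key <- as.character(rr)
      if (is.null(ero_cache[[key]]))
        ero_cache[[key]] <<- which(.erode(sup$inside, rr))
      ero_cache[[key]]
    }
    for (restart in 1:20) {
      placed <- matrix(numeric(0), 0, 3)
      while (nrow(placed) < k) {
        r <- stats::runif(1, cfg$lesion_radius_range[1],
                          cfg$lesion_radius_range[2])
        done <- FALSE
        for (attempt in 1:12) {
          cand <- eligible(ceiling(r) + 1)
          if (length(cand) > 0 && nrow(placed) > 0) {
            pr_all <- ((cand - 1) %% n) + 1
            pc_all <- ((cand - 1) %/% n) + 1
            ok <- rep(TRUE, length(cand))
            for (p in seq_len(nrow(placed)))
              ok <- ok & (sqrt((pr_all - placed[p, 1])^2 +
                               (pc_all - placed[p, 2])^2) >=
                            placed[p, 3] + r + 2)
            cand <- cand[ok]
          }
          if (length(cand) > 0) {
            pos <- cand[sample.int(length(cand), 1)]
            placed <- rbind(placed, c(((pos - 1) %% n) + 1,
                                      ((pos - 1) %/% n) + 1, r))
            done <- TRUE
            break
          }
          # cramped geometry: shrink toward the smallest admissible radius
          r <- max(cfg$lesion_radius_range[1], r * 0.8)
        }
        if (!done) break   # arrangement blocked; restart from scratch
      }
      if (nrow(placed) == k) break
    }
    if (nrow(placed) < k)
      stop("generate_cohort: could not place ", k,
           " lesions at image_size ", n,
           "; reduce lesion_count_range or lesion_radius_range")
    rows <- matrix(rep(seq_len(n), times = n), n)
    cols <- matrix(rep(seq_len(n), each = n), n)
    for (i in seq_len(nrow(placed))) {
      d2 <- (rows - placed[i, 1])^2 + (cols - placed[i, 2])^2
      sg <- placed[i, 3] / sqrt(2 * log(2))   # half-max at the stated radius
      img <- img + cfg$lesion_contrast * exp(-d2 / (2 * sg^2))
      mask[d2 <= placed[i, 3]^2] <- 1
    }
  }
  img <- img + stats::rnorm(n * n, 0, cfg$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  thermogram_record(list(subject_code = code, group = group,
                         gender = gender, side = side), img, mask)
}

#' Generate a synthetic cohort of plantar thermograms
#'
#' Returns `n_dm + n_cg` records.  Every DM record's mask contains at least
#' one connected hyperthermic component elevated by `lesion_contrast` over
#' its local background; every CG mask is all zero.  Regeneration with the
#' same config (including seed) is bit-identical; the caller's RNG state is
#' left untouched.
#'
#' @param cfg a [synth_config()].
#' @return list of [thermogram_record()] objects (DM first, then CG).
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "synth_config")) cfg <- do.call(synth_config, cfg)
  rs <- .save_rng(); on.exit(.restore_rng(rs))
  set.seed(cfg$seed)
  n <- cfg$image_size
  codes <- sprintf("%03d", seq_len(cfg$n_dm + cfg$n_cg))
  recs <- vector("list", cfg$n_dm + cfg$n_cg)
  for (i in seq_len(cfg$n_dm))
    recs[[i]] <- .gen_record("DM", codes[i], n, cfg)
  for (i in seq_len(cfg$n_cg))
    recs[[cfg$n_dm + i]] <- .gen_record("CG", codes[cfg$n_dm + i], n, cfg)
  recs
}

# ---- on-disk layout ------------------------------------------------------

.record_filename <- function(meta)
  sprintf("%s%s%s_%s", meta$group, meta$subject_code, meta$gender, meta$side)

#' Write a cohort to disk
#'
#' Images become 16-bit grayscale TIFF named
#' `{group}{code}{gender}_{side}.tif`, masks 8-bit PNG with a `_mask`
#' suffix, and one CSV manifest row is written per record.
#'
#' @param records list of [thermogram_record()] objects.
#' @param root_path output directory (created if needed).
#' @return path to the manifest CSV, invisibly usable by [read_dataset()].
#' @export
write_dataset <- function(records, root_path) {
  dir.create(root_path, showWarnings = FALSE, recursive = TRUE)
  keys <- vapply(records, function(r)
    paste(r$meta$subject_code, r$meta$side), character(1))
  if (anyDuplicated(keys))
    stop("write_dataset: duplicate (subject_code, side): ",
         keys[duplicated(keys)][1])
  rows <- lapply(records, function(r) {
    stem <- .record_filename(r$meta)
    fn <- paste0(stem, ".tif")
    tiff::writeTIFF(r$image, file.path(root_path, fn), bits.per.sample = 16L)
    mfn <- ""
    if (!is.null(r$mask)) {
      mfn <- paste0(stem, "_mask.png")
      png::writePNG(r$mask, file.path(root_path, mfn))
    }
    data.frame(filename = fn, mask_filename = mfn,
               subject_code = r$meta$subject_code, group = r$meta$group,
               gender = r$meta$gender, side = r$meta$side,
               label = r$label, stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(filename = character(), mask_filename = character(),
               subject_code = character(), group = character(),
               gender = character(), side = character(), label = integer())
  mp <- file.path(root_path, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  mp
}

.read_gray <- function(path) {
  img <- if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Read a dataset from its manifest
#'
#' Images are normalized to `[0, 1]` (16-bit TIFF and 8/16-bit PNG are both
#' accepted), masks binarized at 0.5, and the class index assigned from the
#' group (CG = 0, DM = 1).
#'
#' @param manifest_path path to a CSV written by [write_dataset()].
#' @return list of [thermogram_record()] objects.
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("read_dataset: manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                         colClasses = c(subject_code = "character"))
  root <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    ip <- file.path(root, row$filename)
    if (!file.exists(ip)) stop("read_dataset: missing image file: ", ip)
    img <- .read_gray(ip)
    mask <- NULL
    if (!is.na(row$mask_filename) && nzchar(row$mask_filename)) {
      mp <- file.path(root, row$mask_filename)
      if (!file.exists(mp)) stop("read_dataset: missing mask file: ", mp)
      mask <- (.read_gray(mp) >= 0.5) * 1
    }
    thermogram_record(list(subject_code = row$subject_code, group = row$group,
                           gender = row$gender, side = row$side),
                      img, mask, label = row$label)
  })
}

# stack record images into a (B, H, W, 1) batch array
#' @export
records_to_batch <- function(records) {
  n <- length(records)
  d <- dim(records[[1]]$image)
  x <- array(0, c(n, d[1], d[2], 1))
  for (i in seq_len(n)) x[i, , , 1] <- records[[i]]$image
  x
}

#' @export
records_to_masks <- function(records) {
  n <- length(records)
  d <- dim(records[[1]]$image)
  m <- array(0, c(n, d[1], d[2]))
  for (i in seq_len(n))
    if (!is.null(records[[i]]$mask)) m[i, , ] <- records[[i]]$mask
  m
}

#' @export
records_labels <- function(records)
  vapply(records, function(r) r$label, integer(1))
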