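# synthetic cohort generation and dataset round-trips

test_that("cohort composition, labels and masks follow the group design", {
  recs <- tiny_cohort(n_dm = 5, n_cg = 3, seed = 7)
  expect_length(recs, 8)
  labs <- records_labels(recs)
  expect_equal(sum(labs == 1), 5)
  expect_equal(sum(labs == 0), 3)
  for (r in recs) {
    expect_true(all(r$image >= 0 & r$image <= 1))
    expect_true(all(is.finite(r$image)))
    expect_true(all(r$mask %in% c(0, 1)))
    expect_identical(dim(r$image), dim(r$mask))
    # label/mask consistency: DM <=> nonempty mask
    expect_identical(r$label == 1L, sum(r$mask) > 0)
  }
  # the full study composition is representable
  big <- synth_config(n_dm = 122, n_cg = 45, seed = 7)
  expect_equal(big$n_dm + big$n_cg, 167)
})

test_that("regeneration with the same config is bit-identical", {
  cfg <- synth_config(n_dm = 3, n_cg = 2, image_size = 64, seed = 13)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(synth_config(n_dm = 3, n_cg = 2, image_size = 64,
                                     seed = 14))
  expect_false(identical(a, c2))
  # generator leaves the caller's RNG stream untouched
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(generate_cohort(cfg)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("lesion count is controllable and components are connected", {
  recs <- tiny_cohort(n_dm = 5, n_cg = 0, seed = 21,
                      lesion_count_range = c(2, 2))
  for (r in recs)
    expect_equal(count_components(r$mask), 2)
  one <- tiny_cohort(n_dm = 3, n_cg = 0, seed = 22,
                     lesion_count_range = c(1, 1))
  for (r in one)
    expect_equal(count_components(r$mask), 1)
})

test_that("lesions are elevated over the matched background", {
  cfg <- synth_config(n_dm = 6, n_cg = 0, seed = 31)
  for (r in generate_cohort(cfg)) {
    inside <- mean(r$image[r$mask == 1])
    ring <- thermoseg:::.erode(r$mask == 0, 3) == 0 & r$mask == 0
    outside <- mean(r$image[ring])
    expect_gt(inside - outside, cfg$lesion_contrast / 2)
  }
})

test_that("invalid configurations name the offending field", {
  expect_error(synth_config(n_dm = -1), "n_dm")
  expect_error(synth_config(lesion_contrast = 0), "lesion_contrast")
  expect_error(synth_config(lesion_count_range = c(3, 1)),
               "lesion_count_range")
  expect_error(synth_config(noise_sd = -0.1), "noise_sd")
})

test_that("write/read round-trip preserves images to 16-bit precision", {
  recs <- tiny_cohort(n_dm = 3, n_cg = 2, seed = 41)
  root <- withr::local_tempdir()
  mp <- write_dataset(recs, root)
  expect_true(file.exists(mp))
  # naming scheme {group}{code}{gender}_{side}
  r1 <- recs[[1]]
  expect_true(file.exists(file.path(root, sprintf("%s%s%s_%s.tif",
    r1$meta$group, r1$meta$subject_code, r1$meta$gender, r1$meta$side))))
  back <- read_dataset(mp)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_lt(max(abs(back[[i]]$image - recs[[i]]$image)), 1 / 65535 + 1e-12)
    expect_identical(back[[i]]$mask, recs[[i]]$mask)
    expect_identical(back[[i]]$label, recs[[i]]$label)
    expect_identical(back[[i]]$meta, recs[[i]]$meta)
  }
})

test_that("masks written as 8-bit PNG binarize exactly on read", {
  root <- withr::local_tempdir()
  rec <- tiny_cohort(n_dm = 1, n_cg = 0, seed = 51)[[1]]
  write_dataset(list(rec), root)
  mfile <- list.files(root, pattern = "_mask\\.png$", full.names = TRUE)
  expect_length(mfile, 1)
  raw <- png::readPNG(mfile)
  expect_true(all(raw %in% c(0, 1)))
})

test_that("an empty record list yields a header-only manifest", {
  root <- withr::local_tempdir()
  mp <- write_dataset(list(), root)
  man <- read.csv(mp)
  expect_equal(nrow(man), 0)
  expect_true(all(c("filename", "mask_filename", "subject_code", "group",
                    "gender", "side", "label") %in% names(man)))
})

test_that("integrity violations are rejected", {
  recs <- tiny_cohort(n_dm = 2, n_cg = 0, seed = 61)
  dup <- recs[[1]]
  root <- withr::local_tempdir()
  expect_error(write_dataset(list(recs[[1]], dup), root), "duplicate")
  mp <- write_dataset(recs, root)
  bad <- file.path(root, list.files(root, pattern = "\\.tif$")[1])
  file.remove(bad)
  expect_error(read_dataset(mp), basename(bad))
  expect_error(read_dataset(file.path(root, "nope.csv")), "not found")
})

test_that("record invariants are enforced at construction", {
  img <- matrix(0.5, 8, 8)
  meta <- list(subject_code = "007", group = "DM", gender = "F",
               side = "left")
  expect_error(thermogram_record(modifyList(meta, list(subject_code = "7x")),
                                 img), "subject_code")
  expect_error(thermogram_record(meta, img * 3), "\\[0, 1\\]")
  expect_error(thermogram_record(meta, img, matrix(0.5, 8, 8)), "\\{0, 1\\}")
  expect_error(thermogram_record(meta, img, matrix(0, 4, 4)), "shapes")
  ok <- thermogram_record(meta, img, matrix(0, 8, 8))
  expect_equal(ok$label, 1L)
})
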