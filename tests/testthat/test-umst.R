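# U-shaped segmenter: shape contracts, fusion, dice loss

ns <- getNamespace("thermoseg")

test_that("encoder stages follow the halving/doubling geometry", {
  set.seed(50)
  cfg <- umst_config(image_size = 64, patch_size = 4, embed_dim = 32,
                     depths = c(1, 1, 1), heads = c(2, 2, 4))
  ctx <- ns$ctx_new(ns$ps_new(), training = FALSE)
  x <- array(rnorm(2 * 64 * 64), c(2, 64, 64, 1))
  maps <- ns$nn_umst_encode(ctx, ns$ag_node(x), cfg)
  dims <- lapply(maps, function(m) dim(ns$ag_value(m)))
  expect_equal(dims[[1]], c(2, 16, 16, 32))
  expect_equal(dims[[2]], c(2, 8, 8, 64))
  expect_equal(dims[[3]], c(2, 4, 4, 128))
})

test_that("identical images in a batch produce identical encodings", {
  set.seed(51)
  m <- tiny_model()
  img <- tiny_cohort(n_dm = 1, n_cg = 0, seed = 9)[[1]]$image
  x <- array(0, c(2, 64, 64, 1))
  x[1, , , 1] <- img; x[2, , , 1] <- img
  ctx <- ns$ctx_new(m$ps, training = FALSE)
  out <- ns$ag_value(ns$nn_umst_forward(ctx, x, m$umst)$logits)
  expect_equal(out[1, , , ], out[2, , , ], tolerance = 1e-12)
})

test_that("deeper configurations have strictly more parameters", {
  p1 <- ns$ps_n_params(tiny_model(seed = 1)$ps)
  m2 <- create_model(umst_config(image_size = 64, embed_dim = 16,
                                 depths = c(2, 2, 2), heads = c(2, 2, 2)),
                     caps_config(primary_dim = 8, n_out = 4, out_dim = 8,
                                 feature_dim = 16), seed = 1)
  expect_gt(ns$ps_n_params(m2$ps), p1)
})

test_that("decoder restores input resolution with n_seg_classes channels", {
  set.seed(52)
  for (nc in c(2, 3)) {
    cfg <- umst_config(image_size = 32, patch_size = 4, embed_dim = 8,
                       depths = c(1, 1, 1), heads = c(2, 2, 2),
                       window = 2, n_seg_classes = nc)
    ctx <- ns$ctx_new(ns$ps_new(), training = FALSE)
    x <- array(rnorm(32 * 32), c(1, 32, 32, 1))
    out <- ns$nn_umst_forward(ctx, x, cfg)
    expect_equal(dim(ns$ag_value(out$logits)), c(1, 32, 32, nc))
    expect_equal(dim(ns$ag_value(out$bottleneck)), c(1, 2, 2, 32))
  }
})

test_that("feature fusion follows the strided concat-project algebra", {
  set.seed(53)
  cfg <- umst_config(image_size = 64, embed_dim = 32, depths = c(1, 1, 1),
                     heads = c(2, 2, 4))
  ctx <- ns$ctx_new(ns$ps_new(), training = FALSE)
  maps <- list(ns$ag_node(array(rnorm(16 * 16 * 32), c(1, 16, 16, 32))),
               ns$ag_node(array(rnorm(8 * 8 * 64), c(1, 8, 8, 64))),
               ns$ag_node(array(rnorm(4 * 4 * 128), c(1, 4, 4, 128))))
  fused <- ns$nn_umst_fuse(ctx, maps, cfg)
  expect_equal(dim(ns$ag_value(fused[[2]])), c(1, 8, 8, 64))
  expect_equal(dim(ns$ag_value(fused[[3]])), c(1, 4, 4, 128))
  # ablation flag: decoder sees raw encoder maps
  cfg_off <- umst_config(image_size = 64, embed_dim = 32,
                         depths = c(1, 1, 1), heads = c(2, 2, 4),
                         fusion = FALSE)
  expect_identical(ns$nn_umst_fuse(ctx, maps, cfg_off), maps)
  # a zero shallow map with zero bias leaves only the deep map's projection
  ps0 <- ns$ps_new()
  ctx0 <- ns$ctx_new(ps0, training = FALSE)
  z <- list(ns$ag_node(array(0, c(1, 16, 16, 32))), maps[[2]], maps[[3]])
  f0 <- ns$nn_umst_fuse(ctx0, z, cfg)
  W <- ps0$params[["fuse.s1.proj.W"]]
  deep_only <- matrix(ns$ag_value(maps[[2]]), 64, 64) %*% W[33:96, ]
  expect_equal(as.vector(f0[[2]]$value), as.vector(deep_only),
               tolerance = 1e-12)
})

test_that("configuration validation enforces divisibility", {
  expect_error(umst_config(image_size = 60), "divisible")
  expect_error(umst_config(depths = c(1, 1)), "length")
  expect_error(umst_config(embed_dim = 30, heads = c(4, 4, 4)), "heads")
})

test_that("dice loss matches hand-counted overlap cases", {
  # half overlap: |S.T| = 2, |S| = |T| = 4 -> soft dice 0.5 (eps -> 0)
  target <- matrix(0, 4, 4)
  target[1, 1:4] <- 1
  logits <- array(0, c(1, 4, 4, 2))
  big <- 50
  logits[1, , , 1] <- big
  logits[1, 1, 1:2, ] <- c(0, 0, big, big)        # two true positives
  logits[1, 2, 1:2, ] <- c(0, 0, big, big)        # two false positives
  expect_equal(dice_loss(logits, array(target, c(1, 4, 4)), eps = 1e-9),
               0.5, tolerance = 1e-6)
  # perfect prediction -> ~0; inverted -> ~1
  perfect <- array(0, c(1, 4, 4, 2))
  perfect[1, , , 2] <- ifelse(target == 1, big, -big)
  perfect[1, , , 1] <- -perfect[1, , , 2]
  expect_lt(dice_loss(perfect, array(target, c(1, 4, 4))), 1e-3)
  inverted <- perfect[, , , 2:1, drop = FALSE]
  expect_gt(dice_loss(inverted, array(target, c(1, 4, 4)), eps = 1e-9),
            0.999)
  # all-background target stays finite with smoothing
  expect_true(is.finite(dice_loss(perfect, array(0, c(1, 4, 4)))))
  expect_error(dice_loss(perfect, array(0.5, c(1, 4, 4))), "binary")
})

test_that("dice loss is bounded and monotone in the intersection", {
  set.seed(54)
  vals <- sapply(1:20, function(i) {
    lg <- array(rnorm(2 * 8 * 8 * 2), c(2, 8, 8, 2))
    tg <- array(rbinom(2 * 64, 1, 0.3), c(2, 8, 8))
    dice_loss(lg, tg)
  })
  expect_true(all(vals >= 0 & vals <= 1))
  # holding |S| and |T| fixed, moving mass into the intersection lowers loss
  target <- array(0, c(1, 4, 4)); target[1, 1:2, ] <- 1
  mk_logits <- function(tp) {
    lg <- array(-50, c(1, 4, 4, 2)); lg[, , , 1] <- 50
    on <- which(target[1, , ] == 1)[seq_len(tp)]
    off <- which(target[1, , ] == 0)[seq_len(8 - tp)]
    for (i in on) { lg[1, , , 2][i] <- 50; lg[1, , , 1][i] <- -50 }
    for (i in off) { lg[1, , , 2][i] <- 50; lg[1, , , 1][i] <- -50 }
    lg
  }
  losses <- sapply(c(2, 4, 6, 8), function(tp) dice_loss(mk_logits(tp), target))
  expect_true(all(diff(losses) < 0))
})
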