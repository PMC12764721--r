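# attention primitives: window attention vs a dense oracle, masking, shapes

ns <- getNamespace("thermoseg")

test_that("window = grid, shift 0 equals dense attention on an 8x8 grid", {
  set.seed(42)
  C <- 4; heads <- 2
  x <- array(rnorm(8 * 8 * C), c(1, 8, 8, C))
  cfg <- swin_block_config(dim = C, heads = heads, window = 8, shift = 0)
  ps <- ns$ps_new()
  ctx <- ns$ctx_new(ps, training = FALSE)
  invisible(ns$ag_value(ns$nn_window_attention(ctx, ns$ag_node(x), cfg, "a")))
  ps$params[["a.relbias"]] <- array(rnorm(15^2 * heads, 0, 0.5),
                                    c(225, heads))
  ctx <- ns$ctx_new(ps, training = FALSE)
  got <- ns$ag_value(ns$nn_window_attention(ctx, ns$ag_node(x), cfg, "a"))
  expect_lt(max(abs(got - dense_attention_oracle(x, ps, "a", heads))), 1e-5)
})

test_that("attention weights are a distribution over keys in every window", {
  set.seed(43)
  x <- array(rnorm(2 * 8 * 8 * 8), c(2, 8, 8, 8))
  for (shift in c(0, 2)) {
    cfg <- swin_block_config(dim = 8, heads = 2, window = 4, shift = shift)
    ctx <- ns$ctx_new(ns$ps_new(), training = FALSE)
    invisible(ns$ag_value(ns$nn_window_attention(ctx, ns$ag_node(x), cfg, "w")))
    p <- ctx$last_attn
    expect_true(all(p >= 0))
    expect_lt(max(abs(apply(p, c(1, 2, 3), sum) - 1)), 1e-12)
  }
})

test_that("shifted windows give exactly zero weight across rolled boundaries", {
  set.seed(44)
  x <- array(rnorm(1 * 8 * 8 * 4), c(1, 8, 8, 4))
  cfg <- swin_block_config(dim = 4, heads = 2, window = 4, shift = 2)
  ctx <- ns$ctx_new(ns$ps_new(), training = FALSE)
  invisible(ns$ag_value(ns$nn_window_attention(ctx, ns$ag_node(x), cfg, "m")))
  mw <- ns$shift_attn_mask(8, 8, 4, 2)
  p <- ctx$last_attn                              # (nwin, heads, T, T)
  for (i in seq_len(dim(mw)[1])) for (hd in 1:2) {
    blocked <- p[i, hd, , ][mw[i, , ] < 0]
    if (length(blocked)) expect_equal(max(blocked), 0)
  }
})

test_that("a constant input stays constant through shifted attention", {
  x <- array(0.7, c(1, 8, 8, 4))
  cfg <- swin_block_config(dim = 4, heads = 2, window = 4, shift = 2)
  ctx <- ns$ctx_new(ns$ps_new(), training = FALSE)
  out <- ns$ag_value(ns$nn_window_attention(ctx, ns$ag_node(x), cfg, "c"))
  expect_lt(diff(range(out[1, , , 1])), 1e-12)
})

test_that("patch partition tokenizes with the declared geometry", {
  set.seed(45)
  ps <- ns$ps_new()
  ctx <- ns$ctx_new(ps, training = FALSE)
  x <- array(rnorm(2 * 64 * 64), c(2, 64, 64, 1))
  tok <- ns$ag_value(ns$nn_patch_partition(ctx, ns$ag_node(x), 4, 32, "pp"))
  expect_equal(dim(tok), c(2, 16, 16, 32))
  expect_error(ns$ag_value(ns$nn_patch_partition(
    ns$ctx_new(ns$ps_new()), ns$ag_node(array(0, c(1, 64, 64, 1))), 7, 8,
    "pq")), "divisible")
  # patch 1 with an identity projection passes pixels through
  ps2 <- ns$ps_new()
  ps2$params[["id.W"]] <- diag(1)
  ps2$params[["id.b"]] <- array(0, 1)
  ctx2 <- ns$ctx_new(ps2, training = FALSE)
  got <- ns$ag_value(ns$nn_patch_partition(ctx2, ns$ag_node(x), 1, 1, "id"))
  expect_equal(got, x)
})

test_that("patch merging halves the grid and doubles the channels", {
  set.seed(46)
  ctx <- ns$ctx_new(ns$ps_new(), training = FALSE)
  x <- array(rnorm(2 * 16 * 16 * 8), c(2, 16, 16, 8))
  y <- ns$ag_value(ns$nn_patch_merging(ctx, ns$ag_node(x), "pm"))
  expect_equal(dim(y), c(2, 8, 8, 16))
  # token count drops by 4
  expect_equal(prod(dim(x)[2:3]) / prod(dim(y)[2:3]), 4)
  expect_error(ns$nn_patch_merging(ns$ctx_new(ns$ps_new()),
                                   ns$ag_node(array(0, c(1, 7, 7, 4))), "pe"),
               "even")
})

test_that("pixel shuffle inverts space-to-depth", {
  set.seed(47)
  x <- array(rnorm(2 * 8 * 8 * 3), c(2, 8, 8, 3))
  y <- ns$ag_value(ns$ag_depth_to_space(
    ns$ag_space_to_depth(ns$ag_node(x), 2), 2))
  expect_identical(y, x)
})

test_that("hybrid channel-spatial gates stay in (0,1) and respect symmetry", {
  set.seed(48)
  cfg <- swin_block_config(dim = 8, heads = 2, window = 4, shift = 0,
                           attn_kind = "SW_HCMA")
  # uniform input: output within each window is proportional to the input
  xu <- array(1, c(1, 8, 8, 8))
  ps <- ns$ps_new()
  ctx <- ns$ctx_new(ps, training = FALSE)
  out <- ns$ag_value(ns$nn_hcma_attention(ctx, ns$ag_node(xu), cfg, "h"))
  # per channel, the gate product must be spatially constant within a window
  for (ch in 1:8)
    expect_lt(diff(range(out[1, 1:4, 1:4, ch])), 1e-10)
  # gates attenuate: |output| <= |input|
  xr <- array(rnorm(2 * 8 * 8 * 8), c(2, 8, 8, 8))
  ctx2 <- ns$ctx_new(ps, training = FALSE)
  o2 <- ns$ag_value(ns$nn_hcma_attention(ctx2, ns$ag_node(xr), cfg, "h"))
  expect_true(all(abs(o2) <= abs(xr) + 1e-12))
  expect_true(all(sign(o2) == sign(xr) | o2 == 0))
})

test_that("single-channel hybrid attention follows the closed form", {
  set.seed(49)
  cfg <- swin_block_config(dim = 1, heads = 1, window = 4, shift = 0,
                           attn_kind = "SW_HCMA")
  x <- array(rnorm(1 * 4 * 4 * 1), c(1, 4, 4, 1))
  ps <- ns$ps_new()
  ctx <- ns$ctx_new(ps, training = FALSE)
  out <- ns$ag_value(ns$nn_hcma_attention(ctx, ns$ag_node(x), cfg, "s"))
  # with one channel the channel gate is a single scalar per window:
  # out = x * sigmoid(mlp(mean(x))) * sigmoid(conv(x))
  w1 <- ps$params[["s.cg1.W"]]; b1 <- ps$params[["s.cg1.b"]]
  w2 <- ps$params[["s.cg2.W"]]; b2 <- ps$params[["s.cg2.b"]]
  d <- mean(x)
  g <- d * as.numeric(w1) + as.numeric(b1)
  g <- g * stats::pnorm(g)                         # gelu
  cgate <- 1 / (1 + exp(-(g * as.numeric(w2) + as.numeric(b2))))
  # spatial conv at init: identity kernel (center 1) + zero bias
  sgate <- 1 / (1 + exp(-x[1, , , 1]))
  expect_equal(out[1, , , 1], x[1, , , 1] * cgate * sgate, tolerance = 1e-10)
})

test_that("config validation catches head/shift violations", {
  expect_error(swin_block_config(dim = 7, heads = 2), "divisible")
  expect_error(swin_block_config(dim = 8, heads = 2, window = 4, shift = 4),
               "shift")
})
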