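# Shifted-window attention primitives: patch partition/merging, windowed
# multi-head self-attention with relative position bias and cyclic-shift
# masking, the hybrid channel-spatial attention (SW-HCMA), and the standard /
# modified transformer blocks.
#
# Feature maps are (batch, height, width, channels) arrays throughout.

#' Configuration for one transformer block
#'
#' @param dim channel count of the incoming feature map; must be divisible
#'   by `heads`.
#' @param heads number of attention heads.
#' @param window window edge length in tokens.
#' @param shift cyclic shift in tokens, `0 <= shift < window`; `shift > 0`
#'   selects the shifted-window variant with cross-boundary masking.
#' @param mlp_ratio hidden width of the block MLP as a multiple of `dim`.
#' @param norm_kind `"layer_norm"` (standard block) or `"batch_norm"`
#'   (modified block).
#' @param attn_kind `"W_MHSA"`, `"SW_MHSA"` or `"SW_HCMA"`.
#' @return a `swin_block_config` list.
#' @export
swin_block_config <- function(dim, heads = 2, window = 4, shift = 0,
                              mlp_ratio = 4, norm_kind = "layer_norm",
                              attn_kind = "W_MHSA") {
  if (dim %% heads != 0)
    stop("swin_block_config: dim (", dim, ") not divisible by heads (", heads, ")")
  if (shift < 0 || shift >= window)
    stop("swin_block_config: need 0 <= shift < window")
  norm_kind <- match.arg(norm_kind, c("layer_norm", "batch_norm"))
  attn_kind <- match.arg(attn_kind, c("W_MHSA", "SW_MHSA", "SW_HCMA"))
  structure(list(dim = dim, heads = heads, window = window, shift = shift,
                 mlp_ratio = mlp_ratio, norm_kind = norm_kind,
                 attn_kind = attn_kind),
            class = "swin_block_config")
}

# ---- token <-> window reshaping -----------------------------------------

# (B, H, W, C) -> (B, H/p, W/p, C*p*p): non-overlapping p x p blocks folded
# into channels (within-block row index fastest, then column, then channel)
ag_space_to_depth <- function(x, p) {
  x <- ag_const(x)
  d <- dim(x$value)
  B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  if (H %% p != 0 || W %% p != 0)
    stop("space_to_depth: spatial dims (", H, "x", W,
         ") must be divisible by ", p)
  out <- s2d_fwd(x$value, B, H, W, C, p)
  ag_node(out, list(x), function(g) list(s2d_bwd(g, B, H, W, C, p)))
}

# (B, H, W, C) -> (B*nh*nw, w*w, C); window order: batch fastest, then
# window-row, then window-column; row-fastest tokens
ag_win_partition <- function(x, w) {
  x <- ag_const(x)
  d <- dim(x$value)
  B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  if (H %% w != 0 || W %% w != 0)
    stop("window partition: spatial dims (", H, "x", W,
         ") must be divisible by window ", w)
  out <- win_part_fwd(x$value, B, H, W, C, w)
  ag_node(out, list(x), function(g) list(win_part_bwd(g, B, H, W, C, w)))
}

ag_win_reverse <- function(x, w, B, H, W) {
  x <- ag_const(x)
  C <- dim(x$value)[3]
  out <- win_part_bwd(x$value, B, H, W, C, w)
  ag_node(out, list(x), function(g) list(win_part_fwd(g, B, H, W, C, w)))
}

# ---- relative position bias ---------------------------------------------

# index into the (2w-1)^2 bias table for every (query, key) token pair of a
# w x w window; tokens ordered row-fastest as produced by ag_win_partition
rel_pos_index <- function(w) {
  coords <- expand.grid(r = seq_len(w), c = seq_len(w))  # r fastest
  dr <- outer(coords$r, coords$r, `-`) + w               # 1 .. 2w-1
  dc <- outer(coords$c, coords$c, `-`) + w
  as.vector(dr + (dc - 1) * (2 * w - 1))                 # query fastest
}

# ---- shifted-window attention mask --------------------------------------

# region ids on the rolled grid; tokens from different regions must not
# attend to each other across the cyclic boundary
shift_region_ids <- function(H, W, w, s) {
  cuts <- function(n) unique(pmax(0, c(0, n - w, n - s, n)))
  idh <- integer(H); idw <- integer(W)
  ch <- cuts(H); cw <- cuts(W)
  for (i in seq_len(length(ch) - 1)) idh[(ch[i] + 1):ch[i + 1]] <- i
  for (i in seq_len(length(cw) - 1)) idw[(cw[i] + 1):cw[i + 1]] <- i
  outer(idh, idw, function(a, b) a * 100L + b)
}

# additive mask (nwin, T, T): 0 within region, -1e9 across
shift_attn_mask <- function(H, W, w, s) {
  ids <- shift_region_ids(H, W, w, s)
  idarr <- array(ids, c(1, H, W, 1))
  win <- ag_value(ag_win_partition(ag_node(idarr), w))  # (nwin, T, 1)
  nwin <- dim(win)[1]; Tt <- dim(win)[2]
  m <- array(0, c(nwin, Tt, Tt))
  for (i in seq_len(nwin)) {
    v <- win[i, , 1]
    m[i, , ] <- ifelse(outer(v, v, `!=`), -1e9, 0)
  }
  m
}

# ---- attention operators -------------------------------------------------

#' Windowed multi-head self-attention
#'
#' Scaled dot-product attention computed independently inside each
#' non-overlapping window, with a learned relative position bias added to the
#' logits.  For `cfg$shift > 0` the map is cyclically rolled before
#' partitioning and attention across rolled boundaries is masked out.
#'
#' @param ctx forward context over the parameter store.
#' @param x `(B, H, W, C)` tape node or array.
#' @param cfg a [swin_block_config()].
#' @param name parameter name prefix.
#' @return tape node of the same shape; the attention probabilities of the
#'   last call are stored in `ctx$last_attn` as a plain
#'   `(B*nwin, heads, T, T)` array for inspection.
#' @keywords internal
nn_window_attention <- function(ctx, x, cfg, name) {
  d <- dim(ag_value(x))
  B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  w <- cfg$window; s <- cfg$shift; hh <- cfg$heads
  if (C %% hh != 0) stop("window attention: dim not divisible by heads")
  dh <- C / hh
  if (s > 0) x <- ag_roll(x, -s, -s)
  xw <- ag_win_partition(x, w)                # (NW, T, C)
  NW <- dim(ag_value(xw))[1]; Tt <- w * w
  qkv <- nn_linear(ctx, xw, paste0(name, ".qkv"), C, 3 * C)
  split_heads <- function(z) {
    z <- ag_reshape(z, c(NW, Tt, dh, hh))
    z <- ag_aperm(z, c(1, 4, 2, 3))           # (NW, h, T, dh)
    ag_reshape(z, c(NW * hh, Tt, dh))
  }
  q <- split_heads(ag_slice_last(qkv, 1:C))
  k <- split_heads(ag_slice_last(qkv, (C + 1):(2 * C)))
  v <- split_heads(ag_slice_last(qkv, (2 * C + 1):(3 * C)))
  logits <- ag_scale(ag_bmm(q, ag_aperm(k, c(1, 3, 2))), 1 / sqrt(dh))
  logits <- ag_reshape(logits, c(NW, hh, Tt, Tt))
  # relative position bias, shared across windows
  tab <- ctx_param(ctx, paste0(name, ".relbias"),
                   c((2 * w - 1)^2, hh), "zeros")
  bias <- ag_gather_rows(tab, rel_pos_index(w))      # (T*T, h)
  bias <- ag_reshape(ag_aperm(bias, c(2, 1)), c(hh, Tt, Tt))
  bias <- ag_aperm(ag_expand_last(bias, NW), c(4, 1, 2, 3))
  logits <- ag_add(logits, bias)
  if (s > 0) {
    mw <- shift_attn_mask(H, W, w, s)                # (nwin, T, T)
    nwin <- dim(mw)[1]
    mfull <- aperm(array(mw, c(nwin, Tt, Tt, B, hh)), c(4, 1, 5, 2, 3))
    logits <- ag_add(logits, ag_node(array(mfull, c(NW, hh, Tt, Tt))))
  }
  probs <- ag_softmax_last(logits)
  ctx$last_attn <- ag_value(probs)
  pm <- ag_reshape(probs, c(NW * hh, Tt, Tt))
  out <- ag_bmm(pm, v)                               # (NW*h, T, dh)
  out <- ag_reshape(out, c(NW, hh, Tt, dh))
  out <- ag_reshape(ag_aperm(out, c(1, 3, 4, 2)), c(NW, Tt, C))
  out <- nn_linear(ctx, out, paste0(name, ".proj"), C, C)
  out <- ag_win_reverse(out, w, B, H, W)
  if (s > 0) out <- ag_roll(out, s, s)
  out
}

# zero-padded shift matrix: (S %*% v)[i] = v[i + k]
.shift_mat <- function(n, k) {
  S <- matrix(0, n, n)
  for (i in seq_len(n)) if (i + k >= 1 && i + k <= n) S[i, i + k] <- 1
  S
}

#' Hybrid channel-spatial attention inside shifted windows
#'
#' Gating variant of the attention slot: the window content is multiplied by
#' a sigmoid channel gate (window-pooled descriptor through a two-layer MLP)
#' and a sigmoid spatial gate (channel-pooled map through a 3x3 convolution).
#' Both gates lie in (0, 1); the output keeps the input shape.
#'
#' @keywords internal
nn_hcma_attention <- function(ctx, x, cfg, name) {
  d <- dim(ag_value(x))
  B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  w <- cfg$window; s <- cfg$shift
  if (s > 0) x <- ag_roll(x, -s, -s)
  xw <- ag_win_partition(x, w)                       # (NW, T, C)
  NW <- dim(ag_value(xw))[1]; Tt <- w * w
  # channel gate
  desc <- ag_scale(ag_sum_axis(xw, 2), 1 / Tt)       # (NW, C)
  hidden <- max(1L, C %/% 4L)
  cg <- nn_linear(ctx, desc, paste0(name, ".cg1"), C, hidden)
  cg <- nn_linear(ctx, ag_gelu(cg), paste0(name, ".cg2"), hidden, C)
  cg <- ag_sigmoid(cg)                               # (NW, C)
  cg <- ag_aperm(ag_expand_last(cg, Tt), c(1, 3, 2)) # (NW, T, C)
  # spatial gate: channel-pooled window map through a 3x3 conv
  sp <- ag_scale(ag_sum_axis(xw, 3), 1 / C)          # (NW, T)
  sp <- ag_reshape(sp, c(NW, w, w))
  acc <- NULL
  kidx <- 0L
  for (dj in -1:1) for (di in -1:1) {
    kidx <- kidx + 1L
    wk <- ctx_param(ctx, paste0(name, ".sk", kidx), c(1L),
                    if (di == 0 && dj == 0) "ones" else "zeros")
    term <- ag_mul(ag_axismm(.shift_mat(w, di),
                             ag_axismm(.shift_mat(w, dj), sp, 3), 2), wk)
    acc <- if (is.null(acc)) term else ag_add(acc, term)
  }
  acc <- ag_add(acc, ctx_param(ctx, paste0(name, ".sb"), c(1L), "zeros"))
  sg <- ag_expand_last(ag_reshape(ag_sigmoid(acc), c(NW, Tt)), C)
  out <- ag_mul(ag_mul(xw, cg), sg)
  out <- ag_win_reverse(out, w, B, H, W)
  if (s > 0) out <- ag_roll(out, s, s)
  out
}

# ---- transformer blocks --------------------------------------------------

#' One (modified) Swin transformer block
#'
#' Pre-norm residual structure `u = x + Attn(Norm(x))`;
#' `out = u + MLP(Norm(u))`, where the attention slot is W-MHSA, SW-MHSA or
#' SW-HCMA and the norm is layer norm (standard block) or batch norm
#' (modified block).
#'
#' @keywords internal
nn_swin_block <- function(ctx, x, cfg, name) {
  C <- cfg$dim
  norm <- function(z, nm) {
    if (cfg$norm_kind == "layer_norm") nn_layernorm(ctx, z, nm, C)
    else nn_batchnorm(ctx, z, nm, C)
  }
  attn <- if (cfg$attn_kind == "SW_HCMA") nn_hcma_attention else nn_window_attention
  u <- ag_add(x, attn(ctx, norm(x, paste0(name, ".n1")), cfg, paste0(name, ".attn")))
  ag_add(u, nn_mlp(ctx, norm(u, paste0(name, ".n2")), paste0(name, ".mlp"),
                   C, round(cfg$mlp_ratio * C)))
}

#' Patch partition + linear embedding
#'
#' Splits the image into non-overlapping `patch x patch` squares and projects
#' each flattened patch to `embed_dim` channels.
#'
#' @keywords internal
nn_patch_partition <- function(ctx, x, patch, embed_dim, name, in_channels = 1) {
  tok <- ag_space_to_depth(x, patch)
  nn_linear(ctx, tok, name, patch * patch * in_channels, embed_dim)
}

# inverse of ag_space_to_depth: (B, H, W, p*p*C) -> (B, p*H, p*W, C)
ag_depth_to_space <- function(x, p) {
  x <- ag_const(x)
  d <- dim(x$value)
  B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4] / (p * p)
  stopifnot(C == round(C))
  out <- s2d_bwd(x$value, B, p * H, p * W, C, p)
  ag_node(out, list(x),
          function(g) list(s2d_fwd(g, B, p * H, p * W, C, p)))
}

#' Patch merging: 2x2 token neighborhoods -> half resolution, double channels
#' @keywords internal
nn_patch_merging <- function(ctx, x, name) {
  d <- dim(ag_value(x))
  if (d[2] %% 2 != 0 || d[3] %% 2 != 0)
    stop("patch merging: spatial dims (", d[2], "x", d[3], ") must be even")
  C <- d[4]
  tok <- ag_space_to_depth(x, 2)
  nn_linear(ctx, tok, name, 4 * C, 2 * C)
}
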