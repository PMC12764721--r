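# The U-shaped modified-Swin-transformer segmenter (U-MST): a three-stage
# encoder (patch partition + transformer blocks, patch merging between
# stages), a multi-level feature-fusion module, a three-stage decoder with
# skip connections, and a segmentation head at input resolution.

#' U-MST model configuration
#'
#' @param image_size square input edge length in pixels; must be divisible
#'   by `patch_size * 2^(stages-1)`.
#' @param patch_size patch edge for the initial tokenization.
#' @param embed_dim channel count after patch embedding; doubled at each
#'   patch merging.
#' @param depths integer vector of transformer-block counts per stage
#'   (length 3).
#' @param heads attention heads per stage (length 3).
#' @param window attention window edge in tokens.
#' @param mlp_ratio MLP hidden-width multiple.
#' @param n_seg_classes segmentation classes (2 = lesion vs background).
#' @param norm_kind `"batch_norm"` for the modified block (default) or
#'   `"layer_norm"` for the standard one.
#' @param fusion enable the multi-level feature-fusion module (disable for
#'   ablation runs).
#' @param in_channels input image channels (1 for thermograms).
#' @return a `umst_config` list.
#' @export
umst_config <- function(image_size = 64, patch_size = 4, embed_dim = 32,
                        depths = c(1, 1, 1), heads = c(2, 2, 4), window = 4,
                        mlp_ratio = 4, n_seg_classes = 2,
                        norm_kind = "batch_norm", fusion = TRUE,
                        in_channels = 1) {
  stages <- 3L
  if (length(depths) != stages || length(heads) != stages)
    stop("umst_config: depths and heads must have length ", stages)
  div <- patch_size * 2^(stages - 1)
  if (image_size %% div != 0)
    stop("umst_config: image_size (", image_size,
         ") must be divisible by patch_size * 2^(stages-1) = ", div)
  g1 <- image_size / patch_size
  for (i in seq_len(stages)) {
    gi <- g1 / 2^(i - 1)
    if (gi %% window != 0 && gi != window && window %% gi != 0)
      stop("umst_config: stage ", i, " grid (", gi,
           ") incompatible with window ", window)
    if ((embed_dim * 2^(i - 1)) %% heads[i] != 0)
      stop("umst_config: stage ", i, " dim not divisible by heads")
  }
  structure(list(image_size = image_size, patch_size = patch_size,
                 embed_dim = embed_dim, depths = as.integer(depths),
                 heads = as.integer(heads), window = window,
                 mlp_ratio = mlp_ratio, n_seg_classes = n_seg_classes,
                 norm_kind = norm_kind, fusion = fusion,
                 in_channels = in_channels, stages = stages),
            class = "umst_config")
}

# window size actually used at a given grid edge (shrinks when the grid is
# smaller than the configured window)
.eff_window <- function(grid, window) min(grid, window)

# block configs for one stage: SW-MHSA and SW-HCMA alternate, with the
# cyclic shift active on every second block
.stage_blocks <- function(cfg, stage) {
  dim_s <- cfg$embed_dim * 2^(stage - 1)
  grid <- cfg$image_size / cfg$patch_size / 2^(stage - 1)
  w <- .eff_window(grid, cfg$window)
  lapply(seq_len(cfg$depths[stage]), function(b) {
    shifted <- b %% 2 == 0 && grid > w
    swin_block_config(dim = dim_s, heads = cfg$heads[stage], window = w,
                      shift = if (shifted) w %/% 2 else 0,
                      mlp_ratio = cfg$mlp_ratio, norm_kind = cfg$norm_kind,
                      attn_kind = if (b %% 2 == 0) "SW_HCMA"
                                  else if (shifted) "SW_MHSA" else "W_MHSA")
  })
}

#' Encoder: three stages of (patch partition | merging) + transformer blocks
#'
#' Stage `i` output has spatial edge `image_size / (patch_size * 2^(i-1))`
#' and `embed_dim * 2^(i-1)` channels.
#'
#' @keywords internal
nn_umst_encode <- function(ctx, x, cfg) {
  maps <- vector("list", cfg$stages)
  h <- nn_patch_partition(ctx, x, cfg$patch_size, cfg$embed_dim, "enc.embed",
                          in_channels = cfg$in_channels)
  for (s in seq_len(cfg$stages)) {
    if (s > 1) h <- nn_patch_merging(ctx, h, sprintf("enc.s%d.merge", s))
    for (b in seq_along(.stage_blocks(cfg, s)))
      h <- nn_swin_block(ctx, h, .stage_blocks(cfg, s)[[b]],
                         sprintf("enc.s%d.b%d", s, b))
    maps[[s]] <- h
  }
  maps
}

#' Feature fusion: each stage map is downsampled by a strided 2x2 projection
#' and folded into the next stage along the channel axis
#'
#' @keywords internal
nn_umst_fuse <- function(ctx, maps, cfg) {
  if (!cfg$fusion) return(maps)
  out <- maps
  for (s in 1:(cfg$stages - 1)) {
    C_s <- cfg$embed_dim * 2^(s - 1)
    C_n <- 2 * C_s
    down <- nn_linear(ctx, ag_space_to_depth(out[[s]], 2),
                      sprintf("fuse.s%d.down", s), 4 * C_s, C_s)
    cat_ <- ag_concat_last(list(down, out[[s + 1]]))
    out[[s + 1]] <- nn_linear(ctx, cat_, sprintf("fuse.s%d.proj", s),
                              C_s + C_n, C_n)
  }
  out
}

# constant 1-D linear-interpolation matrix (n*f rows, n cols)
.upsample_mat <- function(n, f) {
  m <- n * f
  M <- matrix(0, m, n)
  for (i in seq_len(m)) {
    src <- (i - 0.5) / f - 0.5          # 0-based source coordinate
    lo <- floor(src)
    t <- src - lo
    lo_c <- min(max(lo, 0), n - 1)
    hi_c <- min(max(lo + 1, 0), n - 1)
    M[i, lo_c + 1] <- M[i, lo_c + 1] + (1 - t)
    M[i, hi_c + 1] <- M[i, hi_c + 1] + t
  }
  M
}

ag_upsample <- function(x, f) {
  d <- dim(ag_value(x))
  Mh <- .upsample_mat(d[2], f)
  Mw <- .upsample_mat(d[3], f)
  ag_axismm(Mw, ag_axismm(Mh, x, 2), 3)
}

#' Decoder: transformer block at the bottleneck, then two stages of
#' (2x upsample, skip concatenation, projection, transformer block), then a
#' segmentation head that restores the input resolution
#'
#' @keywords internal
nn_umst_decode <- function(ctx, fused, cfg) {
  S <- cfg$stages
  Cb <- cfg$embed_dim * 2^(S - 1)
  hb <- fused[[S]]
  hb <- nn_swin_block(ctx, hb, .stage_blocks(cfg, S)[[1]], "dec.bottom")
  h <- hb
  for (s in (S - 1):1) {
    C_s <- cfg$embed_dim * 2^(s - 1)
    # patch expanding: learned 2x upsampling by projection + pixel shuffle
    h <- ag_depth_to_space(nn_linear(ctx, h, sprintf("dec.s%d.up", s),
                                     2 * C_s, 4 * C_s), 2)
    h <- ag_concat_last(list(h, fused[[s]]))
    h <- nn_linear(ctx, h, sprintf("dec.s%d.proj", s), 2 * C_s, C_s)
    h <- nn_swin_block(ctx, h, .stage_blocks(cfg, s)[[1]],
                       sprintf("dec.s%d.blk", s))
  }
  p <- cfg$patch_size
  logits <- ag_depth_to_space(
    nn_linear(ctx, h, "dec.head", cfg$embed_dim,
              p * p * cfg$n_seg_classes), p)
  list(logits = logits, bottleneck = hb)
}

#' Full U-MST forward pass
#'
#' @param ctx forward context.
#' @param x `(B, H, W, C)` image batch (array or node), values in `[0, 1]`.
#' @param cfg a [umst_config()].
#' @return list with `logits` (`(B, H, W, n_seg_classes)` node), `bottleneck`
#'   (deepest fused map after the bottleneck block) and `stages` (encoder
#'   maps).
#' @keywords internal
nn_umst_forward <- function(ctx, x, cfg) {
  x <- ag_const(x)
  d <- dim(ag_value(x))
  if (d[2] != cfg$image_size || d[3] != cfg$image_size)
    stop("umst: input is ", d[2], "x", d[3], ", config expects square ",
         cfg$image_size)
  maps <- nn_umst_encode(ctx, x, cfg)
  fused <- nn_umst_fuse(ctx, maps, cfg)
  dec <- nn_umst_decode(ctx, fused, cfg)
  list(logits = dec$logits, bottleneck = dec$bottleneck,
       stages = maps, fused = fused)
}

# ---- Dice loss -----------------------------------------------------------

# tape version used during training: soft Dice on the foreground probability
ag_dice_loss <- function(logits, target, eps = 1) {
  d <- dim(ag_value(logits))
  nc <- d[length(d)]
  p <- ag_slice_last(ag_softmax_last(logits), nc)   # foreground channel
  t <- array(ag_value(ag_const(target)), dim(ag_value(p)))
  inter <- ag_sum(ag_mul(p, ag_node(t)))
  num <- ag_add(ag_scale(inter, 2), eps)
  den <- ag_add(ag_add(ag_sum(p), sum(t)), eps)
  ag_sub(ag_const(1), ag_div(num, den))
}

#' Soft Dice loss
#'
#' `1 - (2|S.T| + eps) / (|S| + |T| + eps)` where `S` is the predicted
#' foreground probability map (softmax over the channel axis of `logits`,
#' last channel taken as foreground) and `T` the binary target.  Lies in
#' `[0, 1]` and is finite for an all-background target whenever `eps > 0`.
#'
#' @param logits numeric array `(B, H, W, n_classes)` (or `(H, W, n_classes)`).
#' @param target binary array matching the spatial (and batch) dimensions.
#' @param eps smoothing constant.
#' @return scalar loss.
#' @export
dice_loss <- function(logits, target, eps = 1) {
  logits <- as.array(logits)
  if (length(dim(logits)) == 3) dim(logits) <- c(1, dim(logits))
  target <- as.array(target)
  if (!all(target %in% c(0, 1))) stop("dice_loss: target must be binary")
  if (prod(dim(target)) * dim(logits)[4] != prod(dim(logits)))
    stop("dice_loss: shape mismatch between logits and target")
  as.numeric(ag_value(ag_dice_loss(ag_node(logits), target, eps)))
}

#' Count trainable parameters of a parameter store
#' @keywords internal
ps_n_params <- function(ps) sum(vapply(ps$params, length, numeric(1)))
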