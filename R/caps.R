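# Capsule-network feature extraction: primary capsules from the segmenter's
# bottleneck, the squash nonlinearity, iterative dynamic routing by
# agreement, and reduction to a flat feature vector.

#' Capsule layer configuration
#'
#' @param primary_dim pose-vector length of the primary capsules.
#' @param n_out number of output capsules.
#' @param out_dim pose-vector length of the output capsules.
#' @param routing_iters dynamic-routing iterations (>= 1, typically 3).
#' @param feature_dim length of the flattened feature vector Z.
#' @param use_mask concatenate the predicted foreground probability
#'   (downsampled) to the bottleneck before forming primary capsules.
#' @return a `caps_config` list.
#' @export
caps_config <- function(primary_dim = 8, n_out = 8, out_dim = 16,
                        routing_iters = 3, feature_dim = 32,
                        use_mask = FALSE) {
  stopifnot(primary_dim >= 1, n_out >= 1, out_dim >= 1, routing_iters >= 1,
            feature_dim >= 1)
  structure(list(primary_dim = as.integer(primary_dim),
                 n_out = as.integer(n_out), out_dim = as.integer(out_dim),
                 routing_iters = as.integer(routing_iters),
                 feature_dim = as.integer(feature_dim),
                 use_mask = isTRUE(use_mask)),
            class = "caps_config")
}

#' Squash nonlinearity
#'
#' Maps a vector `v` to `(||v||^2 / (1 + ||v||^2)) * v / ||v||`: direction is
#' preserved, the norm is compressed into `[0, 1)`, and the zero vector maps
#' to itself (the well-defined limit).  For a matrix, rows are squashed
#' independently.
#'
#' @param v numeric vector, or matrix of row vectors.
#' @return object of the same shape.
#' @export
squash <- function(v) {
  if (any(!is.finite(v))) stop("squash: input must be finite")
  if (is.matrix(v)) {
    r2 <- rowSums(v * v)
    return(v * (sqrt(r2) / (1 + r2)))
  }
  r2 <- sum(v * v)
  v * (sqrt(r2) / (1 + r2))
}

#' Dynamic routing by agreement (reference form)
#'
#' Plain-arithmetic routing for a single set of input capsules: logits
#' `b[i, j]` start at zero; each iteration computes coupling coefficients
#' `D = softmax_j(b)`, weighted sums `S_j = sum_i D[i,j] * Yhat[i,j,]` with
#' prediction vectors `Yhat[i,j,] = W[,,j] %*% U[i,]`, squashed outputs
#' `G_j`, and the agreement update `b[i,j] <- b[i,j] + Yhat[i,j,] . G_j`.
#' The transformation matrices are shared across input capsules (global
#' parameter sharing).
#'
#' @param U input capsules, `(n_in, primary_dim)` matrix.
#' @param W transformation array `(primary_dim, out_dim, n_out)`.
#' @param routing_iters number of iterations (>= 1).
#' @return list with `G` (`(n_out, out_dim)` output capsules), `D_history`
#'   (coupling matrices per iteration) and `b` (final logits).
#' @export
dynamic_routing <- function(U, W, routing_iters = 3) {
  stopifnot(routing_iters >= 1)
  U <- as.matrix(U)
  n_in <- nrow(U); pd <- ncol(U)
  stopifnot(dim(W)[1] == pd)
  od <- dim(W)[2]; n_out <- dim(W)[3]
  Yhat <- array(0, c(n_in, n_out, od))
  for (j in seq_len(n_out)) Yhat[, j, ] <- U %*% W[, , j]
  b <- matrix(0, n_in, n_out)
  D_history <- vector("list", routing_iters)
  G <- matrix(0, n_out, od)
  for (it in seq_len(routing_iters)) {
    D <- t(apply(b, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
    if (n_out == 1) D <- matrix(D, n_in, 1)
    D_history[[it]] <- D
    for (j in seq_len(n_out))
      G[j, ] <- squash(colSums(D[, j] * matrix(Yhat[, j, ], n_in, od)))
    if (it < routing_iters)
      for (j in seq_len(n_out))
        b[, j] <- b[, j] + matrix(Yhat[, j, ], n_in, od) %*% G[j, ]
  }
  list(G = G, D_history = D_history, b = b)
}

# ---- tape versions used inside the trainable pipeline -------------------

# primary capsules: 1x1 projection of the (B, h, w, C) bottleneck, reshaped
# into (B, n_primary, primary_dim) pose vectors and squashed
nn_primary_capsules <- function(ctx, fmap, cfg, name, channels = NULL) {
  d <- dim(ag_value(fmap))
  B <- d[1]; S <- d[2] * d[3]; C <- d[4]
  pc <- if (is.null(channels)) C else channels
  if (pc %% cfg$primary_dim != 0)
    stop("primary capsules: channel count ", pc,
         " not divisible by primary_dim ", cfg$primary_dim)
  h <- nn_linear(ctx, fmap, paste0(name, ".proj"), C, pc)
  Gr <- pc %/% cfg$primary_dim
  h <- ag_reshape(h, c(B, d[2], d[3], cfg$primary_dim, Gr))
  h <- ag_reshape(h, c(B, S, cfg$primary_dim, Gr))
  h <- ag_aperm(h, c(1, 2, 4, 3))                    # (B, S, G, pd)
  h <- ag_reshape(h, c(B, S * Gr, cfg$primary_dim))  # (B, n_primary, pd)
  ag_squash_last(h)
}

# dynamic routing on the tape; mirrors dynamic_routing() but batched and
# differentiable end to end (gradients flow through the unrolled iterations)
nn_dynamic_routing <- function(ctx, U, cfg, name) {
  d <- dim(ag_value(U))
  B <- d[1]; nP <- d[2]; pd <- d[3]
  nO <- cfg$n_out; od <- cfg$out_dim
  parts <- vector("list", nO)
  Um <- ag_reshape(U, c(B * nP, pd))
  for (j in seq_len(nO)) {
    Wj <- ctx_param(ctx, sprintf("%s.W%d", name, j), c(pd, od), "xavier")
    parts[[j]] <- ag_reshape(ag_matmul(Um, Wj), c(B, nP, od))
  }
  Yhat <- ag_reshape(ag_concat_last(parts), c(B, nP, od, nO))
  Yhat <- ag_aperm(Yhat, c(1, 2, 4, 3))              # (B, nP, nO, od)
  b <- ag_node(array(0, c(B, nP, nO)))
  G <- NULL
  for (it in seq_len(cfg$routing_iters)) {
    D <- ag_softmax_last(b)                          # couplings sum to 1 over j
    Dex <- ag_expand_last(D, od)                     # (B, nP, nO, od)
    S <- ag_sum_axis(ag_mul(Dex, Yhat), 2)           # (B, nO, od)
    G <- ag_squash_last(S)
    if (it < cfg$routing_iters) {
      Gex <- ag_aperm(ag_expand_last(G, nP), c(1, 4, 2, 3))
      b <- ag_add(b, ag_sum_axis(ag_mul(Yhat, Gex), 4))
    }
  }
  G
}

# fully connected reduction of the output capsules to a flat feature vector
nn_capsule_features <- function(ctx, G, cfg, name) {
  d <- dim(ag_value(G))
  flat <- ag_reshape(G, c(d[1], d[2] * d[3]))
  ag_gelu(nn_linear(ctx, flat, paste0(name, ".fc"), d[2] * d[3],
                    cfg$feature_dim))
}

# complete capsule head: bottleneck (+ optional predicted-mask channel) ->
# primary capsules -> routing -> feature vector Z
nn_caps_forward <- function(ctx, bottleneck, cfg, name = "caps",
                            seg_logits = NULL) {
  fmap <- bottleneck
  if (cfg$use_mask && !is.null(seg_logits)) {
    d <- dim(ag_value(seg_logits))
    db <- dim(ag_value(bottleneck))
    nc <- d[length(d)]
    p <- ag_slice_last(ag_softmax_last(seg_logits), nc)
    f <- d[2] / db[2]
    Md <- t(.upsample_mat(db[2], f)) / f              # average pooling
    p <- ag_axismm(t(.upsample_mat(db[3], d[3] / db[3])) / (d[3] / db[3]),
                   ag_axismm(Md, p, 2), 3)
    fmap <- ag_concat_last(list(fmap, p))
  }
  U <- nn_primary_capsules(ctx, fmap, cfg, paste0(name, ".prim"))
  G <- nn_dynamic_routing(ctx, U, cfg, paste0(name, ".route"))
  nn_capsule_features(ctx, G, cfg, paste0(name, ".feat"))
}
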