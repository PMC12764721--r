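# shared fixtures: tiny cohorts and models, built in code at test time

tiny_cohort <- function(n_dm = 4, n_cg = 2, size = 64, seed = 3, ...)
  generate_cohort(synth_config(n_dm = n_dm, n_cg = n_cg, image_size = size,
                               seed = seed, ...))

tiny_model <- function(embed = 16, size = 64, seed = 5, feature_dim = 16,
                       norm = "batch_norm")
  create_model(umst_config(image_size = size, embed_dim = embed,
                           depths = c(1, 1, 1), heads = c(2, 2, 2),
                           norm_kind = norm),
               caps_config(primary_dim = 8, n_out = 4, out_dim = 8,
                           feature_dim = feature_dim),
               seed = seed)

# independent brute-force confusion-matrix counting (loops, no vectorization)
brute_confusion <- function(pred, truth, positive = 1) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] == positive; t <- truth[i] == positive
    if (p && t) tp <- tp + 1 else if (!p && !t) tn <- tn + 1
    else if (p && !t) fp <- fp + 1 else fn <- fn + 1
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# independent pixel counting for overlap metrics
brute_overlap <- function(S, T_) {
  i <- u <- s <- t <- 0
  for (k in seq_along(S)) {
    if (S[k] == 1 && T_[k] == 1) i <- i + 1
    if (S[k] == 1 || T_[k] == 1) u <- u + 1
    if (S[k] == 1) s <- s + 1
    if (T_[k] == 1) t <- t + 1
  }
  c(inter = i, union = u, s = s, t = t)
}

# brute-force global attention over the token grid, plain loops; reads the
# projection weights straight out of the parameter store
dense_attention_oracle <- function(x, ps, prefix, heads) {
  H <- dim(x)[2]; W <- dim(x)[3]; C <- dim(x)[4]
  dh <- C / heads
  tok <- matrix(0, H * W, C)
  for (r in seq_len(H)) for (cc in seq_len(W))
    tok[r + (cc - 1) * H, ] <- x[1, r, cc, ]
  QKV <- tok %*% ps$params[[paste0(prefix, ".qkv.W")]] +
    matrix(ps$params[[paste0(prefix, ".qkv.b")]], H * W, 3 * C, byrow = TRUE)
  Q <- QKV[, 1:C]; K <- QKV[, (C + 1):(2 * C)]; V <- QKV[, (2 * C + 1):(3 * C)]
  ridx <- thermoseg:::rel_pos_index(H)
  tab <- ps$params[[paste0(prefix, ".relbias")]]
  out <- matrix(0, H * W, C)
  for (hd in seq_len(heads)) {
    cols <- ((hd - 1) * dh + 1):(hd * dh)
    S <- (Q[, cols] %*% t(K[, cols])) / sqrt(dh) +
      matrix(tab[ridx, hd], H * W, H * W)
    P <- t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
    out[, cols] <- P %*% V[, cols]
  }
  out <- out %*% ps$params[[paste0(prefix, ".proj.W")]] +
    matrix(ps$params[[paste0(prefix, ".proj.b")]], H * W, C, byrow = TRUE)
  res <- array(0, dim(x))
  for (r in seq_len(H)) for (cc in seq_len(W))
    res[1, r, cc, ] <- out[r + (cc - 1) * H, ]
  res
}

# connected components of a binary mask by flood fill (4-connectivity)
count_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  seen <- matrix(FALSE, n, m)
  comp <- 0
  for (r0 in seq_len(n)) for (c0 in seq_len(m)) {
    if (mask[r0, c0] == 1 && !seen[r0, c0]) {
      comp <- comp + 1
      stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- p[1] + d[1]; cc <- p[2] + d[2]
          if (rr >= 1 && rr <= n && cc >= 1 && cc <= m &&
              mask[rr, cc] == 1 && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            stack[[length(stack) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  comp
}
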