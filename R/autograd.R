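# Reverse-mode automatic differentiation on base-R arrays.
#
# A node is an environment holding a value (always an array), the list of
# parent nodes it was computed from, and a vector-Jacobian product closure.
# ag_backward() walks the tape in reverse topological order and accumulates
# gradients into every node; parameter gradients are then read off by name.
# Every op's backward rule is exercised against central finite differences
# in the test suite.

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$n <- 0L

#' @keywords internal
ag_node <- function(value, parents = list(), vjp = NULL) {
  if (is.null(dim(value))) dim(value) <- length(value)
  e <- new.env(parent = emptyenv())
  .ag_counter$n <- .ag_counter$n + 1L
  e$id <- .ag_counter$n
  e$value <- value
  e$parents <- parents
  e$vjp <- vjp
  e$grad <- NULL
  class(e) <- "ag_node"
  e
}

is_ag <- function(x) inherits(x, "ag_node")

#' Wrap a plain array as a constant node
#' @keywords internal
ag_const <- function(x) {
  if (is_ag(x)) return(x)
  ag_node(as.array(x))
}

ag_value <- function(x) if (is_ag(x)) x$value else as.array(x)

# ---- backward pass -------------------------------------------------------

#' Run reverse-mode accumulation from a scalar root
#' @keywords internal
ag_backward <- function(root, grad = NULL) {
  if (is.null(grad)) {
    stopifnot(length(root$value) == 1L)
    grad <- array(1, dim = dim(root$value))
  }
  # iterative post-order topological sort
  topo <- vector("list", 256L); nt <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, i = 0L))
  ns <- 1L
  assign(as.character(root$id), TRUE, envir = seen)
  while (ns > 0L) {
    fr <- stack[[ns]]
    node <- fr$node
    ps <- node$parents
    if (fr$i < length(ps)) {
      stack[[ns]]$i <- fr$i + 1L
      p <- ps[[fr$i + 1L]]
      key <- as.character(p$id)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        ns <- ns + 1L
        stack[[ns]] <- list(node = p, i = 0L)
      }
    } else {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- node
      ns <- ns - 1L
    }
  }
  root$grad <- grad
  for (k in seq(nt, 1L)) {
    node <- topo[[k]]
    if (is.null(node$vjp) || is.null(node$grad)) next
    gs <- node$vjp(node$grad)
    for (j in seq_along(node$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- node$parents[[j]]
      if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
    }
  }
  invisible(root)
}

# ---- elementwise arithmetic ---------------------------------------------

# b may be: same shape as a, a scalar, or a vector matching a's last axis
# (bias broadcast).  The backward rule sums over the broadcast dimensions.
ag_add <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  da <- dim(a$value); db <- dim(b$value)
  if (identical(da, db)) {
    ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
  } else if (length(b$value) == 1L) {
    ag_node(a$value + as.vector(b$value), list(a, b),
            function(g) list(g, array(sum(g), dim = c(1L))))
  } else if (length(db) == 1L && db == da[length(da)]) {
    C <- db; rest <- prod(da) / C
    val <- a$value + rep(as.vector(b$value), each = rest)
    ag_node(val, list(a, b), function(g)
      list(g, array(colSums(matrix(g, rest, C)), dim = c(C))))
  } else stop("ag_add: incompatible shapes")
}

ag_neg <- function(a) {
  a <- ag_const(a)
  ag_node(-a$value, list(a), function(g) list(-g))
}

ag_sub <- function(a, b) ag_add(a, ag_neg(b))

ag_mul <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  if (identical(dim(a$value), dim(b$value))) {
    av <- a$value; bv <- b$value
    ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
  } else if (length(b$value) == 1L) {
    av <- a$value; bv <- as.vector(b$value)
    ag_node(av * bv, list(a, b),
            function(g) list(g * bv, array(sum(g * av), dim = c(1L))))
  } else if (length(a$value) == 1L) {
    ag_mul(b, a)
  } else stop("ag_mul: incompatible shapes")
}

ag_scale <- function(a, s) { # s plain numeric scalar, no grad
  a <- ag_const(a); s <- as.numeric(s)
  ag_node(a$value * s, list(a), function(g) list(g * s))
}

ag_div <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  av <- a$value; bv <- b$value
  if (identical(dim(av), dim(bv))) {
    ag_node(av / bv, list(a, b),
            function(g) list(g / bv, -g * av / (bv * bv)))
  } else if (length(bv) == 1L) {
    b1 <- as.vector(bv)
    ag_node(av / b1, list(a, b),
            function(g) list(g / b1, array(-sum(g * av) / (b1 * b1), c(1L))))
  } else stop("ag_div: incompatible shapes")
}

# ---- linear algebra ------------------------------------------------------

ag_matmul <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  av <- a$value; bv <- b$value
  ag_node(av %*% bv, list(a, b), function(g) {
    g <- matrix(g, nrow(av), ncol(bv))
    list(tcrossprod(g, bv), crossprod(av, g))
  })
}

# batched matmul: a (n, p, q) x b (n, q, r) -> (n, p, r); compiled kernels
ag_bmm <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  av <- a$value; bv <- b$value
  n <- dim(av)[1]; p <- dim(av)[2]; q <- dim(av)[3]; r <- dim(bv)[3]
  stopifnot(dim(bv)[1] == n, dim(bv)[2] == q)
  out <- bmm_fwd(av, bv, n, p, q, r)
  ag_node(out, list(a, b), function(g) {
    list(bmm_grad_a(g, bv, n, p, q, r),
         bmm_grad_b(av, g, n, p, q, r))
  })
}

# apply a constant matrix M (m x d) along one axis of x (that axis has size d)
ag_axismm <- function(M, x, axis) {
  x <- ag_const(x)
  d <- dim(x$value)
  k <- length(d)
  perm <- c(axis, setdiff(seq_len(k), axis))
  xp <- aperm(x$value, perm)
  rest <- prod(d[-axis])
  y <- M %*% matrix(xp, d[axis], rest)
  newd <- d; newd[axis] <- nrow(M)
  out <- aperm(array(y, c(nrow(M), d[-axis])), order(perm))
  ag_node(out, list(x), function(g) {
    gp <- aperm(g, perm)
    gx <- t(M) %*% matrix(gp, nrow(M), rest)
    list(aperm(array(gx, c(d[axis], d[-axis])), order(perm)))
  })
}

# ---- shape ops -----------------------------------------------------------

ag_reshape <- function(x, dims) {
  x <- ag_const(x)
  old <- dim(x$value)
  stopifnot(prod(old) == prod(dims))
  v <- x$value; dim(v) <- dims
  ag_node(v, list(x), function(g) { dim(g) <- old; list(g) })
}

ag_aperm <- function(x, perm) {
  x <- ag_const(x)
  ag_node(aperm(x$value, perm), list(x),
          function(g) list(aperm(g, order(perm))))
}

# concatenate along the last axis; all heads equal
ag_concat_last <- function(xs) {
  xs <- lapply(xs, ag_const)
  ds <- lapply(xs, function(x) dim(x$value))
  k <- length(ds[[1]])
  head_d <- ds[[1]][-k]
  rest <- prod(head_d)
  Cs <- vapply(ds, function(d) d[k], numeric(1))
  mat <- do.call(cbind, lapply(xs, function(x) matrix(x$value, rest)))
  out <- array(mat, c(head_d, sum(Cs)))
  ag_node(out, xs, function(g) {
    gm <- matrix(g, rest)
    offs <- cumsum(c(0, Cs))
    lapply(seq_along(xs), function(i) {
      array(gm[, (offs[i] + 1):offs[i + 1], drop = FALSE],
            c(head_d, Cs[i]))
    })
  })
}

# select indices along the last axis
ag_slice_last <- function(x, idx) {
  x <- ag_const(x)
  d <- dim(x$value); k <- length(d)
  rest <- prod(d[-k])
  m <- matrix(x$value, rest, d[k])
  out <- array(m[, idx, drop = FALSE], c(d[-k], length(idx)))
  ag_node(out, list(x), function(g) {
    gm <- matrix(0, rest, d[k])
    gsub <- matrix(g, rest, length(idx))
    for (j in seq_along(idx))
      gm[, idx[j]] <- gm[, idx[j]] + gsub[, j]
    list(array(gm, d))
  })
}

# cyclic roll along the H and W axes of a (B, H, W, C) tensor
ag_roll <- function(x, sh, sw) {
  x <- ag_const(x)
  d <- dim(x$value)
  rollidx <- function(n, s) { if (s %% n == 0) seq_len(n) else ((seq_len(n) - 1 - s) %% n) + 1 }
  ih <- rollidx(d[2], sh); iw <- rollidx(d[3], sw)
  out <- x$value[, ih, iw, , drop = FALSE]
  ag_node(out, list(x), function(g) {
    jh <- rollidx(d[2], -sh); jw <- rollidx(d[3], -sw)
    list(g[, jh, jw, , drop = FALSE])
  })
}

# repeat along a new trailing axis
ag_expand_last <- function(x, times) {
  x <- ag_const(x)
  d <- dim(x$value)
  out <- array(rep(as.vector(x$value), times), c(d, times))
  ag_node(out, list(x), function(g) {
    list(array(rowSums(matrix(g, prod(d), times)), d))
  })
}

# sum over one axis
ag_sum_axis <- function(x, axis) {
  x <- ag_const(x)
  d <- dim(x$value); k <- length(d)
  perm <- c(axis, setdiff(seq_len(k), axis))
  xp <- aperm(x$value, perm)
  out <- array(colSums(matrix(xp, d[axis], prod(d[-axis]))), d[-axis])
  ag_node(out, list(x), function(g) {
    gx <- matrix(rep(as.vector(g), each = d[axis]), d[axis])
    list(aperm(array(gx, c(d[axis], d[-axis])), order(perm)))
  })
}

ag_sum <- function(x) {
  x <- ag_const(x)
  d <- dim(x$value)
  ag_node(array(sum(x$value), c(1L)), list(x),
          function(g) list(array(as.vector(g), d)))
}

ag_mean <- function(x) ag_scale(ag_sum(x), 1 / length(ag_value(x)))

# ---- nonlinearities ------------------------------------------------------

ag_sigmoid <- function(x) {
  x <- ag_const(x)
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_gelu <- function(x) {
  x <- ag_const(x)
  v <- x$value
  fw <- gelu_fwd(v)
  ph <- fw$ph
  ag_node(fw$y, list(x), function(g) list(gelu_bwd(g, v, ph)))
}

# softmax over the last axis
ag_softmax_last <- function(x) {
  x <- ag_const(x)
  d <- dim(x$value); k <- length(d)
  rest <- prod(d[-k]); C <- d[k]
  m <- matrix(x$value, rest, C)
  m <- m - m[cbind(seq_len(rest), max.col(m, ties.method = "first"))]
  e <- exp(m)
  p <- e / .rowSums(e, nrow(e), ncol(e))
  out <- array(p, d)
  ag_node(out, list(x), function(g) {
    gm <- matrix(g, rest, C)
    pm <- p * gm; dot <- .rowSums(pm, nrow(pm), ncol(pm))
    list(array(p * (gm - dot), d))
  })
}

# squash nonlinearity along the last axis: v * ||v|| / (1 + ||v||^2)
ag_squash_last <- function(x) {
  x <- ag_const(x)
  d <- dim(x$value); k <- length(d)
  rest <- prod(d[-k]); C <- d[k]
  V <- matrix(x$value, rest, C)
  VV <- V * V; r2 <- .rowSums(VV, nrow(VV), ncol(VV))
  r <- sqrt(r2)
  a <- r / (1 + r2)                # norm scale factor
  out <- array(V * a, d)
  ag_node(out, list(x), function(g) {
    G <- matrix(g, rest, C)
    dadr <- (1 - r2) / (1 + r2)^2
    GV <- G * V; gv <- .rowSums(GV, nrow(GV), ncol(GV))
    coef <- ifelse(r > 1e-12, dadr / r, 0) * gv
    list(array(G * a + V * coef, d))
  })
}

# layer norm over the last axis, with per-channel gain and bias
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- ag_const(x); gamma <- ag_const(gamma); beta <- ag_const(beta)
  d <- dim(x$value); k <- length(d)
  rest <- prod(d[-k]); C <- d[k]
  X <- matrix(x$value, rest, C)
  mu <- .rowMeans(X, nrow(X), ncol(X))
  xc <- X - mu
  xc2 <- xc * xc; va <- .rowMeans(xc2, nrow(xc2), ncol(xc2))
  inv <- 1 / sqrt(va + eps)
  xh <- xc * inv
  gv <- as.vector(gamma$value); bv <- as.vector(beta$value)
  out <- array(sweep(xh, 2, gv, `*`) + rep(bv, each = rest), d)
  ag_node(out, list(x, gamma, beta), function(g) {
    G <- matrix(g, rest, C)
    dxh <- sweep(G, 2, gv, `*`)
    s1 <- .rowMeans(dxh, nrow(dxh), ncol(dxh))
    dxx <- dxh * xh; s2 <- .rowMeans(dxx, nrow(dxx), ncol(dxx))
    dx <- inv * (dxh - s1 - xh * s2)
    list(array(dx, d),
         array(colSums(G * xh), c(C)),
         array(colSums(G), c(C)))
  })
}

# batch norm over all axes but the last (channel axis) of a 4-D map.
# `state` is an environment carrying running_mean / running_var, updated as a
# side effect in training mode and consumed in eval mode.
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  x <- ag_const(x); gamma <- ag_const(gamma); beta <- ag_const(beta)
  d <- dim(x$value); k <- length(d)
  C <- d[k]; N <- prod(d[-k])
  X <- matrix(x$value, N, C)
  gv <- as.vector(gamma$value); bv <- as.vector(beta$value)
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    va <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var  <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
    xc <- sweep(X, 2, mu)
  }
  inv <- 1 / sqrt(va + eps)
  xh <- sweep(xc, 2, inv, `*`)
  out <- array(sweep(xh, 2, gv, `*`) + rep(bv, each = N), d)
  if (!training) {
    return(ag_node(out, list(x, gamma, beta), function(g) {
      G <- matrix(g, N, C)
      list(array(sweep(G, 2, gv * inv, `*`), d),
           array(colSums(G * xh), c(C)),
           array(colSums(G), c(C)))
    }))
  }
  ag_node(out, list(x, gamma, beta), function(g) {
    G <- matrix(g, N, C)
    dxh <- sweep(G, 2, gv, `*`)
    s1 <- colMeans(dxh)
    s2 <- colMeans(dxh * xh)
    dx <- sweep(dxh - rep(s1, each = N) - sweep(xh, 2, s2, `*`), 2, inv, `*`)
    list(array(dx, d),
         array(colSums(G * xh), c(C)),
         array(colSums(G), c(C)))
  })
}

# gather rows of a (R, H) table by an integer index vector (with repeats);
# backward scatter-adds, so the table can be a learned bias lookup.
ag_gather_rows <- function(table, idx) {
  table <- ag_const(table)
  Tv <- table$value
  out <- Tv[idx, , drop = FALSE]
  ag_node(as.array(out), list(table), function(g) {
    g <- matrix(g, length(idx), ncol(Tv))
    acc <- rowsum(g, group = idx)
    full <- matrix(0, nrow(Tv), ncol(Tv))
    full[as.integer(rownames(acc)), ] <- acc
    list(array(full, dim(Tv)))
  })
}

# mean cross-entropy between rows of `logits` (N, C) and one-hot `onehot`
ag_ce_logits <- function(logits, onehot) {
  logits <- ag_const(logits)
  Y <- ag_value(onehot)
  L <- logits$value
  N <- nrow(L)
  m <- L - L[cbind(seq_len(N), max.col(L, ties.method = "first"))]
  e <- exp(m)
  P <- e / .rowSums(e, nrow(e), ncol(e))
  ce <- -sum(Y * log(pmax(P, 1e-12))) / N
  ag_node(array(ce, c(1L)), list(logits), function(g) {
    list(array(as.vector(g) * (P - Y) / N, dim(L)))
  })
}
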