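# Parameter store, layer helpers and optimizers.
#
# Parameters live in a plain environment keyed by name (numeric arrays).
# A forward pass opens a context (ctx) over the store; ctx_param() wraps each
# array in a tape node exactly once per pass, creating and initializing it on
# first use.  After ag_backward(), gradients are collected by name and handed
# to the optimizer.

#' @keywords internal
ps_new <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$state <- list()   # batch-norm running statistics, keyed by name
  e
}

#' @keywords internal
ctx_new <- function(ps, training = TRUE, dropout = 0) {
  e <- new.env(parent = emptyenv())
  e$ps <- ps
  e$nodes <- list()
  e$training <- training
  e$dropout <- dropout
  e
}

.ag_init <- function(dims, init, fan_in = NULL, fan_out = NULL) {
  switch(init,
    zeros = array(0, dims),
    ones  = array(1, dims),
    xavier = {
      if (is.null(fan_in)) { fan_in <- dims[1]; fan_out <- dims[length(dims)] }
      lim <- sqrt(6 / (fan_in + fan_out))
      array(stats::runif(prod(dims), -lim, lim), dims)
    },
    normal = array(stats::rnorm(prod(dims), 0, 0.02), dims),
    stop("unknown init: ", init))
}

#' @keywords internal
ctx_param <- function(ctx, name, dims, init = "xavier",
                      fan_in = NULL, fan_out = NULL) {
  nd <- ctx$nodes[[name]]
  if (!is.null(nd)) return(nd)
  p <- ctx$ps$params[[name]]
  if (is.null(p)) {
    p <- .ag_init(dims, init, fan_in, fan_out)
    ctx$ps$params[[name]] <- p
  }
  nd <- ag_node(p)
  ctx$nodes[[name]] <- nd
  nd
}

#' @keywords internal
ctx_bn_state <- function(ctx, name, C) {
  st <- ctx$ps$state[[name]]
  if (is.null(st)) {
    st <- new.env(parent = emptyenv())
    st$running_mean <- rep(0, C)
    st$running_var <- rep(1, C)
    ctx$ps$state[[name]] <- st
  }
  st
}

#' @keywords internal
ctx_grads <- function(ctx) {
  out <- list()
  for (nm in names(ctx$nodes)) {
    g <- ctx$nodes[[nm]]$grad
    if (is.null(g)) g <- array(0, dim(ctx$nodes[[nm]]$value))
    out[[nm]] <- g
  }
  out
}

# ---- layers --------------------------------------------------------------

# affine map over the last axis of x
nn_linear <- function(ctx, x, name, d_in, d_out, bias = TRUE, init = "xavier") {
  W <- ctx_param(ctx, paste0(name, ".W"), c(d_in, d_out), init,
                 fan_in = d_in, fan_out = d_out)
  d <- dim(ag_value(x))
  k <- length(d)
  stopifnot(d[k] == d_in)
  rest <- prod(d[-k])
  xm <- ag_reshape(x, c(rest, d_in))
  y <- ag_matmul(xm, W)
  if (bias) {
    b <- ctx_param(ctx, paste0(name, ".b"), c(d_out), "zeros")
    y <- ag_add(y, b)
  }
  ag_reshape(y, c(d[-k], d_out))
}

nn_dropout <- function(ctx, x, rate = NULL) {
  if (is.null(rate)) rate <- ctx$dropout
  if (!ctx$training || rate <= 0) return(x)
  keep <- 1 - rate
  d <- dim(ag_value(x))
  mask <- array(stats::rbinom(prod(d), 1L, keep) / keep, d)
  ag_mul(x, ag_node(mask))
}

nn_mlp <- function(ctx, x, name, dim, hidden) {
  h <- ag_gelu(nn_linear(ctx, x, paste0(name, ".fc1"), dim, hidden))
  h <- nn_dropout(ctx, h)
  y <- nn_linear(ctx, h, paste0(name, ".fc2"), hidden, dim)
  nn_dropout(ctx, y)
}

nn_layernorm <- function(ctx, x, name, C) {
  g <- ctx_param(ctx, paste0(name, ".g"), c(C), "ones")
  b <- ctx_param(ctx, paste0(name, ".b"), c(C), "zeros")
  ag_layernorm(x, g, b)
}

nn_batchnorm <- function(ctx, x, name, C) {
  g <- ctx_param(ctx, paste0(name, ".g"), c(C), "ones")
  b <- ctx_param(ctx, paste0(name, ".b"), c(C), "zeros")
  st <- ctx_bn_state(ctx, name, C)
  ag_batchnorm(x, g, b, st, training = ctx$training)
}

# ---- optimizers ----------------------------------------------------------

#' @keywords internal
optimizer_new <- function(kind = c("adam", "sgd"), lr = 1e-3,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          momentum = 0.02, clip = 1) {
  kind <- match.arg(kind)
  e <- new.env(parent = emptyenv())
  e$kind <- kind; e$lr <- lr
  e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$momentum <- momentum; e$clip <- clip
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

#' @keywords internal
optimizer_step <- function(opt, ps, grads) {
  opt$t <- opt$t + 1L
  if (!is.null(opt$clip) && is.finite(opt$clip)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
    if (gn > opt$clip)
      grads <- lapply(grads, function(g) g * (opt$clip / gn))
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    p <- ps$params[[nm]]
    if (opt$kind == "adam") {
      m <- opt$m[[nm]]; v <- opt$v[[nm]]
      if (is.null(m)) {
        m <- array(0, dim(p)); v <- array(0, dim(p))
        opt$m[[nm]] <- m; opt$v[[nm]] <- v
      }
      # m and v are owned by the optimizer and updated in place
      ps$params[[nm]] <- adam_update(p, m, v, g, opt$lr, opt$beta1,
                                     opt$beta2, opt$eps,
                                     1 - opt$beta1^opt$t,
                                     1 - opt$beta2^opt$t)
    } else {
      m <- opt$m[[nm]]
      if (is.null(m)) m <- array(0, dim(p))
      m <- opt$momentum * m + g
      opt$m[[nm]] <- m
      ps$params[[nm]] <- p - opt$lr * m
    }
  }
  invisible(ps)
}
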