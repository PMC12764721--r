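# Extreme Learning Machine head: a single hidden layer with randomly drawn,
# fixed weights and a sigmoid activation; output weights beta solved in
# closed form by ridge-regularized least squares (Moore-Penrose limit as the
# regularization vanishes).  No iterative training.

#' Initialize an ELM model
#'
#' Hidden weights and biases are drawn once from uniform(-1, 1) under `seed`
#' and never updated; only the output weights `beta` are fitted (in closed
#' form) by [elm_fit()].
#'
#' @param input_dim length of the input feature vectors.
#' @param L hidden neuron count (>= 1).
#' @param seed integer seed for the random hidden layer.
#' @param n_classes number of output classes.
#' @param C ridge regularization constant (> 0); larger is weaker.
#' @return an object of class `elm_model`.
#' @export
elm_init <- function(input_dim, L, seed = 1, n_classes = 2, C = 1e3) {
  if (L < 1 || input_dim < 1)
    stop("elm_init: input_dim and L must be >= 1")
  if (C <= 0) stop("elm_init: C must be > 0")
  rs <- .save_rng()
  on.exit(.restore_rng(rs))
  set.seed(seed)
  structure(list(
    W = matrix(stats::runif(input_dim * L, -1, 1), input_dim, L),
    b = stats::runif(L, -1, 1),
    L = as.integer(L), input_dim = as.integer(input_dim),
    n_classes = as.integer(n_classes), C = C, seed = as.integer(seed),
    beta = NULL, fit_report = NULL), class = "elm_model")
}

#' Hidden-layer activations h(x)
#' @param model an `elm_model`.
#' @param Z feature matrix `(N, input_dim)`.
#' @return `(N, L)` matrix of sigmoid activations.
#' @export
elm_hidden <- function(model, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != model$input_dim)
    stop("elm_hidden: feature dimension ", ncol(Z), " != ", model$input_dim)
  H <- Z %*% model$W + matrix(model$b, nrow(Z), model$L, byrow = TRUE)
  1 / (1 + exp(-H))
}

#' Fit ELM output weights in closed form
#'
#' Solves the ridge-regularized least-squares problem for `beta`: the dual
#' form `beta = H' (I/C + H H')^{-1} O` when `N <= L`, the primal form
#' `beta = (I/C + H' H)^{-1} H' O` otherwise.  As `C -> Inf` both converge
#' to the minimum-norm Moore-Penrose solution `H^+ O`.
#'
#' @param model an `elm_model` from [elm_init()].
#' @param Z training features `(N, input_dim)`.
#' @param labels integer class labels (0-based or factor) or a one-hot
#'   matrix `(N, n_classes)`.
#' @param C optional override of the regularization constant.
#' @param form `"auto"` (default), `"primal"` or `"dual"`.
#' @return the model with `beta` filled in and a `fit_report` holding the
#'   mean squared training residual and a condition estimate of the
#'   regularized Gram matrix.
#' @export
elm_fit <- function(model, Z, labels, C = NULL, form = c("auto", "primal", "dual")) {
  form <- match.arg(form)
  if (!is.null(C)) { if (C <= 0) stop("elm_fit: C must be > 0"); model$C <- C }
  Z <- as.matrix(Z)
  O <- .as_onehot(labels, model$n_classes)
  if (nrow(Z) != nrow(O)) stop("elm_fit: rows of Z and labels disagree")
  H <- elm_hidden(model, Z)
  N <- nrow(H); L <- model$L
  if (form == "auto") form <- if (N <= L) "dual" else "primal"
  if (form == "dual") {
    K <- tcrossprod(H)                       # (N, N)
    A <- diag(N) / model$C + K
    beta <- crossprod(H, solve(A, O))
    cond <- kappa(A, exact = FALSE)
  } else {
    Gm <- crossprod(H)                       # (L, L)
    A <- diag(L) / model$C + Gm
    beta <- solve(A, crossprod(H, O))
    cond <- kappa(A, exact = FALSE)
  }
  model$beta <- beta
  resid <- H %*% beta - O
  model$fit_report <- list(train_error = mean(resid^2),
                           max_residual = max(abs(resid)),
                           condition_estimate = cond, form = form,
                           n_train = N)
  model
}

#' Class probabilities from a fitted ELM
#'
#' @param model fitted `elm_model` (after [elm_fit()]).
#' @param Z feature matrix `(N, input_dim)`.
#' @return `(N, n_classes)` matrix of softmax probabilities; rows sum to 1.
#'   Predicted labels are `max.col(.) - 1`.
#' @export
elm_predict <- function(model, Z) {
  if (is.null(model$beta))
    stop("elm_predict: model has not been fitted; call elm_fit() first")
  S <- elm_hidden(model, Z) %*% model$beta
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Regularized cross-entropy loss
#'
#' Mean negative log-likelihood of one-hot targets under predicted
#' probabilities, plus a ridge penalty `eta * ||theta||^2`.  The mean is
#' taken over samples by default; `normalizer = "feature_length"` divides by
#' `K` (the capsule feature length) instead.
#'
#' @param Y_prob predicted probability matrix `(N, n_classes)`.
#' @param Y one-hot target matrix (or integer labels).
#' @param theta parameter vector entering the ridge penalty (typically beta).
#' @param eta regularization coefficient (>= 0).
#' @param K feature length used when `normalizer = "feature_length"`.
#' @param normalizer `"samples"` or `"feature_length"`.
#' @return scalar loss (>= 0 when `eta >= 0`).
#' @export
elm_loss <- function(Y_prob, Y, theta = 0, eta = 0, K = NULL,
                     normalizer = c("samples", "feature_length")) {
  normalizer <- match.arg(normalizer)
  Y_prob <- as.matrix(Y_prob)
  Y <- .as_onehot(Y, ncol(Y_prob))
  nll <- -sum(Y * log(pmax(Y_prob, 1e-12)))
  den <- if (normalizer == "samples") nrow(Y_prob) else {
    if (is.null(K)) stop("elm_loss: K required for feature_length normalizer")
    K
  }
  nll / den + eta * sum(theta^2)
}

# ---- helpers -------------------------------------------------------------

.as_onehot <- function(labels, n_classes) {
  if (is.matrix(labels)) return(labels)
  lab <- as.integer(labels)
  if (any(lab < 0 | lab >= n_classes))
    stop("labels must be in 0..", n_classes - 1)
  diag(n_classes)[lab + 1L, , drop = FALSE]
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
  invisible(NULL)
}
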