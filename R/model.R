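# Model bundle: U-MST segmenter + capsule feature extractor + softmax head
# used during backprop training, with the ELM fitted afterwards in closed
# form on the frozen capsule features.

#' Assemble a full pipeline model
#'
#' @param umst a [umst_config()].
#' @param caps a [caps_config()].
#' @param n_classes classification classes (2: CG vs DM).
#' @param elm_L hidden neuron count of the ELM head.
#' @param elm_C ELM ridge constant.
#' @param seed seed governing parameter initialization.
#' @return object of class `thermoseg_model`.
#' @export
create_model <- function(umst = umst_config(), caps = caps_config(),
                         n_classes = 2, elm_L = 100, elm_C = 1e3, seed = 1) {
  m <- structure(list(umst = umst, caps = caps,
                      n_classes = as.integer(n_classes),
                      elm_L = as.integer(elm_L), elm_C = elm_C,
                      seed = as.integer(seed),
                      ps = ps_new(), elm = NULL),
                 class = "thermoseg_model")
  # build parameters now so their shapes and init order are fixed
  rs <- .save_rng(); on.exit(.restore_rng(rs))
  set.seed(seed)
  dummy <- array(0, c(1, umst$image_size, umst$image_size, umst$in_channels))
  ctx <- ctx_new(m$ps, training = FALSE)
  invisible(model_forward(ctx, dummy, m))
  m$ps$state <- list()   # discard batch-norm stats touched by the dry run
  m
}

# one forward pass; returns tape nodes
#' @keywords internal
model_forward <- function(ctx, x, model) {
  seg <- nn_umst_forward(ctx, x, model$umst)
  Z <- nn_caps_forward(ctx, seg$bottleneck, model$caps,
                       seg_logits = if (model$caps$use_mask) seg$logits)
  cls <- nn_linear(ctx, Z, "cls.head", model$caps$feature_dim,
                   model$n_classes)
  list(logits = seg$logits, Z = Z, cls_logits = cls)
}

#' Predicted segmentation masks for an image batch
#'
#' @param model a `thermoseg_model`.
#' @param x `(B, H, W, 1)` array (or a single `(H, W)` matrix).
#' @return list with `logits` (`(B, H, W, n_seg_classes)`) and `mask`
#'   (`(B, H, W)` binary array from the channel argmax).
#' @export
predict_segmentation <- function(model, x) {
  x <- .as_batch(x)
  ctx <- ctx_new(model$ps, training = FALSE)
  logits <- ag_value(nn_umst_forward(ctx, x, model$umst)$logits)
  nc <- dim(logits)[4]
  d <- dim(logits)
  mask <- array(0, d[1:3])
  flat <- matrix(logits, prod(d[1:3]), nc)
  mask[] <- (max.col(flat, ties.method = "first") == nc) * 1
  list(logits = logits, mask = mask)
}

#' Capsule feature vectors for an image batch
#'
#' @param model a `thermoseg_model`.
#' @param x image batch.
#' @return `(B, feature_dim)` matrix of frozen capsule features Z.
#' @export
extract_features <- function(model, x) {
  x <- .as_batch(x)
  ctx <- ctx_new(model$ps, training = FALSE)
  matrix(ag_value(model_forward(ctx, x, model)$Z),
         dim(x)[1], model$caps$feature_dim)
}

#' Class probabilities and labels via the fitted ELM head
#'
#' @param model a trained `thermoseg_model` (ELM fitted).
#' @param x image batch.
#' @return list with `prob` (`(B, n_classes)`) and `label` (0 = CG, 1 = DM).
#' @export
predict_classes <- function(model, x) {
  if (is.null(model$elm))
    stop("predict_classes: model has no fitted ELM; train it first")
  Z <- extract_features(model, x)
  prob <- elm_predict(model$elm, Z)
  list(prob = prob, label = max.col(prob) - 1L)
}

.as_batch <- function(x) {
  x <- as.array(x)
  if (length(dim(x)) == 2) dim(x) <- c(1, dim(x), 1)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  x
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding configs, parameter arrays,
#' batch-norm statistics and the ELM head.
#'
#' @param model a `thermoseg_model`.
#' @param path file path.
#' @return `load_checkpoint()` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  st <- lapply(model$ps$state, function(e)
    list(running_mean = e$running_mean, running_var = e$running_var))
  saveRDS(list(umst = model$umst, caps = model$caps,
               n_classes = model$n_classes, elm_L = model$elm_L,
               elm_C = model$elm_C, seed = model$seed,
               params = model$ps$params, state = st, elm = model$elm),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  m <- structure(list(umst = obj$umst, caps = obj$caps,
                      n_classes = obj$n_classes, elm_L = obj$elm_L,
                      elm_C = obj$elm_C, seed = obj$seed,
                      ps = ps_new(), elm = obj$elm),
                 class = "thermoseg_model")
  m$ps$params <- obj$params
  for (nm in names(obj$state)) {
    st <- new.env(parent = emptyenv())
    st$running_mean <- obj$state[[nm]]$running_mean
    st$running_var <- obj$state[[nm]]$running_var
    m$ps$state[[nm]] <- st
  }
  m
}
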