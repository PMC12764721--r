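# Training loop (ADAM, early stopping, combined loss), subject-level
# stratified five-fold cross-validation, and report generation.

#' Training configuration
#'
#' Defaults follow the study protocol: initial learning rate 0.001, up to
#' 289 epochs, batch size 30, ADAM, combined-loss weights alpha = 0.6 /
#' beta = 0.4.  The `momentum_param` is kept as a configuration passthrough
#' (ADAM does not consume it; the SGD fallback does).
#'
#' @param lr initial learning rate.
#' @param epochs_max maximum epoch count.
#' @param batch_size minibatch size.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param momentum_param momentum constant (used by SGD only).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (0 = stop at the first non-improvement).
#' @param min_delta minimum validation-loss improvement that resets patience.
#' @param alpha,beta combined-loss weights (segmentation / classification).
#' @param dropout dropout rate applied inside the block MLPs.
#' @param val_fraction fraction of training subjects held out for early
#'   stopping (at least one subject).
#' @param seed seed for batching, dropout and parameter initialization.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.001, epochs_max = 289, batch_size = 30,
                         optimizer = "adam", momentum_param = 0.02,
                         early_stop_patience = 20, min_delta = 1e-4,
                         alpha = 0.6, beta = 0.4, dropout = 0,
                         val_fraction = 0.1, seed = 1) {
  if (lr <= 0) stop("train_config: lr must be > 0")
  if (batch_size < 1) stop("train_config: batch_size must be >= 1")
  if (alpha < 0 || beta < 0) stop("train_config: alpha, beta must be >= 0")
  structure(list(lr = lr, epochs_max = as.integer(epochs_max),
                 batch_size = as.integer(batch_size),
                 optimizer = match.arg(optimizer, c("adam", "sgd")),
                 momentum_param = momentum_param,
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, alpha = alpha, beta = beta,
                 dropout = dropout, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- folds ---------------------------------------------------------------

#' Stratified subject-level k-fold plan
#'
#' Partitions subjects (not records) into `k` folds, stratified by group so
#' each fold keeps approximately the cohort's DM/CG composition; every
#' subject lands in exactly one test fold.  Records — including augmented
#' copies — follow their subject.
#'
#' @param records list of [thermogram_record()] objects.
#' @param k fold count.
#' @param seed shuffling seed.
#' @return a `fold_plan`: data.frame `assignments` (subject_code, group,
#'   fold) plus `k`.
#' @export
make_folds <- function(records, k = 5, seed = 1) {
  subj <- unique(data.frame(
    subject_code = vapply(records, function(r) r$meta$subject_code, character(1)),
    group = vapply(records, function(r) r$meta$group, character(1)),
    stringsAsFactors = FALSE))
  for (g in unique(subj$group))
    if (sum(subj$group == g) < k)
      stop("make_folds: class ", g, " has fewer than ", k, " subjects")
  rs <- .save_rng(); on.exit(.restore_rng(rs))
  set.seed(seed)
  subj$fold <- NA_integer_
  for (g in unique(subj$group)) {
    idx <- which(subj$group == g)
    idx <- idx[sample.int(length(idx))]
    subj$fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  structure(list(assignments = subj[order(subj$subject_code), ], k = k),
            class = "fold_plan")
}

#' Record indices of the test / train split for one fold
#' @param plan a [make_folds()] plan.
#' @param records the record list the plan was built from (or an augmented
#'   superset of it).
#' @param fold fold index in `1..k`.
#' @return list with integer vectors `train` and `test`.
#' @export
fold_split <- function(plan, records, fold) {
  codes <- vapply(records, function(r) r$meta$subject_code, character(1))
  test_subj <- plan$assignments$subject_code[plan$assignments$fold == fold]
  list(train = which(!codes %in% test_subj),
       test = which(codes %in% test_subj))
}

# ---- training ------------------------------------------------------------

.batch_loss <- function(model, ctx, x, masks, labels, cfg) {
  fw <- model_forward(ctx, x, model)
  seg <- ag_dice_loss(fw$logits, masks)
  if (cfg$beta > 0) {
    Y <- .as_onehot(labels, model$n_classes)
    cls <- ag_ce_logits(fw$cls_logits, Y)
    ag_add(ag_scale(seg, cfg$alpha), ag_scale(cls, cfg$beta))
  } else ag_scale(seg, cfg$alpha)
}

#' Train the pipeline on one training set
#'
#' Backprop phase: ADAM on the combined loss
#' `alpha * Dice + beta * cross-entropy` (the classification term uses a
#' softmax head on the capsule features), with early stopping on the
#' validation loss of a held-out subject split.  Closed-form phase: the ELM
#' is then fitted on the frozen capsule features of the full training set.
#'
#' @param model a [create_model()] bundle.
#' @param records training records.
#' @param cfg a [train_config()].
#' @param quiet suppress per-epoch messages.
#' @return the trained model, with `$history` (epoch, train_loss, val_loss)
#'   and the fitted `$elm`.
#' @export
train_model <- function(model, records, cfg = train_config(), quiet = TRUE) {
  rs <- .save_rng(); on.exit(.restore_rng(rs))
  set.seed(cfg$seed)
  codes <- vapply(records, function(r) r$meta$subject_code, character(1))
  subjects <- unique(codes)
  n_val <- max(1L, round(cfg$val_fraction * length(subjects)))
  if (n_val >= length(subjects))
    stop("train_model: not enough subjects for a validation split")
  val_subj <- sample(subjects, n_val)
  itrain <- which(!codes %in% val_subj)
  ival <- which(codes %in% val_subj)
  xv <- records_to_batch(records[ival])
  mv <- records_to_masks(records[ival])
  lv <- records_labels(records[ival])
  opt <- optimizer_new(cfg$optimizer, lr = cfg$lr,
                       momentum = cfg$momentum_param)
  best <- Inf; best_params <- NULL; best_state <- NULL; wait <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  for (ep in seq_len(cfg$epochs_max)) {
    ord <- itrain[sample.int(length(itrain))]
    tl <- 0; nb <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      ctx <- ctx_new(model$ps, training = TRUE, dropout = cfg$dropout)
      loss <- .batch_loss(model, ctx, records_to_batch(records[bi]),
                          records_to_masks(records[bi]),
                          records_labels(records[bi]), cfg)
      lval <- as.numeric(ag_value(loss))
      if (!is.finite(lval))
        stop(sprintf("train_model: non-finite loss at epoch %d (lr=%g)",
                     ep, cfg$lr))
      ag_backward(loss)
      optimizer_step(opt, model$ps, ctx_grads(ctx))
      tl <- tl + lval; nb <- nb + 1
    }
    vctx <- ctx_new(model$ps, training = FALSE)
    vloss <- as.numeric(ag_value(.batch_loss(model, vctx, xv, mv, lv, cfg)))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / nb,
                                   val_loss = vloss))
    if (!quiet)
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep, tl / nb, vloss))
    if (vloss < best - cfg$min_delta) {
      best <- vloss; wait <- 0L
      best_params <- model$ps$params
      best_state <- lapply(model$ps$state, function(e)
        list(m = e$running_mean, v = e$running_var))
    } else {
      wait <- wait + 1L
      if (wait > cfg$early_stop_patience) break
    }
  }
  if (!is.null(best_params)) {
    model$ps$params <- best_params
    for (nm in names(best_state)) {
      model$ps$state[[nm]]$running_mean <- best_state[[nm]]$m
      model$ps$state[[nm]]$running_var <- best_state[[nm]]$v
    }
  }
  # closed-form ELM on frozen capsule features of the full training set
  Z <- extract_features(model, records_to_batch(records))
  elm <- elm_init(model$caps$feature_dim, model$elm_L,
                  seed = cfg$seed + 7L, n_classes = model$n_classes,
                  C = model$elm_C)
  model$elm <- elm_fit(elm, Z, records_labels(records))
  model$history <- hist
  model
}

# ---- evaluation ----------------------------------------------------------

#' Evaluate a trained model on test records
#'
#' @param model trained `thermoseg_model`.
#' @param records test records (ground-truth masks required for the
#'   segmentation metrics).
#' @return named numeric vector: mean per-record `dsc`, `iou`,
#'   `seg_precision`, `seg_recall`, plus cohort `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluate_model <- function(model, records) {
  x <- records_to_batch(records)
  seg <- predict_segmentation(model, x)
  segm <- sapply(seq_along(records), function(i)
    segmentation_metrics(seg$mask[i, , ],
                         if (is.null(records[[i]]$mask))
                           matrix(0, dim(x)[2], dim(x)[3])
                         else records[[i]]$mask))
  cls <- predict_classes(model, x)
  cm <- classification_metrics(cls$label, records_labels(records))
  c(dsc = mean(segm["dsc", ]), iou = mean(segm["iou", ]),
    seg_precision = mean(segm["precision", ]),
    seg_recall = mean(segm["recall", ]),
    accuracy = unname(cm["accuracy"]), precision = unname(cm["precision"]),
    recall = unname(cm["recall"]), f1 = unname(cm["f1"]))
}

#' Five-fold cross-validation of the full pipeline
#'
#' Trains a fresh model per fold on the other `k - 1` folds (optionally
#' augmenting the training records only) and evaluates on the held-out
#' fold; reports per-fold metrics with their mean and standard deviation.
#'
#' @param records cohort records.
#' @param cfg a [train_config()].
#' @param model_args list of arguments to [create_model()].
#' @param k fold count (5 in the study design).
#' @param aug optional [augment_spec()] applied to training folds only.
#' @param out_dir if set, writes `metrics.csv` and a plain-text log there.
#' @param quiet suppress progress messages.
#' @return a `cv_report`: list with `metrics` (data.frame: one row per fold
#'   + `mean` + `sd`), `plan`, and `models` (per-fold ELM betas for
#'   reproducibility checks).
#' @export
run_cv <- function(records, cfg = train_config(), model_args = list(),
                   k = 5, aug = NULL, out_dir = NULL, quiet = TRUE) {
  plan <- make_folds(records, k = k, seed = cfg$seed)
  rows <- NULL; betas <- vector("list", k)
  for (f in seq_len(k)) {
    sp <- fold_split(plan, records, f)
    train_recs <- records[sp$train]
    if (!is.null(aug)) {
      rs <- .save_rng()
      set.seed(cfg$seed + 1000L + f)
      extra <- unlist(lapply(train_recs, augment, spec = aug,
                             .rng_local = FALSE), recursive = FALSE)
      .restore_rng(rs)
      train_recs <- c(train_recs, extra)
    }
    model <- do.call(create_model,
                     c(model_args, list(seed = cfg$seed + f)))
    fcfg <- cfg; fcfg$seed <- cfg$seed + f
    model <- train_model(model, train_recs, fcfg, quiet = quiet)
    met <- evaluate_model(model, records[sp$test])
    if (!quiet)
      message(sprintf("fold %d: dice %.3f acc %.3f", f, met["dsc"],
                      met["accuracy"]))
    rows <- rbind(rows, met)
    betas[[f]] <- model$elm$beta
  }
  metrics <- as.data.frame(rows)
  metrics <- rbind(metrics, mean = colMeans(metrics),
                   sd = apply(metrics, 2, stats::sd))
  metrics <- cbind(fold = c(seq_len(k), "mean", "sd"), metrics)
  rownames(metrics) <- NULL
  rep <- structure(list(metrics = metrics, plan = plan, betas = betas,
                        seed = cfg$seed), class = "cv_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    writeLines(c(sprintf("[info] seed=%d k=%d n=%d", cfg$seed, k,
                         length(records)),
                 utils::capture.output(print(metrics))),
               file.path(out_dir, "cv.log"))
  }
  rep
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation report (", x$plan$k, "folds )\n")
  print(x$metrics, digits = 3)
  invisible(x)
}

#' Desk-scale cross-validation study
#'
#' The package's reference end-to-end run: a synthetic cohort of 30 DM and
#' 12 CG subjects at 64x64 with the default (high-contrast) generator
#' settings, preprocessed, then five-fold cross-validation of the full
#' U-MST -> capsule -> ELM pipeline with the desk-scale model
#' (embed_dim 16, depths 1/1/1, layer-norm blocks) and training protocol
#' (ADAM, lr 1e-3, batch 4, up to 30 epochs, patience 6).  Every source of
#' randomness derives from `seed`.
#'
#' @param seed integer seed for cohort, folds, initialization and batching.
#' @return a `cv_report` (see [run_cv()]).
#' @export
desk_cv <- function(seed = 1) {
  recs <- generate_cohort(synth_config(n_dm = 30, n_cg = 12,
                                       image_size = 64, seed = seed))
  recs <- lapply(recs, preprocess_record)
  cfg <- train_config(lr = 1e-3, epochs_max = 30, batch_size = 4,
                      early_stop_patience = 6, alpha = 0.6, beta = 0.4,
                      seed = seed)
  run_cv(recs, cfg,
         model_args = list(
           umst = umst_config(image_size = 64, embed_dim = 16,
                              depths = c(1, 1, 1), heads = c(2, 2, 2),
                              norm_kind = "layer_norm"),
           caps = caps_config(primary_dim = 8, n_out = 4, out_dim = 8,
                              feature_dim = 16),
           elm_L = 100),
         k = 5)
}

#' Drop-out stability sweep
#'
#' Retrains (scaled down) at each dropout rate on one train/test split and
#' reports the test accuracy per rate.
#'
#' @param records cohort records.
#' @param rates dropout rates within `[0, 0.9]`.
#' @param cfg a [train_config()] (its `dropout` field is overridden).
#' @param model_args list of arguments to [create_model()].
#' @return data.frame with columns `rate` and `accuracy`.
#' @export
dropout_sweep <- function(records, rates = c(0, 0.25, 0.5),
                          cfg = train_config(), model_args = list()) {
  if (any(rates < 0 | rates > 0.9))
    stop("dropout_sweep: rates must lie in [0, 0.9]")
  plan <- make_folds(records, k = 5, seed = cfg$seed)
  sp <- fold_split(plan, records, 1)
  out <- lapply(rates, function(r) {
    fcfg <- cfg; fcfg$dropout <- r
    model <- do.call(create_model, c(model_args, list(seed = cfg$seed)))
    model <- train_model(model, records[sp$train], fcfg)
    met <- evaluate_model(model, records[sp$test])
    data.frame(rate = r, accuracy = unname(met["accuracy"]))
  })
  do.call(rbind, out)
}
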