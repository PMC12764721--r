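# YAML configuration: one file drives the generator, preprocessing,
# augmentation, model, capsule head, ELM and training harness.

#' Default pipeline configuration
#'
#' Nested list mirroring the YAML layout with blocks `data`, `preprocess`,
#' `augment`, `model`, `caps`, `elm`, `train` and `eval`.  Training defaults
#' follow the study protocol (learning rate 0.001, 289 epochs, batch 30,
#' ADAM, alpha/beta = 0.6/0.4).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    data = list(n_dm = 122, n_cg = 45, image_size = 64,
                lesion_count_range = c(1, 3), lesion_radius_range = c(3, 6),
                lesion_contrast = 0.35, noise_sd = 0.02, seed = 1),
    preprocess = list(enabled = TRUE, k = 3, tiles = 8, clip = 2),
    augment = list(enabled = FALSE, max_translation = 0.1,
                   scale_range = c(0.9, 1.1), max_rotation_deg = 15,
                   copies_per_image = 2, seed = 1),
    model = list(image_size = 64, patch_size = 4, embed_dim = 32,
                 depths = c(1, 1, 1), heads = c(2, 2, 4), window = 4,
                 mlp_ratio = 4, n_seg_classes = 2, norm_kind = "batch_norm",
                 fusion = TRUE),
    caps = list(primary_dim = 8, n_out = 8, out_dim = 16, routing_iters = 3,
                feature_dim = 32, use_mask = FALSE),
    elm = list(L = 100, C = 1e3),
    train = list(lr = 0.001, epochs_max = 289, batch_size = 30,
                 optimizer = "adam", momentum_param = 0.02,
                 early_stop_patience = 20, min_delta = 1e-4, alpha = 0.6,
                 beta = 0.4, dropout = 0, val_fraction = 0.1, seed = 1),
    eval = list(k_folds = 5))
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a YAML configuration, filling unset fields with defaults
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("load_config: file not found: ", path)
    cfg <- .merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Constructors from a configuration list
#'
#' Map the nested configuration onto the typed objects the pipeline
#' consumes.
#'
#' @param cfg nested list from [load_config()].
#' @return the corresponding typed configuration object.
#' @export
config_synth <- function(cfg) do.call(synth_config, cfg$data)

#' @rdname config_synth
#' @export
config_umst <- function(cfg)
  do.call(umst_config, c(cfg$model, list(in_channels = 1)))

#' @rdname config_synth
#' @export
config_caps <- function(cfg) do.call(caps_config, cfg$caps)

#' @rdname config_synth
#' @export
config_train <- function(cfg) do.call(train_config, cfg$train)

#' @rdname config_synth
#' @export
config_augment <- function(cfg) {
  a <- cfg$augment
  a$enabled <- NULL
  do.call(augment_spec, a)
}
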