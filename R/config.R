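# YAML run configuration: defaults mirror the reference training and RPN
# hyperparameter tables; unknown keys are rejected with their full path so
# typos never silently fall back to a default.

#' Default run configuration
#'
#' @return nested list of all configuration sections and defaults
#' @export
default_config <- function() {
  list(
    seed = 42L,
    train = list(input_size = 600L, lr = 1e-4, batch_size = 4L,
                 epochs = 100L, steps = NULL, optimizer = "adam",
                 momentum = 0.9, weight_decay = 5e-4, enhance = TRUE),
    rpn = list(ratios = c(0.5, 1, 2), scales = c(8, 16, 32),
               feat_stride = 16L, nms_iou = 0.7, pre_nms_top_n = 3000L,
               post_nms_top_n = 300L),
    enhance = list(method = "unsharp_mask", k = 1.5, sigma = 2.0,
                   kernel_size = 13L),
    sam = list(groups = 1L, kernel = 7L),
    backbone = list(light = TRUE, stage_blocks = c(3L, 4L, 6L, 3L),
                    stage_mid = c(64L, 128L, 256L, 512L),
                    stem_channels = 64L,
                    sam_stages = c(TRUE, TRUE, TRUE, TRUE)),
    head = list(roi_size = 7L, rpn_channels = 256L),
    eval = list(iou = 0.5, score_thr = 0.5, nms_iou = 0.3),
    synth = list(n_images = 50L, classes = PLANT_CLASSES,
                 n_objects = c(1L, 3L)),
    split = list(ratios = c(0.8, 0.1, 0.1))
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    key <- if (path == "") nm else paste(path, nm, sep = ".")
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ", key)
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]])) {
        stop("configuration key ", key, " expects a section")
      }
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], key)
    } else {
      old <- base[[nm]]
      new <- user[[nm]]
      if (!is.null(old) && is.numeric(old) && !is.numeric(new)) {
        stop("configuration key ", key, " expects a numeric value")
      }
      if (!is.null(old) && is.character(old) && !is.character(new)) {
        stop("configuration key ", key, " expects a character value")
      }
      base[[nm]] <- new
    }
  }
  base
}

#' Parse a run configuration
#'
#' Reads YAML (when `path` is given), applies it over [default_config()],
#' then applies `overrides` on top (overrides win). Unknown keys and type
#' mismatches raise errors naming the offending key path.
#'
#' @param path optional YAML file
#' @param overrides optional nested list of overrides
#' @return resolved configuration list
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- merge_config(cfg, user)
  }
  merge_config(cfg, overrides)
}

config_to_specs <- function(cfg) {
  nst <- length(cfg$backbone$stage_blocks)
  list(
    bspec = backbone_spec(stage_blocks = cfg$backbone$stage_blocks,
                          stage_mid = cfg$backbone$stage_mid,
                          light = cfg$backbone$light,
                          sam_stages = rep(cfg$backbone$sam_stages,
                                           length.out = nst),
                          stem_channels = cfg$backbone$stem_channels,
                          sam_groups = cfg$sam$groups,
                          sam_kernel = cfg$sam$kernel),
    aspec = anchor_spec(ratios = cfg$rpn$ratios, scales = cfg$rpn$scales,
                        feat_stride = cfg$rpn$feat_stride),
    rspec = rpn_spec(nms_iou = cfg$rpn$nms_iou,
                     pre_nms_top_n = cfg$rpn$pre_nms_top_n,
                     post_nms_top_n = cfg$rpn$post_nms_top_n),
    tspec = train_spec(input_size = cfg$train$input_size,
                       lr = cfg$train$lr,
                       batch_size = cfg$train$batch_size,
                       epochs = cfg$train$epochs, steps = cfg$train$steps,
                       momentum = cfg$train$momentum,
                       weight_decay = cfg$train$weight_decay,
                       enhance = cfg$train$enhance,
                       enhance_params = sharpen_params(
                         k = cfg$enhance$k, sigma = cfg$enhance$sigma,
                         kernel_size = cfg$enhance$kernel_size))
  )
}
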