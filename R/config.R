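# Run configuration: a YAML file resolving to seeds, data paths, the model
# stage table, training hyper-parameters, exit policy and quantization spec.
# A run echoes its resolved configuration verbatim into the output directory.

default_run_config <- function() {
  list(
    seed = 1L,
    preset = "tiny",
    data = list(dir = "data", image_size = 64L, n_per_class = 60L,
                scale = NULL, train_fraction = 0.8),
    model = list(),                    # overrides of stage_config fields
    training = list(batch_size = 32L, lr = 4e-3, epochs = 18L,
                    optimizer = "adamw", lr_decay_after = 10L,
                    lr_decay = 0.88, flip_augment = TRUE),
    exit = list(mode = "confidence", thresholds = c(0.6, 0.7, 0.8)),
    quant = list(bitwidth = 8L, momentum = 0.99, epochs = 2L, lr = 5e-4),
    out_dir = "runs"
  )
}

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
      merge_lists(base[[nm]], over[[nm]]) else over[[nm]]
  }
  base
}

#' Load a YAML run configuration
#'
#' Unspecified keys fall back to the desk-scale defaults (width / 8 model,
#' 64 x 64 images, batch 32). `preset: full` selects the full-width stage
#' table with 256 x 256 inputs; `model:` keys override individual
#' [stage_config()] fields. The paper-scale training defaults (batch 128,
#' learning rate 5e-5) apply under `preset: full`.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    cfg <- merge_lists(cfg, yaml::read_yaml(path))
  }
  if (identical(cfg$preset, "full")) {
    cfg$training <- merge_lists(list(batch_size = 128L, lr = 5e-5,
                                     epochs = 100L, optimizer = "adamw",
                                     lr_decay_after = 50L, lr_decay = 0.95,
                                     flip_augment = TRUE),
                                if (!is.null(path)) yaml::read_yaml(path)$training else list())
    cfg$data$image_size <- cfg$data$image_size %||% 256L
  }
  class(cfg) <- "run_config"
  cfg
}

run_stage_config <- function(cfg) {
  base <- if (identical(cfg$preset, "full")) rfc_config_full()
          else rfc_config_tiny()
  over <- cfg$model
  if (length(over)) {
    args <- utils::modifyList(
      list(width_multiplier = 1, num_classes = base$num_classes,
           widths = base$widths, attn_dims = base$attn_dims,
           depths = base$depths, expansion = base$expansion,
           patch = base$patch, head_width = base$head_width,
           input_size = base$input_size, ffn_mult = base$ffn_mult),
      over)
    base <- do.call(stage_config, args)
  }
  base
}

config_hash <- function(cfg) {
  sprintf("%08x", derive_seed(0L, yaml::as.yaml(unclass(cfg))))
}

echo_config <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(file.path(out_dir, "config.yaml"))
}
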