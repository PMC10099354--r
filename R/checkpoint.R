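#' Save a segmentation model
#'
#' Serializes the model with R's native serialization and writes a
#' plain-text sidecar (`<path>.config.txt`) with the architecture,
#' widths, depth, flags and trainable-parameter count, so checkpoints can
#' be audited without loading the weights.
#'
#' @param model A `seg_model`.
#' @param path Output path (e.g. `unet.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(model, path)
  cfg <- model$config
  lines <- c(
    sprintf("arch: %s", cfg$arch),
    sprintf("input_size: %d", cfg$input_size),
    sprintf("in_channels: %d", cfg$in_channels),
    sprintf("base_width: %d", cfg$base_width),
    sprintf("depth: %d", cfg$depth),
    sprintf("bottleneck_width: %s", cfg$bottleneck_width),
    sprintf("deep_supervision: %s", cfg$deep_supervision),
    sprintf("attention_gates: %s", cfg$attention_gates),
    sprintf("seed: %d", cfg$seed),
    sprintf("trainable_parameters: %d", model$parameter_count),
    sprintf("trained: %s", isTRUE(model$trained)))
  writeLines(lines, paste0(path, ".config.txt"))
  invisible(path)
}

#' Load a segmentation model saved by [save_model()]
#'
#' @param path Path to the `.rds` checkpoint.
#' @return A `seg_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "seg_model"))
    stop(path, " does not contain a seg_model")
  model
}
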