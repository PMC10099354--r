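#' Desk-scale end-to-end benchmark on synthetic fundus data
#'
#' Runs the complete pipeline at a reduced scale chosen to finish on one
#' CPU in minutes: generate a seeded synthetic dataset, cut overlapping
#' patches, split 70/10/20, train scaled-down versions of all three
#' architectures (window 64, base width 8), ensemble them, and evaluate
#' pooled Dice on the held-out test patches. The returned scores validate
#' pipeline mechanics on synthetic data; they are not clinical
#' performance figures.
#'
#' @param seed Master seed controlling data generation, the split, weight
#'   initialization and shuffling.
#' @param n_images Number of synthetic images (default 30).
#' @param image_size Image size (default 320 x 320).
#' @param window Patch window (default 64).
#' @param base_width Channel width of the scaled models (default 8).
#' @param epochs Training epochs per member (default 3).
#' @param combine Ensemble combiner, see [seg_ensemble()].
#' @return List with `members` (named list of trained models), `ensemble`,
#'   `dice` (named numeric: per-member and ensemble pooled test Dice),
#'   and the `split` sizes.
#' @export
synthetic_benchmark <- function(seed = 1L, n_images = 30L,
                                image_size = c(320L, 320L), window = 64L,
                                base_width = 8L, epochs = 3L,
                                combine = "mean") {
  seed <- as.integer(seed)
  samples <- generate_dataset(n_images, seed = seed * 1000L,
                              image_size = image_size)
  tcfg <- tiling_config(window = window, overlap = 0.30)
  patches <- make_patch_dataset(samples, tcfg)
  sp <- split_patches(patches, split_spec(seed = seed + 1L))
  depth <- 3L
  cfgs <- list(
    unet = model_config("unet", input_size = window, base_width = base_width,
                        depth = depth, bottleneck_width = 8L * base_width,
                        seed = seed + 11L),
    resnet34_unet = model_config("resnet34_unet", input_size = window,
                                 base_width = base_width, seed = seed + 12L),
    unetpp = model_config("unetpp", input_size = window,
                          base_width = base_width, depth = depth,
                          seed = seed + 13L))
  builders <- list(unet = build_unet, resnet34_unet = build_resnet34_unet,
                   unetpp = build_unetpp)
  members <- list()
  dice <- c()
  for (nm in names(cfgs)) {
    m <- builders[[nm]](cfgs[[nm]])
    m <- train_model(m, sp$train, sp$val,
                     train_config(epochs = epochs, seed = seed + 21L))
    members[[nm]] <- m
    dice[nm] <- .pooled_dice(m, sp$test)
  }
  ens <- seg_ensemble(members$unet, members$resnet34_unet, members$unetpp,
                      combine = combine)
  dice["ensemble"] <- .pooled_dice(ens, sp$test)
  list(members = members, ensemble = ens, dice = dice,
       split = vapply(sp, length, integer(1)))
}
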