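#' Synthetic fundus generator configuration
#'
#' The generator emulates the visual ingredients of a color fundus
#' photograph that matter for microaneurysm segmentation: a circular
#' illuminated field of view on a black frame, a reddish textured
#' background with a radial illumination falloff, darker curvilinear
#' vessel-like structures (smoothed random walks), and small round
#' dark-red microaneurysm blobs with a soft edge whose exact pixel
#' supports are recorded in the ground-truth mask. Microaneurysm
#' diameters default to 5-50 px, matching the rule of thumb that a
#' microaneurysm does not exceed about 50 px at full device resolution.
#'
#' @param seed Integer RNG seed; the whole sample is a deterministic
#'   function of the configuration.
#' @param image_size `(height, width)` in pixels (default 640 x 640; the
#'   2124 x 2056 device resolution is supported but not the default).
#' @param n_mas Number of microaneurysm blobs (>= 0).
#' @param ma_diameter_range `(min, max)` blob diameter in pixels.
#' @param vessel_count Number of vessel-like curves.
#' @param illumination_gradient Relative amplitude in `[0, 1]` of the
#'   radial brightness falloff across the field of view.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise,
#'   in 8-bit intensity units.
#' @return A `synth_config` object.
#' @export
synth_config <- function(seed = 1L, image_size = c(640L, 640L), n_mas = 10L,
                         ma_diameter_range = c(5, 50), vessel_count = 6L,
                         illumination_gradient = 0.3, noise_sigma = 4) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2, all(image_size >= 32),
            n_mas >= 0, length(ma_diameter_range) == 2,
            ma_diameter_range[1] >= 2,
            ma_diameter_range[1] <= ma_diameter_range[2],
            vessel_count >= 0,
            illumination_gradient >= 0, illumination_gradient <= 1,
            noise_sigma >= 0)
  structure(list(seed = as.integer(seed), image_size = image_size,
                 n_mas = as.integer(n_mas),
                 ma_diameter_range = as.numeric(ma_diameter_range),
                 vessel_count = as.integer(vessel_count),
                 illumination_gradient = illumination_gradient,
                 noise_sigma = noise_sigma),
            class = "synth_config")
}

# bilinear upscale of a coarse matrix to (h, w) -- low-frequency texture
.upscale <- function(m, h, w) {
  ry <- seq(1, nrow(m), length.out = h)
  rx <- seq(1, ncol(m), length.out = w)
  y0 <- pmin(floor(ry), nrow(m) - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), ncol(m) - 1L); fx <- rx - x0
  a <- m[y0, x0] * outer(1 - fy, 1 - fx) + m[y0 + 1L, x0] * outer(fy, 1 - fx) +
    m[y0, x0 + 1L] * outer(1 - fy, fx) + m[y0 + 1L, x0 + 1L] * outer(fy, fx)
  a
}

#' Generate one synthetic fundus sample
#'
#' Deterministic for a fixed configuration: the same `synth_config`
#' produces bit-identical image, mask and field-of-view arrays. Blob
#' centers are placed inside the field of view with a margin of at least
#' one diameter from its edge, and blobs are rejected-resampled so their
#' supports do not overlap; if placement fails after bounded retries an
#' error names the constraint.
#'
#' @param config A [synth_config()].
#' @return A `synth_sample`: list with `image` (`H x W x 3`, values in
#'   `[0, 1]` quantized to 8-bit levels), `mask` (logical, TRUE =
#'   microaneurysm pixel) and `fov` (logical, TRUE = inside the circular
#'   field of view), plus the `config`.
#' @export
generate_sample <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  h <- config$image_size[1]; w <- config$image_size[2]
  withr::with_seed(config$seed, {
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    R <- 0.48 * min(h, w)
    dist <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+"))
    fov <- dist <= R

    # reddish textured background with radial illumination falloff
    base <- c(0.72, 0.38, 0.26)
    tex <- .upscale(matrix(stats::rnorm(12 * 12, sd = 0.05), 12, 12), h, w)
    illum <- 1 - config$illumination_gradient * pmin(dist / R, 1)^2
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) img[, , ch] <- base[ch] * illum * (1 + tex)

    # vessels: smoothed random walks stamped as darkened discs
    vessel_shade <- array(0, c(h, w))
    for (v in seq_len(config$vessel_count)) {
      ang <- stats::runif(1, 0, 2 * pi)
      r0 <- stats::runif(1, 0, 0.5 * R)
      py <- cy + r0 * sin(ang); px <- cx + r0 * cos(ang)
      dir <- stats::runif(1, 0, 2 * pi)
      half_w <- stats::runif(1, 1.0, 2.5)
      n_steps <- as.integer(min(h, w))
      for (s in seq_len(n_steps)) {
        dir <- dir + stats::rnorm(1, sd = 0.12)
        py <- py + 2 * sin(dir); px <- px + 2 * cos(dir)
        if (sqrt((py - cy)^2 + (px - cx)^2) > R - 2) break
        yy <- max(1L, floor(py - half_w - 1)):min(h, ceiling(py + half_w + 1))
        xx <- max(1L, floor(px - half_w - 1)):min(w, ceiling(px + half_w + 1))
        dd <- sqrt(outer((yy - py)^2, (xx - px)^2, "+"))
        vessel_shade[yy, xx] <- pmax(vessel_shade[yy, xx],
                                     pmin(pmax(half_w + 0.5 - dd, 0), 1))
      }
    }
    # vessels darken all channels, green/blue slightly more (darker red look)
    img[, , 1] <- img[, , 1] * (1 - 0.35 * vessel_shade)
    img[, , 2] <- img[, , 2] * (1 - 0.55 * vessel_shade)
    img[, , 3] <- img[, , 3] * (1 - 0.55 * vessel_shade)

    # microaneurysms: non-overlapping soft-edged dark-red discs
    mask <- matrix(FALSE, h, w)
    centers <- matrix(numeric(0), 0, 3) # y, x, radius
    max_tries <- 100L
    for (b in seq_len(config$n_mas)) {
      diam <- stats::runif(1, config$ma_diameter_range[1],
                           config$ma_diameter_range[2])
      rad <- diam / 2
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rr <- sqrt(stats::runif(1)) * max(R - diam, 0)
        py <- cy + rr * sin(ang); px <- cx + rr * cos(ang)
        ok <- TRUE
        if (nrow(centers)) {
          dc <- sqrt((centers[, 1] - py)^2 + (centers[, 2] - px)^2)
          ok <- all(dc >= centers[, 3] + rad + 3)
        }
        if (ok) {
          centers <- rbind(centers, c(py, px, rad))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", config$n_mas, " non-overlapping ",
             "microaneurysms of diameter <= ", config$ma_diameter_range[2],
             " inside the field of view after ", max_tries,
             " retries; reduce n_mas or the diameter range")
      yy <- max(1L, floor(py - rad)):min(h, ceiling(py + rad))
      xx <- max(1L, floor(px - rad)):min(w, ceiling(px + rad))
      dd <- sqrt(outer((yy - py)^2, (xx - px)^2, "+"))
      support <- dd <= rad
      mask[yy, xx] <- mask[yy, xx] | support
      # sigmoid radial profile: dark core, soft edge near the rim
      alpha <- 1 / (1 + exp((dd - 0.85 * rad) / (0.06 * rad + 0.2)))
      target <- c(0.34, 0.10, 0.08)
      for (ch in 1:3) {
        img[yy, xx, ch] <- (1 - alpha) * img[yy, xx, ch] + alpha * target[ch]
      }
    }

    # sensor noise, clamp, black frame outside the field of view, quantize
    if (config$noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), sd = config$noise_sigma / 255)
    }
    img <- pmin(pmax(img, 0), 1)
    fov3 <- array(fov, dim(img))
    img[!fov3] <- 0
    img <- round(img * 255) / 255
    structure(list(image = img, mask = mask & fov, fov = fov,
                   config = config),
              class = "synth_sample")
  })
}

#' Generate a seeded synthetic dataset
#'
#' Convenience wrapper producing `n_images` samples whose per-sample seeds
#' are derived from `seed`, with all other settings shared.
#'
#' @param n_images Number of samples.
#' @param seed Base seed; sample i uses `seed + i`.
#' @param ... Passed to [synth_config()] (everything except `seed`).
#' @return List of `synth_sample` objects.
#' @export
generate_dataset <- function(n_images, seed = 1L, ...) {
  lapply(seq_len(n_images), function(i) {
    generate_sample(synth_config(seed = seed + i, ...))
  })
}

#' @export
print.synth_sample <- function(x, ...) {
  cat(sprintf("<synth_sample: %d x %d, %d MA pixels in %d blobs>\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$config$n_mas))
  invisible(x)
}
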