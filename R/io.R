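#' Read a color fundus image
#'
#' Reads PNG, TIFF or JPEG into an `H x W x 3` numeric array with values
#' in `[0, 1]`. Grayscale images are promoted to three identical channels
#' and an alpha channel, if present, is dropped. JPEG input is accepted
#' with a warning, since lossy compression perturbs pixel values.
#'
#' @param path Path to the image file.
#' @return Numeric array `H x W x 3` in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = {
      warning("JPEG is a lossy format; pixel values may differ from the ",
              "original: ", path)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format '", ext, "' for ", path,
         " (PNG, TIFF or JPEG expected)")),
    error = function(e) stop("failed to read image ", path, ": ",
                             conditionMessage(e)))
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- array(img[, , 1L], c(dim(img)[1:2], 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image as 8-bit PNG
#'
#' @param image Numeric array `H x W x 3` in `[0, 1]`.
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Read a binary annotation mask
#'
#' Follows the annotation convention for microaneurysm masks: black
#' pixels (intensity at or below the midpoint) mark microaneurysms, white
#' pixels are background. Color masks are converted to gray by channel
#' mean. If many pixels have intermediate intensities the file does not
#' look binary and a warning summarizes the intensity histogram.
#'
#' @param path Path to the mask image.
#' @return Logical matrix, TRUE = microaneurysm.
#' @export
read_mask <- function(path) {
  img <- suppressWarnings(read_image(path))
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  mid <- 0.5
  frac_mid <- mean(gray > 0.1 & gray < 0.9)
  if (frac_mid > 0.01) {
    h <- table(cut(gray, c(0, 0.1, 0.5, 0.9, 1), include.lowest = TRUE))
    warning("mask ", path, " does not look binary: ",
            round(100 * frac_mid, 1), "% of pixels have intermediate ",
            "intensity (histogram: ",
            paste(names(h), h, sep = "=", collapse = ", "), ")")
  }
  gray <= mid
}

#' Write a binary mask as 8-bit PNG
#'
#' Microaneurysm pixels are written black (0), background white (255), so
#' that `read_mask(write_mask(m, f))` is lossless.
#'
#' @param mask Logical matrix, TRUE = microaneurysm.
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(ifelse(mask, 0, 1), path)
  invisible(path)
}

#' Write a synthetic sample to disk
#'
#' @param sample A `synth_sample` from [generate_sample()].
#' @param image_path,mask_path Output PNG paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_sample <- function(sample, image_path, mask_path) {
  write_image(sample$image, image_path)
  write_mask(sample$mask, mask_path)
  invisible(c(image = image_path, mask = mask_path))
}
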