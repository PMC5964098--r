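#' Micrograph container
#'
#' A 2D grayscale intensity grid with a physical pixel size. Intensities are
#' stored as a numeric matrix (rows x columns); continuous image coordinates
#' put `x` along columns and `y` along rows with the origin at the center of
#' the top-left pixel, so the pixel `intensities[r, c]` is centered at
#' `(x, y) = (c - 1, r - 1)`.
#'
#' @param intensities Numeric matrix of intensities, at least 2 x 2, finite.
#' @param pixel_size Physical pixel size in nm per pixel.
#' @param metadata Optional named list of free-form metadata.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(intensities, pixel_size, metadata = list()) {
  intensities <- as.matrix(intensities)
  stopifnot(is.numeric(intensities),
            nrow(intensities) >= 2, ncol(intensities) >= 2,
            is_scalar_num(pixel_size), pixel_size > 0,
            is.list(metadata))
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  structure(list(intensities = intensities, pixel_size = pixel_size,
                 metadata = metadata),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("Micrograph %d x %d px, %.3g nm/px (%.2f x %.2f um)\n",
              d[1], d[2], x$pixel_size,
              d[2] * x$pixel_size / 1000, d[1] * x$pixel_size / 1000))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
plot.micrograph <- function(x, ...) {
  z <- t(x$intensities)[, nrow(x$intensities):1, drop = FALSE]
  image(z, col = gray(seq(0, 1, length.out = 256)), asp = nrow(x$intensities) /
          ncol(x$intensities), axes = FALSE, ...)
  invisible(x)
}

#' Read a micrograph from a TIFF or PNG file
#'
#' Grayscale 8- or 16-bit images are supported; multi-channel images are
#' averaged to one channel. Image headers do not reliably carry EM pixel
#' sizes, so the physical calibration must be supplied by the caller.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size Pixel size in nm per pixel.
#' @return A [micrograph()] with intensities in `[0, 1]`.
#' @export
read_micrograph <- function(path, pixel_size) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '.", ext, "' (use TIFF or PNG)"))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  micrograph(img, pixel_size, metadata = list(source = path))
}

#' Write a micrograph to a TIFF or PNG file
#'
#' Intensities are rescaled to `[0, 1]` and written as 16-bit grayscale TIFF
#' or 8-bit grayscale PNG depending on the file extension.
#'
#' @param m A [micrograph()].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(m, path) {
  stopifnot(inherits(m, "micrograph"))
  z <- m$intensities
  rng <- range(z)
  z <- if (diff(rng) > 0) (z - rng[1]) / diff(rng) else z * 0
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(z, path, bits.per.sample = 16),
    png = png::writePNG(z, path),
    stop("unsupported image format '.", ext, "' (use TIFF or PNG)"))
  invisible(path)
}

#' Invert the contrast of a micrograph
#'
#' Maps each intensity `v` to `max + min - v`, the affine reflection that
#' turns the dark negative-stain silhouette into a bright object while
#' preserving the histogram shape and the pixel size. Applying it twice
#' returns the original image exactly.
#'
#' @param m A [micrograph()].
#' @return The contrast-inverted [micrograph()].
#' @export
invert_contrast <- function(m) {
  stopifnot(inherits(m, "micrograph"))
  z <- m$intensities
  micrograph(max(z) + min(z) - z, m$pixel_size, m$metadata)
}

#' Band-pass filter a micrograph
#'
#' Frequency-domain Gaussian difference filter that attenuates structures
#' smaller than `small_px` and larger than `large_px` (including the constant
#' background, so the output has approximately zero mean), enhancing the
#' cilium's edge contrast. The two Gaussians use the full-width-half-maximum
#' convention `sigma = size / (2 sqrt(2 log 2))`, and the image is
#' mirror-padded before the FFT to avoid wrap-around artifacts. The filter is
#' linear.
#'
#' @param m A [micrograph()].
#' @param small_px Structures smaller than this (in pixels) are attenuated.
#' @param large_px Structures larger than this (in pixels) are attenuated.
#' @return The filtered [micrograph()] (pixel size preserved).
#' @export
bandpass_filter <- function(m, small_px = 3, large_px = 40) {
  stopifnot(inherits(m, "micrograph"),
            is_scalar_num(small_px), is_scalar_num(large_px), small_px > 0)
  if (small_px >= large_px) stop("small_px must be < large_px")
  z <- m$intensities
  nr <- nrow(z); nc <- ncol(z)
  zp <- rbind(cbind(z, z[, nc:1]), cbind(z[nr:1, ], z[nr:1, nc:1]))
  np_r <- 2 * nr; np_c <- 2 * nc
  # spatial frequencies in cycles per pixel
  fr <- c(0:(np_r %/% 2), -((np_r - np_r %/% 2 - 1):1)) / np_r
  fc <- c(0:(np_c %/% 2), -((np_c - np_c %/% 2 - 1):1)) / np_c
  f2 <- outer(fr^2, fc^2, `+`)
  s_small <- small_px / (2 * sqrt(2 * log(2)))
  s_large <- large_px / (2 * sqrt(2 * log(2)))
  H <- exp(-2 * pi^2 * s_small^2 * f2) - exp(-2 * pi^2 * s_large^2 * f2)
  out <- Re(fft(fft(zp) * H, inverse = TRUE)) / (np_r * np_c)
  micrograph(out[seq_len(nr), seq_len(nc), drop = FALSE],
             m$pixel_size, m$metadata)
}
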