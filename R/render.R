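#' Rendering specification for synthetic micrographs
#'
#' Controls how a [cilium_geometry()] is rasterized into a negative-stain
#' style micrograph: the filament is drawn darker than the background (stain
#' convention), with optional additive Gaussian noise and a linear background
#' gradient.
#'
#' @param pixel_size nm per pixel.
#' @param image_shape `(rows, cols)` of the rendered image.
#' @param background_level Background intensity.
#' @param filament_level Filament intensity; must be below
#'   `background_level`.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param gradient_amplitude Peak-to-peak amplitude of a left-to-right linear
#'   background gradient.
#' @param seed Integer RNG seed for the noise.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(pixel_size = 2, image_shape = c(512, 2048),
                        background_level = 0.8, filament_level = 0.3,
                        noise_sd = 0, gradient_amplitude = 0, seed = 1L) {
  stopifnot(is_scalar_num(pixel_size), pixel_size > 0,
            length(image_shape) == 2, all(image_shape >= 2),
            is_scalar_num(background_level), is_scalar_num(filament_level),
            is_scalar_num(noise_sd), noise_sd >= 0,
            is_scalar_num(gradient_amplitude))
  if (filament_level >= background_level)
    stop("filament_level must be below background_level (negative stain)")
  structure(list(pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 background_level = background_level,
                 filament_level = filament_level, noise_sd = noise_sd,
                 gradient_amplitude = gradient_amplitude,
                 seed = as.integer(seed)),
            class = "render_spec")
}

#' Render a synthetic micrograph of a cilium
#'
#' Rasterizes the geometry as a filled dark band around a smooth centerline:
#' a pixel belongs to the filament when its distance to the centerline is at
#' most the local radius (half the geometry's diameter at the nearest
#' centerline arclength). The centerline runs left to right through the
#' image center, either straight or as a circular arc of the geometry's
#' constant curvature, with the distal tip on the left. An elliptical bulge
#' of the flagellar tip complex is drawn at the distal end when the geometry
#' specifies one. Anti-aliasing is deliberately off so band widths are
#' countable in pixels. Additive noise and the linear background gradient
#' are applied afterwards.
#'
#' @param geometry A [cilium_geometry()].
#' @param spec A [render_spec()].
#' @return A list with components `micrograph` (the rendered [micrograph()]),
#'   `polyline` (the exact centerline used, as a [polyline()] from the distal
#'   tip), and `profile` (the ground-truth [diameter_profile()] sampled every
#'   pixel).
#' @export
render_micrograph <- function(geometry, spec = render_spec()) {
  stopifnot(inherits(geometry, "cilium_geometry"),
            inherits(spec, "render_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  px <- spec$pixel_size
  len_px <- geometry$total_length / px
  margin <- 8 + max(geometry$full_diameter, geometry$ftc_bulge_diameter) /
    (2 * px)
  x0 <- margin                       # distal tip x, px
  yc <- (nr - 1) / 2 + 0.25          # off half-integers: countable widths
  kappa_px <- geometry$centerline_curvature * px

  # centerline in pixel coordinates, arclength s_px from the distal tip
  if (kappa_px == 0) {
    if (x0 + len_px > nc - 1 - margin)
      stop("cilium does not fit inside the image at this pixel size")
    center_xy <- function(s_px) cbind(x0 + s_px, yc)
    # pixel -> (arclength along centerline, distance to centerline), px
    pix_s <- function(X, Y) X - x0
    pix_d <- function(X, Y) abs(Y - yc)
  } else {
    R <- 1 / abs(kappa_px)
    # arc center below the start point; arc sweeps left-to-right
    cx <- x0; cy <- yc + R
    phi <- function(s_px) -pi / 2 + s_px / R
    center_xy <- function(s_px)
      cbind(cx + R * sin(s_px / R), cy - R * cos(s_px / R))
    end <- center_xy(len_px)
    if (max(end[, 1], x0) > nc - 1 - margin || len_px / R > pi / 2)
      stop("cilium does not fit inside the image at this pixel size")
    pix_s <- function(X, Y) {
      ang <- atan2(X - cx, cy - Y)       # 0 at the tip, increases with s
      ang * R
    }
    pix_d <- function(X, Y) abs(sqrt((X - cx)^2 + (Y - cy)^2) - R)
  }

  X <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  Y <- matrix(rep(0:(nr - 1), nc), nr, nc)
  S <- pix_s(X, Y)
  D <- pix_d(X, Y)
  radius_px <- diameter_at(geometry, pmin(pmax(S, 0), geometry$total_length) *
                             px) / (2 * px)
  inside <- S >= 0 & S <= len_px & D <= radius_px

  # FTC bulge: filled ellipse around the centerline just behind the tip
  if (geometry$ftc_bulge_diameter > 0) {
    b_px <- geometry$ftc_bulge_diameter / (2 * px)   # across semi-axis
    a_px <- 1.5 * b_px                               # along semi-axis
    inside <- inside | (S >= -a_px & ((S - a_px) / a_px)^2 +
                          (D / b_px)^2 <= 1)
  }

  z <- matrix(spec$background_level, nr, nc)
  z[inside] <- spec$filament_level
  if (spec$gradient_amplitude != 0)
    z <- z + spec$gradient_amplitude * (X / (nc - 1) - 0.5)
  if (spec$noise_sd > 0)
    z <- z + with_seed(spec$seed, rnorm(length(z), 0, spec$noise_sd))

  s_grid <- seq(0, geometry$total_length, by = px)
  cl <- center_xy(s_grid / px)
  list(micrograph = micrograph(z, px,
                               metadata = list(synthetic = TRUE,
                                               seed = spec$seed)),
       polyline = polyline(cl[, 1], cl[, 2]),
       profile = diameter_profile(s_grid, diameter_at(geometry, s_grid)))
}
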