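#' Idealized cilium geometry
#'
#' Describes a cilium as a piecewise-linear diameter function of arclength
#' measured from the absolute distal tip, together with its total length,
#' mature shaft diameter, an optional flagellar-tip-complex (FTC) bulge and
#' an optional constant centerline curvature. Regrowing cilia typically taper
#' from a narrow distal tip (60--75 nm) up to a mature full width of
#' 200--300 nm over a tip region that can span up to about 2 um.
#'
#' @param total_length Total cilium length in nm.
#' @param full_diameter Mature shaft diameter in nm.
#' @param tip_profile Two-column matrix or data frame of breakpoints
#'   `(arclength_nm, diameter_nm)` from the distal tip; arclengths must be
#'   strictly increasing and the diameter at the last breakpoint must equal
#'   `full_diameter`. Beyond the last breakpoint the diameter is constant at
#'   `full_diameter`. Defaults to a uniform cylinder.
#' @param ftc_bulge_diameter Diameter in nm of the elliptical FTC bulge at the
#'   distal end; 0 means no bulge.
#' @param centerline_curvature Constant centerline curvature in 1/nm
#'   (0 = straight).
#' @return An object of class `cilium_geometry`.
#' @examples
#' # 5-degree half-angle cone reaching full width at ~1429 nm
#' g <- cone_cylinder_geometry(half_angle_deg = 5, junction_nm = 1428.8,
#'                             total_length = 2500)
#' diameter_at(g, c(0, 714.4, 1428.8, 2000))
#' @export
cilium_geometry <- function(total_length, full_diameter,
                            tip_profile = NULL,
                            ftc_bulge_diameter = 0,
                            centerline_curvature = 0) {
  stopifnot(is_scalar_num(total_length), total_length > 0,
            is_scalar_num(full_diameter), full_diameter >= 0,
            is_scalar_num(ftc_bulge_diameter), ftc_bulge_diameter >= 0,
            is_scalar_num(centerline_curvature))
  if (is.null(tip_profile)) {
    tip_profile <- cbind(arclength_nm = 0, diameter_nm = full_diameter)
  }
  tip_profile <- as.matrix(tip_profile)
  if (ncol(tip_profile) != 2)
    stop("tip_profile must have two columns (arclength_nm, diameter_nm)")
  colnames(tip_profile) <- c("arclength_nm", "diameter_nm")
  s <- tip_profile[, 1]; d <- tip_profile[, 2]
  if (any(d < 0)) stop("tip_profile diameters must be >= 0")
  if (any(diff(s) <= 0)) stop("tip_profile arclengths must be strictly increasing")
  if (abs(d[length(d)] - full_diameter) > 1e-9)
    stop("diameter at the last breakpoint must equal full_diameter")
  structure(
    list(total_length = total_length, full_diameter = full_diameter,
         tip_profile = tip_profile, ftc_bulge_diameter = ftc_bulge_diameter,
         centerline_curvature = centerline_curvature),
    class = "cilium_geometry")
}

#' Cone--cylinder test geometry
#'
#' A cilium tapering linearly from `tip_diameter` at the distal tip at a
#' constant half-angle per side up to `full_diameter` at `junction_nm`
#' (computed from the half-angle if omitted), then cylindrical out to
#' `total_length`. The diameter slope over the cone is `2 * tan(half_angle)`.
#'
#' @param half_angle_deg Taper half-angle per side, degrees.
#' @param junction_nm Arclength of the cone--cylinder junction, nm. If `NULL`,
#'   derived from `full_diameter`, `tip_diameter` and the angle.
#' @param total_length Total length, nm.
#' @param full_diameter Shaft diameter, nm. If `junction_nm` is given the
#'   full diameter is derived instead.
#' @param tip_diameter Diameter at the absolute tip, nm.
#' @inheritParams cilium_geometry
#' @return A `cilium_geometry`.
#' @export
cone_cylinder_geometry <- function(half_angle_deg = 5, junction_nm = NULL,
                                   total_length = 2500, full_diameter = 250,
                                   tip_diameter = 0, ftc_bulge_diameter = 0,
                                   centerline_curvature = 0) {
  slope <- 2 * tan(half_angle_deg * pi / 180)
  if (is.null(junction_nm)) {
    junction_nm <- (full_diameter - tip_diameter) / slope
  } else {
    full_diameter <- tip_diameter + slope * junction_nm
  }
  if (junction_nm >= total_length)
    stop("junction must lie inside the cilium")
  cilium_geometry(
    total_length, full_diameter,
    tip_profile = cbind(c(0, junction_nm), c(tip_diameter, full_diameter)),
    ftc_bulge_diameter = ftc_bulge_diameter,
    centerline_curvature = centerline_curvature)
}

#' Evaluate the ideal diameter of a geometry at given arclengths
#'
#' Linear interpolation between the tip-profile breakpoints; constant at
#' `full_diameter` beyond the last breakpoint and at the first breakpoint's
#' diameter before the first.
#'
#' @param geometry A `cilium_geometry`.
#' @param arclength_nm Numeric vector of arclengths from the distal tip, nm.
#' @return Numeric vector of diameters in nm.
#' @export
diameter_at <- function(geometry, arclength_nm) {
  stopifnot(inherits(geometry, "cilium_geometry"))
  bp <- geometry$tip_profile
  if (nrow(bp) == 1) return(rep(bp[1, 2], length(arclength_nm)))
  approx(bp[, 1], bp[, 2], xout = arclength_nm, rule = 2)$y
}

#' @export
print.cilium_geometry <- function(x, ...) {
  cat("Cilium geometry\n")
  cat(sprintf("  total length : %.1f nm\n", x$total_length))
  cat(sprintf("  full diameter: %.1f nm\n", x$full_diameter))
  cat(sprintf("  tip breakpoints: %d (last at %.1f nm)\n",
              nrow(x$tip_profile), max(x$tip_profile[, 1])))
  if (x$ftc_bulge_diameter > 0)
    cat(sprintf("  FTC bulge    : %.1f nm\n", x$ftc_bulge_diameter))
  if (x$centerline_curvature != 0)
    cat(sprintf("  curvature    : %g 1/nm\n", x$centerline_curvature))
  invisible(x)
}

#' Sample a noisy diameter profile from an ideal geometry
#'
#' Evaluates the piecewise-linear diameter function on a regular arclength
#' grid `0, step, 2*step, ...` up to the total length and adds independent
#' zero-mean Gaussian noise, truncated at zero (a width cannot be negative).
#' With `noise_sd = 0` the returned diameters are exact. This is the
#' ground-truth profile a perfect width measurement of the geometry would
#' produce.
#'
#' @param geometry A `cilium_geometry`.
#' @param step Arclength sampling interval, nm.
#' @param noise_sd Standard deviation of additive diameter noise, nm.
#' @param seed Integer seed for reproducibility (`NULL` = use current RNG).
#' @return A `diameter_profile` data frame with columns `arclength_nm`,
#'   `diameter_nm`, `flag` (all `"ok"`).
#' @export
make_profile <- function(geometry, step = 25, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(geometry, "cilium_geometry"),
            is_scalar_num(step), step > 0,
            is_scalar_num(noise_sd), noise_sd >= 0)
  if (step >= geometry$total_length) stop("degenerate profile: step >= total length")
  s <- seq(0, geometry$total_length, by = step)
  d <- diameter_at(geometry, s)
  if (noise_sd > 0)
    d <- pmax(0, d + with_seed(seed, rnorm(length(s), 0, noise_sd)))
  diameter_profile(s, d)
}

#' Construct a diameter profile
#'
#' A diameter profile pairs arclength from the absolute distal tip (nm) with
#' the measured cilium width (nm) and a per-point quality flag:
#' `ok`, `no_edge` (no two edge crossings found) or `truncated`
#' (measurement window left the image).
#'
#' @param arclength_nm Strictly increasing arclengths starting at 0, nm.
#' @param diameter_nm Diameters, nm (`NA` allowed where flag is not `ok`).
#' @param flag Character vector of per-point flags.
#' @return A data frame of class `diameter_profile`.
#' @export
diameter_profile <- function(arclength_nm, diameter_nm,
                             flag = rep("ok", length(arclength_nm))) {
  stopifnot(length(arclength_nm) == length(diameter_nm),
            length(flag) == length(arclength_nm))
  if (any(diff(arclength_nm) <= 0))
    stop("arclength_nm must be strictly increasing")
  if (!all(flag %in% c("ok", "no_edge", "truncated")))
    stop("flags must be ok, no_edge or truncated")
  ok <- flag == "ok"
  if (any(ok & (!is.finite(diameter_nm) | diameter_nm < 0)))
    stop("ok points must have finite non-negative diameters")
  structure(
    data.frame(arclength_nm = as.numeric(arclength_nm),
               diameter_nm = as.numeric(diameter_nm),
               flag = as.character(flag),
               stringsAsFactors = FALSE),
    class = c("diameter_profile", "data.frame"))
}
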