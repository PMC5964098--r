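#' Centerline polyline
#'
#' An ordered list of subpixel image coordinates tracing the central axis of
#' a cilium, starting at the absolute distal tip. Coordinates follow the
#' [micrograph()] convention: `x` along columns, `y` along rows, origin at
#' the top-left pixel center.
#'
#' @param x_px,y_px Numeric coordinate vectors (>= 2 points; consecutive
#'   points must be distinct).
#' @return A data frame of class `polyline` with columns `x_px`, `y_px`.
#' @export
polyline <- function(x_px, y_px) {
  stopifnot(is.numeric(x_px), is.numeric(y_px),
            length(x_px) == length(y_px))
  if (length(x_px) < 2) stop("a polyline needs at least 2 points")
  if (!all(is.finite(x_px)) || !all(is.finite(y_px)))
    stop("polyline coordinates must be finite")
  seg <- sqrt(diff(x_px)^2 + diff(y_px)^2)
  if (any(seg == 0)) stop("consecutive polyline points must be distinct")
  structure(data.frame(x_px = as.numeric(x_px), y_px = as.numeric(y_px)),
            class = c("polyline", "data.frame"))
}

# Cumulative arclength along a polyline, px.
polyline_arclength <- function(p) {
  c(0, cumsum(sqrt(diff(p$x_px)^2 + diff(p$y_px)^2)))
}

#' Traced length of a polyline
#'
#' Sum of the segment lengths times the pixel size: the length of the cilium
#' along the drawn axis (not the endpoint chord).
#'
#' @param p A [polyline()].
#' @param pixel_size nm per pixel.
#' @return Length in nm.
#' @export
traced_length <- function(p, pixel_size) {
  stopifnot(inherits(p, "polyline"), is_scalar_num(pixel_size), pixel_size > 0)
  max(polyline_arclength(p)) * pixel_size
}

#' Resample a polyline at uniform arclength steps
#'
#' Places points every `step` nanometers along the polyline by linear
#' interpolation between the drawn vertices, starting at the distal tip
#' (arclength 0). The final point is the last multiple of `step` not
#' exceeding the traced length, so the total arclength is preserved to
#' within one step.
#'
#' @param p A [polyline()].
#' @param step Arclength interval, nm.
#' @param pixel_size nm per pixel.
#' @return A [polyline()] with attribute `arclength_nm`.
#' @export
resample_polyline <- function(p, step, pixel_size) {
  stopifnot(inherits(p, "polyline"), is_scalar_num(step), step > 0,
            is_scalar_num(pixel_size), pixel_size > 0)
  s_px <- polyline_arclength(p)
  total_nm <- max(s_px) * pixel_size
  if (total_nm < step) stop("polyline (", round(total_nm, 2),
                            " nm) is shorter than one step (", step, " nm)")
  s_new <- seq(0, total_nm, by = step) / pixel_size
  out <- polyline(approx(s_px, p$x_px, xout = s_new)$y,
                  approx(s_px, p$y_px, xout = s_new)$y)
  attr(out, "arclength_nm") <- s_new * pixel_size
  out
}

#' Measure a diameter profile along a centerline
#'
#' At each resampled centerline point, image intensity is sampled by
#' bilinear interpolation along the local perpendicular out to
#' `half_window` nm on both sides. The filament core level is estimated from
#' the samples nearest the centerline and the background floor from the 10th
#' percentile of the whole perpendicular window; scanning inward from the two
#' window ends, the outermost crossings of the half-maximum level localize
#' the two edges with subpixel precision, and the diameter is their
#' separation. Points where two edges cannot be found are flagged `no_edge`;
#' points whose window leaves the image are flagged `truncated`. Neither is
#' ever reported as a zero diameter.
#'
#' @param m A [micrograph()], preprocessed so the cilium is bright on a dark
#'   background (see [invert_contrast()] and [bandpass_filter()]); for raw
#'   dark-on-bright images pass `polarity = "dark"`.
#' @param p A [polyline()] drawn from the absolute distal tip.
#' @param half_window Half-width of the perpendicular sampling window, nm.
#' @param step Arclength sampling interval, nm.
#' @param polarity `"bright"` if the filament is brighter than background,
#'   `"dark"` if darker.
#' @return A [diameter_profile()].
#' @export
measure_widths <- function(m, p, half_window = 400, step = 25,
                           polarity = c("bright", "dark")) {
  stopifnot(inherits(m, "micrograph"), inherits(p, "polyline"))
  polarity <- match.arg(polarity)
  z <- m$intensities
  if (polarity == "dark") z <- max(z) + min(z) - z
  nr <- nrow(z); nc <- ncol(z)
  if (any(p$x_px < 0 | p$x_px > nc - 1 | p$y_px < 0 | p$y_px > nr - 1))
    stop("polyline lies outside the image")
  rp <- resample_polyline(p, step, m$pixel_size)
  s_nm <- attr(rp, "arclength_nm")
  n <- nrow(rp)
  # local tangents by central differences on the resampled points
  ip <- pmin(seq_len(n) + 1, n); im <- pmax(seq_len(n) - 1, 1)
  tx <- rp$x_px[ip] - rp$x_px[im]
  ty <- rp$y_px[ip] - rp$y_px[im]
  tl <- sqrt(tx^2 + ty^2)
  nx <- -ty / tl; ny <- tx / tl
  # perpendicular offsets at half-pixel spacing, in px
  hw_px <- half_window / m$pixel_size
  off <- seq(-hw_px, hw_px, by = 0.5)
  X <- outer(rp$x_px, rep(1, length(off))) + outer(nx, off)
  Y <- outer(rp$y_px, rep(1, length(off))) + outer(ny, off)
  inside <- X >= 0 & X <= nc - 1 & Y >= 0 & Y <= nr - 1
  V <- matrix(NA_real_, n, length(off))
  V[inside] <- bilinear_sample(z, X[inside], Y[inside])

  core_half <- max(2, hw_px / 8)
  central <- abs(off) <= core_half
  diam <- rep(NA_real_, n)
  flag <- rep("ok", n)
  for (i in seq_len(n)) {
    v <- V[i, ]
    if (anyNA(v)) { flag[i] <- "truncated"; next }
    bg <- quantile(v, 0.10, names = FALSE)
    # The 90th percentile of the whole window tracks the core plateau for
    # wide filaments (and the edge ridges of a band-passed image); for a
    # narrow tip inside a wide window it collapses to the background, so the
    # same quantile restricted to the samples nearest the centerline is used
    # as a second estimate and the larger of the two is taken.
    core <- max(quantile(v, 0.90, names = FALSE),
                quantile(v[central], 0.90, names = FALSE))
    thr <- (bg + core) / 2
    if (core <= bg + 1e-12 * max(abs(v), 1)) { flag[i] <- "no_edge"; next }
    above <- v > thr
    # Edges come from above-threshold runs that are wide enough to resolve
    # (>= 3 samples, i.e. >= 1 px) and that actually reach near-core level;
    # this rejects sub-resolution blips from noise or the residual ripple of
    # the band-pass filter around its zero mean.
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    qual_level <- bg + 0.75 * (core - bg)
    qual <- which(runs$values & runs$lengths >= 3 &
                    vapply(seq_along(runs$values), function(k)
                      max(v[starts[k]:ends[k]]) >= qual_level, logical(1)))
    if (!length(qual)) { flag[i] <- "no_edge"; next }
    iL <- starts[qual[1]]                # first sample of outermost left run
    iR <- ends[qual[length(qual)]]       # last sample of outermost right run
    if (iL == 1 || iR == length(v)) { flag[i] <- "no_edge"; next }
    xL <- off[iL - 1] + (thr - v[iL - 1]) / (v[iL] - v[iL - 1]) *
      (off[iL] - off[iL - 1])
    xR <- off[iR] + (thr - v[iR]) / (v[iR + 1] - v[iR]) *
      (off[iR + 1] - off[iR])
    if (xR <= xL) { flag[i] <- "no_edge"; next }
    diam[i] <- (xR - xL) * m$pixel_size
  }
  diameter_profile(s_nm, diam, flag)
}

# Bilinear interpolation of matrix z at continuous (x, y) image coordinates
# (x along columns, y along rows, origin at the top-left pixel center).
bilinear_sample <- function(z, x, y) {
  nr <- nrow(z); nc <- ncol(z)
  x0 <- pmin(pmax(floor(x), 0), nc - 2)
  y0 <- pmin(pmax(floor(y), 0), nr - 2)
  dx <- x - x0; dy <- y - y0
  i00 <- y0 + 1 + x0 * nr
  v00 <- z[i00]; v10 <- z[i00 + nr]; v01 <- z[i00 + 1]; v11 <- z[i00 + nr + 1]
  v00 * (1 - dx) * (1 - dy) + v10 * dx * (1 - dy) +
    v01 * (1 - dx) * dy + v11 * dx * dy
}
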