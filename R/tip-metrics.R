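#' Slope cutoff for the tip-region boundary
#'
#' A cilium is considered to have reached its mature full width where the
#' diameter-versus-arclength slope drops below the slope of a cone with the
#' given half-angle on each side, i.e. `2 * tan(half_angle)`. The default
#' 1.5 degrees per side gives 0.052 (to three decimals).
#'
#' @param half_angle_deg Taper half-angle per side, degrees, in `[0, 90)`.
#' @return Dimensionless diameter-per-arclength slope.
#' @examples
#' round(slope_cutoff(1.5), 3)  # 0.052
#' @export
slope_cutoff <- function(half_angle_deg = 1.5) {
  stopifnot(is_scalar_num(half_angle_deg))
  if (half_angle_deg < 0 || half_angle_deg >= 90)
    stop("half_angle_deg must be in [0, 90)")
  2 * tan(half_angle_deg * pi / 180)
}

#' Fit a polynomial to a diameter profile
#'
#' Least-squares polynomial of the given degree (default six) over the
#' points flagged `ok`. The fit is computed on arclength rescaled to
#' `[-1, 1]` for numerical conditioning; coefficients are reported in the
#' original nm basis. Flagged points (`no_edge`, `truncated`) are excluded.
#'
#' @param profile A [diameter_profile()].
#' @param degree Polynomial degree.
#' @return Object of class `profile_fit` with `coefficients` (increasing
#'   powers of arclength in nm), `domain` (first and last ok arclength),
#'   `rms_residual` (nm), `n_ok`, `degree`.
#' @export
fit_profile_poly <- function(profile, degree = 6) {
  stopifnot(inherits(profile, "diameter_profile"), is_count(degree))
  ok <- profile$flag == "ok"
  s <- profile$arclength_nm[ok]; d <- profile$diameter_nm[ok]
  if (length(s) < degree + 1)
    stop("polynomial fit of degree ", degree, " needs at least ",
         degree + 1, " ok points; got ", length(s))
  ctr <- (max(s) + min(s)) / 2
  hw <- (max(s) - min(s)) / 2
  u <- (s - ctr) / hw
  B <- outer(u, 0:degree, `^`)
  qr_fit <- lm.fit(B, d)
  u_coefs <- qr_fit$coefficients
  u_coefs[is.na(u_coefs)] <- 0
  rms <- sqrt(mean(qr_fit$residuals^2))
  structure(
    list(coefficients = poly_rebase(u_coefs, ctr, hw),
         u_coefs = u_coefs, center = ctr, halfwidth = hw,
         domain = c(min(s), max(s)), rms_residual = rms,
         n_ok = length(s), degree = degree),
    class = "profile_fit")
}

# Convert coefficients of p(u), u = (s - ctr)/hw, to powers of s.
poly_rebase <- function(u_coefs, ctr, hw) {
  n <- length(u_coefs)
  out <- rep(0, n)
  # (s - ctr)^k / hw^k expanded binomially
  for (k in seq_along(u_coefs)) {
    kk <- k - 1
    for (j in 0:kk) {
      out[j + 1] <- out[j + 1] +
        u_coefs[k] / hw^kk * choose(kk, j) * (-ctr)^(kk - j)
    }
  }
  names(out) <- paste0("s^", seq_len(n) - 1)
  out
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf(
    "Degree-%d diameter-profile fit over [%.1f, %.1f] nm (%d points)\n",
    x$degree, x$domain[1], x$domain[2], x$n_ok))
  cat(sprintf("  rms residual %.3g nm\n", x$rms_residual))
  invisible(x)
}

#' Predict fitted diameters (or slopes) from a profile fit
#'
#' @param object A `profile_fit`.
#' @param arclength_nm Arclengths inside the fit domain, nm.
#' @param deriv 0 for the fitted diameter, 1 for its analytic slope.
#' @param ... Unused.
#' @return Numeric vector, nm (or dimensionless slope).
#' @export
predict.profile_fit <- function(object, arclength_nm, deriv = 0, ...) {
  if (any(arclength_nm < object$domain[1] - 1e-9 |
          arclength_nm > object$domain[2] + 1e-9))
    stop("evaluation outside the fitted domain")
  u <- (arclength_nm - object$center) / object$halfwidth
  if (deriv == 0) return(poly_eval(object$u_coefs, u))
  if (deriv == 1)
    return(poly_eval(poly_deriv(object$u_coefs), u) / object$halfwidth)
  stop("only deriv 0 or 1 is supported")
}

#' Candidate tip-region boundaries from a fitted profile
#'
#' All arclengths where the fitted slope crosses the cutoff from above as
#' arclength increases away from the distal tip (down-crossings of the
#' analytic derivative polynomial, located by root isolation and reported to
#' 0.1 nm). An empty result is valid: a cylinder has no crossing.
#'
#' @param fit A [fit_profile_poly()] result.
#' @param cutoff Dimensionless slope cutoff, see [slope_cutoff()].
#' @return Sorted numeric vector of arclengths, nm.
#' @export
find_transition_candidates <- function(fit, cutoff = slope_cutoff()) {
  stopifnot(inherits(fit, "profile_fit"), is_scalar_num(cutoff), cutoff > 0)
  dpoly <- poly_deriv(fit$u_coefs) / fit$halfwidth   # slope in nm/nm vs u
  shifted <- dpoly
  shifted[1] <- shifted[1] - cutoff
  u_roots <- poly_real_roots(shifted, lo = -1, hi = 1)
  if (!length(u_roots)) return(numeric(0))
  d2 <- poly_deriv(dpoly)
  down <- poly_eval(d2, u_roots) < 0     # derivative decreasing: from above
  s <- u_roots[down] * fit$halfwidth + fit$center
  round(sort(s), 1)
}

#' Measure the tip-region length of a diameter profile
#'
#' Fits the profile polynomial, finds every down-crossing of the slope
#' cutoff, and selects the tip-region boundary. The default
#' `"last_sustained"` policy takes the largest candidate beyond which the
#' fitted slope stays below the cutoff all the way to the proximal end of
#' the profile, mimicking an operator accepting the transition that agrees
#' with the mature shaft in the micrograph; `"first"` and `"last"` take the
#' distal-most or proximal-most candidate. All candidates are always
#' reported for review, and an explicit `candidate` index overrides the
#' policy.
#'
#' Degenerate profiles are classified by status: a profile whose slope never
#' reaches the cutoff is `no_taper` (tip length 0, e.g. a mature cylinder);
#' one whose slope never falls below it is `all_taper` (tip length = profile
#' length, e.g. a pure cone still growing).
#'
#' @param profile A [diameter_profile()].
#' @param cutoff Slope cutoff, default `slope_cutoff(1.5)`.
#' @param policy `"last_sustained"`, `"first"` or `"last"`.
#' @param degree Polynomial degree for [fit_profile_poly()].
#' @param candidate Optional integer index into the candidate list that
#'   overrides the selection policy (operator adjudication).
#' @return Object of class `tip_measurement`: `tip_length_nm`, `status`
#'   (`ok`, `no_taper`, `all_taper`), `candidates_nm`, `cutoff`, `policy`,
#'   `fit`.
#' @examples
#' pr <- make_profile(cone_cylinder_geometry(5, total_length = 2500), step = 50)
#' tip_length(pr)
#' @export
tip_length <- function(profile, cutoff = slope_cutoff(),
                       policy = c("last_sustained", "first", "last"),
                       degree = 6, candidate = NULL) {
  policy <- match.arg(policy)
  fit <- fit_profile_poly(profile, degree = degree)
  cand <- find_transition_candidates(fit, cutoff)
  grid <- seq(fit$domain[1], fit$domain[2], length.out = 2048)
  slope <- predict(fit, grid, deriv = 1)
  sel <- function(len, status)
    structure(list(tip_length_nm = len, status = status,
                   candidates_nm = cand, cutoff = cutoff, policy = policy,
                   fit = fit),
              class = "tip_measurement")
  if (!is.null(candidate)) {
    if (!is_count(candidate) || candidate > length(cand))
      stop("candidate index must be between 1 and ", length(cand))
    return(sel(cand[candidate], "ok"))
  }
  if (!length(cand)) {
    if (max(slope) < cutoff) return(sel(0, "no_taper"))
    if (slope[length(slope)] >= cutoff)
      return(sel(diff(fit$domain), "all_taper"))
    return(sel(0, "no_taper"))
  }
  chosen <- switch(policy,
    first = cand[1],
    last = cand[length(cand)],
    last_sustained = {
      sustained <- vapply(cand, function(s0) {
        all(slope[grid > s0 + 1] < cutoff)
      }, logical(1))
      if (any(sustained)) max(cand[sustained]) else cand[length(cand)]
    })
  sel(chosen, "ok")
}

#' @export
print.tip_measurement <- function(x, ...) {
  cat(sprintf("Tip-region measurement: %.1f nm [%s]\n",
              x$tip_length_nm, x$status))
  cat(sprintf("  cutoff slope %.4g (%.3g deg/side), policy %s\n",
              x$cutoff, atan(x$cutoff / 2) * 180 / pi, x$policy))
  if (length(x$candidates_nm))
    cat("  candidates (nm):", paste(x$candidates_nm, collapse = ", "), "\n")
  else cat("  no slope-cutoff crossings\n")
  cat(sprintf("  profile fit rms %.3g nm over [%.1f, %.1f] nm\n",
              x$fit$rms_residual, x$fit$domain[1], x$fit$domain[2]))
  invisible(x)
}
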