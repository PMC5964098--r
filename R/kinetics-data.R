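#' Species defaults for regrowth kinetics
#'
#' Ground-truth shape features used by the synthetic generators: the time and
#' value of the tip-region length maximum, the asymptotic mature tip length,
#' and the full-length plateau of the whole cilium. Tetrahymena tip regions
#' peak at 2020 nm at 135 min and settle to 1070 nm with a 6.5 um full-length
#' plateau; Chlamydomonas peaks at 1280 nm at 150 min, settles to 680 nm,
#' with a 10.7 um plateau.
#'
#' @param species `"tetrahymena"` or `"chlamydomonas"`.
#' @return List with `t_max` (min), `L_max` (nm), `L_inf` (nm),
#'   `full_plateau` (nm).
#' @export
species_defaults <- function(species = c("tetrahymena", "chlamydomonas")) {
  switch(match.arg(species),
    tetrahymena   = list(t_max = 135, L_max = 2020, L_inf = 1070,
                         full_plateau = 6500),
    chlamydomonas = list(t_max = 150, L_max = 1280, L_inf = 680,
                         full_plateau = 10700))
}

#' Default regrowth sampling times
#'
#' The regrowth time points (minutes after deciliation) at which cilia are
#' sampled in the default simulated experiments.
#' @return Numeric vector of minutes.
#' @export
default_sampling_times <- function() c(20, 35, 60, 90, 135, 180, 240, 300, 360)

#' Ground truth for a simulated tip-length time course
#'
#' Bundles the shape features of the underlying rational growth curve with the
#' sampling design and noise level of the simulated experiment.
#'
#' @param species_label Free-text label (used for species defaults when the
#'   features are omitted).
#' @param t_max,L_max,L_inf Curve features (min, nm, nm); default to the
#'   species values from [species_defaults()].
#' @param sampling_times Strictly increasing positive times, minutes.
#' @param n_per_time Cilia measured per time point.
#' @param noise_sd Per-cilium length noise sd, nm.
#' @param seed Integer RNG seed.
#' @return A list of class `kinetics_truth`, with the realized
#'   `rational_curve` in `$curve`.
#' @export
kinetics_truth <- function(species_label = "tetrahymena",
                           t_max = NULL, L_max = NULL, L_inf = NULL,
                           sampling_times = default_sampling_times(),
                           n_per_time = 30, noise_sd = 300, seed = 1L) {
  if (is.null(t_max) || is.null(L_max) || is.null(L_inf)) {
    sp <- species_defaults(species_label)
    t_max <- t_max %||% sp$t_max
    L_max <- L_max %||% sp$L_max
    L_inf <- L_inf %||% sp$L_inf
  }
  stopifnot(t_max > 0, L_inf > 0, L_inf < L_max,
            all(sampling_times > 0), all(diff(sampling_times) > 0),
            is_count(n_per_time), noise_sd >= 0)
  structure(
    list(species_label = species_label, t_max = t_max, L_max = L_max,
         L_inf = L_inf, sampling_times = sampling_times,
         n_per_time = n_per_time, noise_sd = noise_sd, seed = seed,
         curve = solve_rational_from_features(t_max, L_max, L_inf)),
    class = "kinetics_truth")
}

#' Kinetics dataset of per-cilium lengths over regrowth time
#'
#' @param records Data frame with columns `cilium_id`, `time_min`,
#'   `length_nm`.
#' @param kind `"tip"` (tip-region lengths) or `"full"` (whole-cilium
#'   lengths).
#' @return A data frame of class `kinetics_dataset` with attribute `kind`.
#' @export
kinetics_dataset <- function(records, kind = c("tip", "full")) {
  kind <- match.arg(kind)
  records <- as.data.frame(records)
  need <- c("cilium_id", "time_min", "length_nm")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  bad <- which(!is.finite(records$time_min) | records$time_min <= 0)
  if (length(bad)) stop("non-positive or missing time at row ", bad[1])
  bad <- which(!is.finite(records$length_nm) | records$length_nm < 0)
  if (length(bad)) stop("negative or missing length at row ", bad[1])
  if (length(unique(records$time_min)) < 2)
    stop("need at least 2 distinct time points")
  structure(records[need], kind = kind,
            class = c("kinetics_dataset", "data.frame"))
}

#' Simulate a tip-region length time course
#'
#' Draws `n_per_time` cilia at each sampling time from the ground-truth
#' rational curve plus zero-mean Gaussian noise, truncated at zero (a
#' measured length cannot be negative).
#'
#' @param truth A [kinetics_truth()] object.
#' @return A `kinetics_dataset` of kind `"tip"`.
#' @examples
#' tk <- make_tip_kinetics(kinetics_truth("tetrahymena", seed = 7))
#' summarize_timepoints(tk)
#' @export
make_tip_kinetics <- function(truth) {
  stopifnot(inherits(truth, "kinetics_truth"))
  times <- rep(truth$sampling_times, each = truth$n_per_time)
  mu <- eval_rational(truth$curve, times)
  len <- with_seed(truth$seed,
                   pmax(0, mu + rnorm(length(times), 0, truth$noise_sd)))
  kinetics_dataset(
    data.frame(cilium_id = sprintf("%s_t%03d_c%02d", truth$species_label,
                                   round(times),
                                   sequence(rep(truth$n_per_time,
                                                length(truth$sampling_times)))),
               time_min = times, length_nm = len),
    kind = "tip")
}

#' Whole-cilium length under the balance-point growth law
#'
#' Solves the balance-point ODE `dL/dt = D (L_inf - L) / L` (assembly rate
#' decreasing with length, constant disassembly) through its closed-form
#' inverse `t(L) = (1/D) (L_inf log(L_inf / (L_inf - L)) - L)`, inverted
#' numerically for each requested time. Lengths grow from 0, are strictly
#' increasing, and stay below the plateau `L_inf` at all finite times.
#'
#' @param t Times, minutes (>= 0).
#' @param L_inf Plateau length, nm.
#' @param D Turnover rate constant, nm/min.
#' @return Lengths in nm.
#' @export
balance_point_length <- function(t, L_inf, D) {
  stopifnot(L_inf > 0, D > 0, all(t >= 0))
  t_of_L <- function(L) (L_inf * log(L_inf / (L_inf - L)) - L) / D
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    hi <- L_inf * (1 - 1e-14)
    if (t_of_L(hi) <= ti) return(hi)
    uniroot(function(L) t_of_L(L) - ti, lower = L_inf * 1e-14, upper = hi,
            tol = .Machine$double.eps^0.75)$root
  }, numeric(1))
}

#' Rate constant reaching a given fraction of the plateau at a given time
#'
#' Convenience inverse of the balance-point closed form: the `D` for which
#' `L(t_at) = frac * L_inf`.
#'
#' @param L_inf Plateau, nm.
#' @param t_at Time, min.
#' @param frac Fraction of plateau reached at `t_at` (default 0.9).
#' @return `D` in nm/min.
#' @export
balance_point_rate <- function(L_inf, t_at, frac = 0.9) {
  stopifnot(L_inf > 0, t_at > 0, frac > 0, frac < 1)
  L_inf * (log(1 / (1 - frac)) - frac) / t_at
}

#' Simulate a whole-cilium length time course
#'
#' Per-cilium lengths drawn around the balance-point growth law with
#' zero-mean Gaussian noise, truncated at zero.
#'
#' @param L_inf Plateau length, nm.
#' @param D Rate constant, nm/min.
#' @param sampling_times Sampling times, minutes.
#' @param n_per_time Cilia per time point.
#' @param noise_sd Length noise sd, nm.
#' @param seed Integer RNG seed.
#' @return A `kinetics_dataset` of kind `"full"`.
#' @export
make_full_kinetics <- function(L_inf, D,
                               sampling_times = default_sampling_times(),
                               n_per_time = 30, noise_sd = 400, seed = 1L) {
  stopifnot(L_inf > 0, D > 0, all(sampling_times > 0),
            is_count(n_per_time), noise_sd >= 0)
  times <- rep(sampling_times, each = n_per_time)
  mu <- balance_point_length(sampling_times, L_inf, D)[
    rep(seq_along(sampling_times), each = n_per_time)]
  len <- if (noise_sd > 0)
    with_seed(seed, pmax(0, mu + rnorm(length(times), 0, noise_sd)))
  else mu
  kinetics_dataset(
    data.frame(cilium_id = sprintf("full_t%03d_c%02d", round(times),
                                   sequence(rep(n_per_time,
                                                length(sampling_times)))),
               time_min = times, length_nm = len),
    kind = "full")
}

#' Per-time-point summary of a kinetics dataset
#'
#' Sample size, mean and sample standard deviation (n - 1 denominator) of
#' length at each time point; times with a single observation get `NA` sd.
#'
#' @param data A `kinetics_dataset` (or data frame with `time_min`,
#'   `length_nm`).
#' @return Data frame with columns `time_min`, `n`, `mean_nm`, `sd_nm`.
#' @export
summarize_timepoints <- function(data) {
  stopifnot(all(c("time_min", "length_nm") %in% names(data)))
  sp <- split(data$length_nm, data$time_min)
  out <- data.frame(
    time_min = as.numeric(names(sp)),
    n = vapply(sp, length, integer(1)),
    mean_nm = vapply(sp, mean, numeric(1)),
    sd_nm = vapply(sp, function(v) if (length(v) > 1) sd(v) else NA_real_,
                   numeric(1)))
  out <- out[order(out$time_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}
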