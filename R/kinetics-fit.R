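#' Fit the rational tip-length growth model
#'
#' Nonlinear least-squares fit of the quotient-of-trinomials curve
#' `L(t) = (a t^3 + b t^2 + c t) / (t^3 + e t^2 + f t + g)` (scale fixed by
#' `d = 1`) to per-cilium tip-region lengths over regrowth time, using the
#' Levenberg--Marquardt algorithm. The denominator coefficients are
#' parameterized on the log scale, which keeps them positive and hence the
#' denominator root-free on the positive axis. Because rational fits are
#' multimodal, the optimizer is started from a deterministic ladder of
#' initializations derived from the empirical time-point means (peak location
#' and height, late-time plateau) via [solve_rational_from_features()], and
#' the best converged objective is kept.
#'
#' @param data A `kinetics_dataset` of kind `"tip"` (or any data frame with
#'   `time_min` and `length_nm`) with at least 7 distinct time points.
#' @param fit_means Fit the per-time mean lengths instead of every per-cilium
#'   record (default `FALSE`: all records are fitted).
#' @param free_shape Also fit the three denominator shape factors instead of
#'   the canonical tail-suppressing closure used by
#'   [solve_rational_from_features()]. With the shape free the horizontal
#'   asymptote is only weakly identified from a finite sampling window and
#'   can drift far from the tail of the data; the canonical closure (default)
#'   identifies it from the post-peak tail.
#' @param horizon Feature-search horizon in minutes; defaults to 10 times the
#'   largest observed time.
#' @param maxiter Maximum Levenberg--Marquardt iterations per start.
#' @return An object of class `rational_growth` with components `curve`
#'   (the fitted [rational_curve()]), `features` ([curve_features()] at the
#'   horizon), `data`, `fitted`, `residuals`, `rss`, `starts` (per-start
#'   diagnostics), `rsstrace` (objective per iteration of the winning start).
#' @seealso [curve_features()], [make_tip_kinetics()]
#' @examples
#' tk <- make_tip_kinetics(kinetics_truth("tetrahymena", seed = 11))
#' fit <- fit_rational(tk)
#' coef(fit)
#' fit$features
#' @export
fit_rational <- function(data, fit_means = FALSE, free_shape = FALSE,
                         horizon = NULL, maxiter = 500) {
  stopifnot(all(c("time_min", "length_nm") %in% names(data)))
  if (!is.null(attr(data, "kind")) && attr(data, "kind") != "tip")
    warning("fitting the tip-length model to a dataset of kind '",
            attr(data, "kind"), "'")
  if (length(unique(data$time_min)) < 7)
    stop("rational fit needs at least 7 distinct time points")
  if (all(data$length_nm == 0))
    stop("degenerate dataset: all lengths are zero")
  sm <- summarize_timepoints(data)
  if (fit_means) {
    t_obs <- sm$time_min; y_obs <- sm$mean_nm
  } else {
    t_obs <- data$time_min; y_obs <- data$length_nm
  }
  horizon <- horizon %||% (10 * max(t_obs))

  # Shape parameterization of the d = 1 family: peak time, peak height,
  # asymptote as a fraction of the peak and, when free_shape = TRUE, the
  # positive denominator shape. Pinning the interior-maximum structure
  # removes the near-flat coefficient ray along which the asymptote a/d is
  # unidentifiable from data on a finite time window; with the canonical
  # denominator closure (default) the asymptote is identified by the height
  # of the post-peak tail inside the window.
  # theta = (log t_max, log L_max, logit(L_inf/L_max)[, log shape[1:3]])
  model_of <- function(theta) {
    shape <- if (free_shape) exp(theta[4:6]) else NULL
    rational_from_constraints(exp(theta[1]), exp(theta[2]),
                              exp(theta[2]) * stats::plogis(theta[3]),
                              shape)
  }
  residual_fn <- function(theta) eval_rational(model_of(theta), t_obs) - y_obs

  starts <- rational_starts(sm, free_shape)
  diag_tab <- data.frame(start = seq_along(starts), rss = NA_real_,
                         iterations = NA_integer_, converged = FALSE,
                         message = NA_character_)
  best <- NULL
  for (i in seq_along(starts)) {
    th0 <- starts[[i]]
    fit <- try(minpack.lm::nls.lm(
      par = th0, fn = residual_fn,
      control = minpack.lm::nls.lm.control(maxiter = maxiter, maxfev = 100000)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      diag_tab$message[i] <- as.character(fit)
      next
    }
    rss <- sum(fit$fvec^2)
    diag_tab$rss[i] <- rss
    diag_tab$iterations[i] <- fit$niter
    diag_tab$converged[i] <- fit$info %in% 1:4
    diag_tab$message[i] <- fit$message
    if (diag_tab$converged[i] && (is.null(best) || rss < best$rss))
      best <- list(rss = rss, fit = fit, start = i)
  }
  if (is.null(best)) {
    stop("no Levenberg-Marquardt start converged; per-start diagnostics:\n",
         paste(utils::capture.output(print(diag_tab)), collapse = "\n"))
  }
  curve <- model_of(best$fit$par)
  # enforce invariants on the accepted solution
  curve <- rational_curve(curve$a, curve$b, curve$c, curve$d,
                          curve$e, curve$f, curve$g, check = TRUE)
  yhat_obs <- eval_rational(curve, t_obs)
  if (max(abs(yhat_obs)) < 1e-6 * max(1, max(y_obs)))
    stop("degenerate fit: curve is numerically zero over the data")
  yhat_all <- eval_rational(curve, data$time_min)
  structure(
    list(curve = curve,
         features = curve_features(curve, horizon = horizon),
         horizon = horizon,
         data = data, fit_means = fit_means,
         fitted = yhat_all, residuals = data$length_nm - yhat_all,
         rss = best$rss,
         sigma = sqrt(best$rss / max(1, length(y_obs) - length(starts[[1]]))),
         n = length(y_obs), starts = diag_tab, chosen_start = best$start,
         free_shape = free_shape,
         rsstrace = best$fit$rsstrace,
         iterations = best$fit$niter),
    class = "rational_growth")
}

# Deterministic initialization ladder from the empirical time-point means.
rational_starts <- function(sm, free_shape = FALSE) {
  i_pk <- which.max(sm$mean_nm)
  t_pk <- sm$time_min[i_pk]
  L_pk <- max(sm$mean_nm[i_pk], 1e-3)
  L_late <- sm$mean_nm[nrow(sm)]
  L_late <- min(max(L_late, 0.2 * L_pk), 0.95 * L_pk)
  grid <- list(
    c(1.00, 1.00, 1.00),
    c(0.75, 1.00, 0.80),
    c(1.30, 1.00, 1.20),
    c(1.00, 1.20, 0.70),
    c(1.00, 0.85, 1.00),
    c(0.60, 1.00, 0.90),
    c(1.00, 1.00, 0.50))
  lapply(grid, function(w) {
    Li <- min(L_late * w[3], 0.95 * L_pk * w[2])
    th <- c(log(t_pk * w[1]), log(L_pk * w[2]),
            stats::qlogis(Li / (L_pk * w[2])))
    if (free_shape) th <- c(th, 0, 0, 0)
    th
  })
}

#' @export
print.rational_growth <- function(x, ...) {
  cat("Rational tip-length growth fit (Levenberg-Marquardt)\n")
  cat(sprintf("  %d observations, %d distinct times%s\n", x$n,
              length(unique(x$data$time_min)),
              if (x$fit_means) " (fitted to time-point means)" else ""))
  cat(sprintf("  RSS %.4g, residual sigma %.4g nm, start %d, %d iterations\n",
              x$rss, x$sigma, x$chosen_start, x$iterations))
  ft <- x$features
  cat(sprintf("  peak %.1f nm at %.1f min; asymptote %.1f nm\n",
              ft$L_max, ft$t_max, ft$L_inf))
  invisible(x)
}

#' @export
coef.rational_growth <- function(object, ...) {
  unlist(object$curve[c("a", "b", "c", "d", "e", "f", "g")])
}

#' @export
predict.rational_growth <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_min
       else if (is.data.frame(newdata)) newdata$time_min else newdata
  eval_rational(object$curve, t)
}

#' @export
residuals.rational_growth <- function(object, ...) object$residuals

#' @export
fitted.rational_growth <- function(object, ...) object$fitted

#' @export
summary.rational_growth <- function(object, ...) {
  out <- list(coefficients = coef(object), features = object$features,
              rss = object$rss, sigma = object$sigma, n = object$n,
              starts = object$starts, by_time = summarize_timepoints(object$data))
  class(out) <- "summary.rational_growth"
  out
}

#' @export
print.summary.rational_growth <- function(x, ...) {
  cat("Rational tip-length growth model\n\nCoefficients (d fixed at 1):\n")
  print(signif(x$coefficients, 6))
  cat("\n"); print(x$features)
  cat(sprintf("\nRSS %.6g on %d observations (sigma %.4g nm)\n",
              x$rss, x$n, x$sigma))
  cat("\nMultistart diagnostics:\n"); print(x$starts)
  invisible(x)
}

#' @export
plot.rational_growth <- function(x, ...) {
  sm <- summarize_timepoints(x$data)
  tg <- seq(0, max(x$data$time_min) * 1.1, length.out = 400)
  plot(sm$time_min, sm$mean_nm,
       xlab = "regrowth time (min)", ylab = "tip-region length (nm)",
       ylim = range(0, sm$mean_nm + ifelse(is.na(sm$sd_nm), 0, sm$sd_nm),
                    x$features$L_max, na.rm = TRUE),
       pch = 19, ...)
  ok <- !is.na(sm$sd_nm)
  arrows(sm$time_min[ok], sm$mean_nm[ok] - sm$sd_nm[ok],
         sm$time_min[ok], sm$mean_nm[ok] + sm$sd_nm[ok],
         angle = 90, code = 3, length = 0.03)
  lines(tg, eval_rational(x$curve, tg), col = "firebrick", lwd = 2)
  abline(h = x$features$L_inf, lty = 3)
  invisible(x)
}

#' @importFrom graphics arrows
#' @export
simulate.rational_growth <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- object$fitted
  with_seed(seed, {
    out <- replicate(nsim,
      pmax(0, mu + rnorm(length(mu), 0, object$sigma)), simplify = FALSE)
    as.data.frame(setNames(out, paste0("sim_", seq_len(nsim))))
  })
}

#' Fit the balance-point whole-cilium growth model
#'
#' Fits the two-parameter balance-point length-control model
#' `dL/dt = D (L_inf - L) / L` to whole-cilium lengths over regrowth time by
#' Levenberg--Marquardt least squares. The model is evaluated through the
#' closed-form inverse of its solution,
#' `t(L) = (1/D) (L_inf log(L_inf/(L_inf - L)) - L)`, inverted numerically at
#' each observation time; the assembly rate falls with length while
#' disassembly is constant, so length rises rapidly at first and plateaus
#' stably at `L_inf`.
#'
#' @param data A `kinetics_dataset` of kind `"full"` (or a data frame with
#'   `time_min`, `length_nm`).
#' @param fit_means Fit per-time means instead of per-cilium records.
#' @param maxiter Maximum LM iterations per start.
#' @return Object of class `balance_point` with `L_inf` (nm), `D` (nm/min),
#'   implied assembly scale `A = D * L_inf`, fitted values and residuals.
#' @examples
#' fk <- make_full_kinetics(L_inf = 6500, D = 75.97, noise_sd = 0)
#' fit <- fit_balance_point(fk)
#' coef(fit)
#' @export
fit_balance_point <- function(data, fit_means = FALSE, maxiter = 500) {
  stopifnot(all(c("time_min", "length_nm") %in% names(data)))
  if (!is.null(attr(data, "kind")) && attr(data, "kind") != "full")
    warning("fitting the full-length model to a dataset of kind '",
            attr(data, "kind"), "'")
  if (all(data$length_nm == 0)) stop("degenerate dataset: all lengths are zero")
  if (fit_means) {
    sm <- summarize_timepoints(data)
    t_obs <- sm$time_min; y_obs <- sm$mean_nm
  } else {
    t_obs <- data$time_min; y_obs <- data$length_nm
  }
  Lmax_obs <- max(y_obs)
  resid_fn <- function(theta)
    balance_point_length(t_obs, exp(theta[1]), exp(theta[2])) - y_obs
  # deterministic starts: plateau slightly above the largest observation,
  # rate set so 90% of plateau is reached at half/0.3x the observed span
  starts <- lapply(c(0.5, 0.3, 1.0), function(w)
    c(log(1.05 * Lmax_obs),
      log(balance_point_rate(1.05 * Lmax_obs, w * max(t_obs)))))
  best <- NULL
  for (th0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = th0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = maxiter, maxfev = 100000)), silent = TRUE)
    if (inherits(fit, "try-error") || !(fit$info %in% 1:4)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(rss = rss, fit = fit)
  }
  if (is.null(best)) stop("balance-point fit did not converge from any start")
  L_inf <- exp(best$fit$par[1]); D <- exp(best$fit$par[2])
  yhat <- balance_point_length(data$time_min, L_inf, D)
  structure(
    list(L_inf = L_inf, D = D, A = D * L_inf,
         data = data, fit_means = fit_means,
         fitted = yhat, residuals = data$length_nm - yhat,
         rss = best$rss,
         sigma = sqrt(best$rss / max(1, length(y_obs) - 2)),
         n = length(y_obs), iterations = best$fit$niter,
         rsstrace = best$fit$rsstrace),
    class = "balance_point")
}

#' @export
print.balance_point <- function(x, ...) {
  cat("Balance-point growth fit: dL/dt = D (L_inf - L) / L\n")
  cat(sprintf("  plateau L_inf = %.1f nm,  D = %.3f nm/min  (A = D L_inf = %.1f nm^2/min)\n",
              x$L_inf, x$D, x$A))
  cat(sprintf("  RSS %.4g on %d observations (sigma %.4g nm)\n",
              x$rss, x$n, x$sigma))
  invisible(x)
}

#' @export
coef.balance_point <- function(object, ...)
  c(L_inf = object$L_inf, D = object$D)

#' @export
predict.balance_point <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_min
       else if (is.data.frame(newdata)) newdata$time_min else newdata
  balance_point_length(t, object$L_inf, object$D)
}

#' @export
residuals.balance_point <- function(object, ...) object$residuals

#' @export
fitted.balance_point <- function(object, ...) object$fitted

#' @export
summary.balance_point <- function(object, ...) {
  cat("Balance-point whole-cilium growth model\n")
  print(object)
  print(summarize_timepoints(object$data))
  invisible(object)
}

#' @export
plot.balance_point <- function(x, ...) {
  sm <- summarize_timepoints(x$data)
  tg <- seq(0, max(x$data$time_min) * 1.1, length.out = 400)
  plot(sm$time_min, sm$mean_nm, pch = 19,
       xlab = "regrowth time (min)", ylab = "cilium length (nm)",
       ylim = range(0, sm$mean_nm, x$L_inf), ...)
  lines(tg, balance_point_length(tg, x$L_inf, x$D), col = "steelblue", lwd = 2)
  abline(h = x$L_inf, lty = 3)
  invisible(x)
}
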