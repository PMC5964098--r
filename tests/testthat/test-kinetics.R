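test_that("summarize_timepoints does the hand arithmetic", {
  d <- kinetics_dataset(
    data.frame(cilium_id = c("a", "b", "c"),
               time_min = c(10, 10, 20), length_nm = c(100, 300, 500)),
    kind = "tip")
  sm <- summarize_timepoints(d)
  expect_equal(sm$time_min, c(10, 20))
  expect_equal(sm$n, c(2L, 1L))
  expect_equal(sm$mean_nm, c(200, 500))
  expect_equal(sm$sd_nm, c(sd(c(100, 300)), NA_real_))
  # constant data: mean is the constant, sd is 0
  dc <- kinetics_dataset(
    data.frame(cilium_id = letters[1:4], time_min = c(5, 5, 9, 9),
               length_nm = rep(700, 4)), kind = "tip")
  smc <- summarize_timepoints(dc)
  expect_equal(smc$mean_nm, c(700, 700))
  expect_equal(smc$sd_nm, c(0, 0))
})

test_that("kinetics_dataset validates its records", {
  expect_error(kinetics_dataset(
    data.frame(cilium_id = "a", time_min = -5, length_nm = 10), "tip"),
    "time")
  expect_error(kinetics_dataset(
    data.frame(cilium_id = c("a", "b"), time_min = c(5, 10),
               length_nm = c(10, -1)), "tip"),
    "row 2")
  expect_error(kinetics_dataset(
    data.frame(cilium_id = c("a", "b"), time_min = c(5, 5),
               length_nm = c(1, 2)), "tip"),
    "distinct")
})

test_that("noiseless rational fits recover the generator features", {
  for (sp in c("tetrahymena", "chlamydomonas")) {
    truth <- kinetics_truth(sp, noise_sd = 0)
    fit <- fit_rational(make_tip_kinetics(truth))
    expect_lt(abs(fit$features$t_max / truth$t_max - 1), 0.005)
    expect_lt(abs(fit$features$L_max / truth$L_max - 1), 0.005)
    expect_lt(abs(fit$features$L_inf / truth$L_inf - 1), 0.005)
    expect_equal(predict(fit, 0), 0)
  }
})

test_that("rational fit rejects degenerate data and small designs", {
  zero <- data.frame(cilium_id = letters[1:8], time_min = seq(10, 80, 10),
                     length_nm = 0)
  expect_error(fit_rational(zero), "all lengths are zero")
  few <- make_tip_kinetics(kinetics_truth(sampling_times = c(20, 60, 120),
                                          noise_sd = 0))
  expect_error(fit_rational(few), "7 distinct")
})

test_that("rational fit exposes honest diagnostics", {
  fit <- fit_rational(make_tip_kinetics(kinetics_truth(seed = 3)))
  expect_s3_class(fit, "rational_growth")
  expect_equal(nrow(fit$starts), 7)
  expect_true(any(fit$starts$converged))
  # LM objective is non-increasing across iterations of the winning start
  expect_true(all(diff(fit$rsstrace) <= 1e-8 * fit$rsstrace[1]))
  # asymptote equals a/d exactly
  expect_identical(fit$features$L_inf,
                   unname(coef(fit)["a"] / coef(fit)["d"]))
  # methods behave
  expect_length(residuals(fit), nrow(fit$data))
  expect_equal(fitted(fit) + residuals(fit), fit$data$length_nm)
  expect_output(print(fit), "asymptote")
  expect_output(print(summary(fit)), "Multistart")
})

test_that("curve_features reports missing features honestly", {
  # monotone-increasing rational curve: no interior maximum
  cv <- rational_curve(a = 1000, b = 500, c = 100, d = 1,
                       e = 100, f = 1000, g = 10000)
  tg <- seq(0.1, 5000, length.out = 2000)
  expect_true(all(diff(predict(cv, tg)) > 0))
  ft <- curve_features(cv, horizon = 5000)
  expect_true(is.na(ft$t_max))
  expect_equal(ft$L_inf, 1000)
})

test_that("rational_curve enforces the denominator invariant", {
  expect_error(rational_curve(1, 1, 1, d = 1, e = -300, f = 100, g = 1000),
               "root")
  expect_error(rational_curve(1, 1, 1, d = 1, e = 1, f = 1, g = 0), "g")
})

test_that("balance-point fits recover generator parameters", {
  # exact recovery from noiseless data
  f0 <- fit_balance_point(make_full_kinetics(6500, 75.97, noise_sd = 0))
  expect_lt(abs(f0$L_inf / 6500 - 1), 0.005)
  expect_lt(abs(f0$D / 75.97 - 1), 0.005)
  # slow-species plateau from a noisy simulation
  D10 <- balance_point_rate(10700, 240)
  f1 <- fit_balance_point(make_full_kinetics(10700, D10, noise_sd = 400,
                                             seed = 2))
  expect_lt(abs(f1$L_inf / 10700 - 1), 0.01)
  # model curve approaches the plateau from below
  tg <- c(10, 100, 1000, 10000)
  expect_true(all(predict(f1, tg) < f1$L_inf))
  expect_gt(predict(f1, 1e6) / f1$L_inf, 0.999)
  expect_output(print(f0), "plateau")
})

test_that("summarize of a noiseless simulation reproduces the truth curve", {
  truth <- kinetics_truth("chlamydomonas", noise_sd = 0)
  sm <- summarize_timepoints(make_tip_kinetics(truth))
  expect_equal(sm$mean_nm, predict(truth$curve, sm$time_min))
})

test_that("tip/full ratio curve has a unique interior peak near t_max", {
  tet <- species_defaults("tetrahymena")
  tip <- solve_rational_from_features(tet$t_max, tet$L_max, tet$L_inf)
  D <- balance_point_rate(tet$full_plateau, 120)
  tg <- seq(5, 720, by = 1)
  ratio <- predict(tip, tg) / balance_point_length(tg, tet$full_plateau, D)
  i <- which.max(ratio)
  expect_gt(i, 1); expect_lt(i, length(tg))       # interior
  expect_lt(abs(tg[i] - tet$t_max), 60)
  # unique: monotone up before, monotone down after (loose structural check)
  expect_true(all(diff(ratio[1:i]) > 0))
  expect_true(all(diff(ratio[i:length(tg)]) < 0))
})
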