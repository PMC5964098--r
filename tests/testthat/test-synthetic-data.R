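test_that("make_profile reproduces piecewise geometry exactly without noise", {
  cyl <- cilium_geometry(1000, 250)
  pr <- make_profile(cyl, step = 50, noise_sd = 0)
  expect_equal(pr$diameter_nm, rep(250, 21))
  expect_equal(pr$arclength_nm, seq(0, 1000, by = 50))

  cone <- cone_cylinder_geometry(5, junction_nm = 1428.8, total_length = 2500)
  pr2 <- make_profile(cone, step = 50, noise_sd = 0)
  on_cone <- pr2$arclength_nm <= 1400
  slopes <- diff(pr2$diameter_nm[on_cone]) / diff(pr2$arclength_nm[on_cone])
  expect_equal(slopes, rep(2 * tan(5 * pi / 180), sum(on_cone) - 1),
               tolerance = 1e-9)
  expect_error(make_profile(cyl, step = 1000), "degenerate")
})

test_that("make_profile noise is seeded and reproducible", {
  g <- cone_cylinder_geometry(5, total_length = 2500)
  a <- make_profile(g, step = 50, noise_sd = 5, seed = 42)
  b <- make_profile(g, step = 50, noise_sd = 5, seed = 42)
  expect_identical(a, b)
  c <- make_profile(g, step = 50, noise_sd = 5, seed = 43)
  expect_false(identical(a$diameter_nm, c$diameter_nm))
})

test_that("cilium_geometry enforces its invariants", {
  expect_error(cilium_geometry(1000, 250,
                               tip_profile = cbind(c(0, 0), c(0, 250))),
               "strictly increasing")
  expect_error(cilium_geometry(1000, 250,
                               tip_profile = cbind(c(0, 500), c(0, 200))),
               "full_diameter")
  expect_error(cilium_geometry(1000, 250,
                               tip_profile = cbind(c(0, 500), c(-5, 250))),
               ">= 0")
})

test_that("rendered cylinder band is exactly as wide as the geometry says", {
  g <- cilium_geometry(2000, 250)
  r <- render_micrograph(g, render_spec(pixel_size = 2,
                                        image_shape = c(256, 1200)))
  z <- r$micrograph$intensities
  # 250 nm at 2 nm/px -> 125 px wide band at every spanned column
  widths <- vapply(300:700, function(cc) sum(z[, cc] < 0.55), numeric(1))
  expect_true(all(abs(widths - 125) <= 1))
  expect_equal(traced_length(r$polyline, 2), 2000, tolerance = 2)
  expect_lt(mean(z[z < 0.55]), mean(z[z >= 0.55]))
})

test_that("render ground truth matches the geometry and errors when too big", {
  g <- fig2_geometry()
  r <- render_fig2()
  expect_equal(max(r$profile$arclength_nm), 3000)
  expect_equal(r$profile$diameter_nm,
               diameter_at(g, r$profile$arclength_nm))
  expect_error(
    render_micrograph(cilium_geometry(10000, 250),
                      render_spec(pixel_size = 2, image_shape = c(128, 256))),
    "fit")
})

test_that("curved centerlines render with the correct traced length", {
  g <- cilium_geometry(2000, 200, centerline_curvature = 1 / 8000)
  r <- render_micrograph(g, render_spec(pixel_size = 2,
                                        image_shape = c(512, 1200)))
  expect_equal(traced_length(r$polyline, 2), 2000, tolerance = 2)
  # band present away from the tip
  expect_gt(sum(r$micrograph$intensities < 0.55), 1000)
})

test_that("solve_rational_from_features hits requested features", {
  for (ft in list(c(135, 2020, 1070), c(150, 1280, 680))) {
    cv <- solve_rational_from_features(ft[1], ft[2], ft[3])
    got <- curve_features(cv, horizon = 30 * ft[1])
    expect_equal(got$t_max, ft[1], tolerance = 1e-6)
    expect_equal(got$L_max, ft[2], tolerance = 1e-6)
    expect_equal(got$L_inf, ft[3], tolerance = 1e-12)
    expect_equal(eval_rational_for_test(cv, 0), 0)
    # positive on the axis, maximum is global
    tg <- seq(1, 50 * ft[1], length.out = 4000)
    expect_true(all(eval_rational_for_test(cv, tg) > 0))
    expect_lt(max(eval_rational_for_test(cv, tg)), ft[2] * (1 + 1e-6))
  }
  expect_error(solve_rational_from_features(135, 1000, 1500), "L_inf")
  expect_error(solve_rational_from_features(135, 1000, 1000), "L_inf")
})

test_that("tip kinetics draws are centered on the truth curve", {
  # exact on the curve without noise
  tr0 <- kinetics_truth("tetrahymena", noise_sd = 0)
  tk0 <- make_tip_kinetics(tr0)
  mu <- summarize_timepoints(tk0)
  expect_equal(mu$mean_nm,
               eval_rational_for_test(tr0$curve, mu$time_min))
  expect_equal(mu$sd_nm, rep(0, nrow(mu)))

  # standard-error bound at default noise across several seeds
  for (s in 1:5) {
    tr <- kinetics_truth("tetrahymena", seed = s)
    sm <- summarize_timepoints(make_tip_kinetics(tr))
    truth <- eval_rational_for_test(tr$curve, sm$time_min)
    expect_true(all(abs(sm$mean_nm - truth) <= 4 * 300 / sqrt(30) +
                      # truncation at zero inflates the earliest time a bit
                      ifelse(sm$time_min <= 20, 30, 0)))
  }
  # at t_max the sample mean sits near L_max
  sm1 <- summarize_timepoints(make_tip_kinetics(kinetics_truth(seed = 7)))
  expect_lt(abs(sm1$mean_nm[sm1$time_min == 135] - 2020), 4 * 300 / sqrt(30))
})

test_that("balance-point closed form and samples behave as the ODE demands", {
  # t(L) inversion: 90% of plateau at 120 min for the reference rate
  expect_equal(balance_point_length(120, 6500, 75.97), 0.9 * 6500,
               tolerance = 1e-3)
  tg <- seq(0, 2000, by = 10)
  L <- balance_point_length(tg, 6500, 75.97)
  expect_true(all(diff(L) > 0))
  expect_true(all(L < 6500))
  # noiseless tables are deterministic regardless of seed
  a <- make_full_kinetics(6500, 75.97, noise_sd = 0, seed = 1)
  b <- make_full_kinetics(6500, 75.97, noise_sd = 0, seed = 999)
  expect_identical(a, b)
  # rate helper is the exact inverse used by the closed form
  D <- balance_point_rate(10700, 240)
  expect_equal(balance_point_length(240, 10700, D) / 10700, 0.9,
               tolerance = 1e-10)
})

test_that("seeded generators are bit-reproducible", {
  t1 <- make_tip_kinetics(kinetics_truth(seed = 5))
  t2 <- make_tip_kinetics(kinetics_truth(seed = 5))
  expect_identical(t1, t2)
  f1 <- make_full_kinetics(6500, 76, seed = 5)
  f2 <- make_full_kinetics(6500, 76, seed = 5)
  expect_identical(f1, f2)
  r1 <- render_fig2(noise_sd = 0.02, seed = 3)
  r2 <- render_fig2(noise_sd = 0.02, seed = 3)
  expect_identical(r1$micrograph$intensities, r2$micrograph$intensities)
})
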