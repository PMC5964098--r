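test_that("slope_cutoff computes 2 tan(half angle)", {
  expect_equal(round(slope_cutoff(1.5), 3), 0.052)
  expect_equal(slope_cutoff(0), 0)
  expect_equal(slope_cutoff(45), 2)
  expect_error(slope_cutoff(-1), "\\[0, 90\\)")
  expect_error(slope_cutoff(90), "\\[0, 90\\)")
})

test_that("fit_profile_poly recovers an exactly representable polynomial", {
  coefs <- c(80, 0.3, -4e-4, 2e-7, -5e-11, 6e-15, -2e-19)
  s <- seq(0, 2400, length.out = 20)
  d <- sapply(s, function(x) sum(coefs * x^(0:6)))
  fit <- fit_profile_poly(diameter_profile(s, d))
  expect_lt(fit$rms_residual, 1e-6)
  expect_equal(predict(fit, s), d, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients), coefs, tolerance = 1e-6)
  # underdetermined: degree + 1 points required
  expect_error(fit_profile_poly(diameter_profile(s[1:6], d[1:6])),
               "at least 7")
})

test_that("fit_profile_poly smooths a cone-cylinder with small residual", {
  pr <- make_profile(cone_cylinder_geometry(5, junction_nm = 1428.8,
                                            total_length = 2500), step = 50)
  fit <- fit_profile_poly(pr)
  expect_lt(fit$rms_residual, 15)
  expect_equal(fit$domain, c(0, 2500))
  # flagged points are excluded from the fit
  pr2 <- pr
  pr2$flag[1:5] <- "no_edge"
  expect_equal(fit_profile_poly(pr2)$domain[1], pr$arclength_nm[6])
})

test_that("transition candidates match an independent dense-grid oracle", {
  cutoff <- slope_cutoff(1.5)
  # cylinder: derivative ~ 0 everywhere, no crossings
  cyl <- make_profile(cilium_geometry(2500, 250), step = 50)
  expect_length(find_transition_candidates(fit_profile_poly(cyl), cutoff), 0)

  # cone-cylinder: exactly one down-crossing, where lm() + dense grid put it
  pr <- make_profile(cone_cylinder_geometry(5, junction_nm = 1428.8,
                                            total_length = 2500), step = 50)
  cand <- find_transition_candidates(fit_profile_poly(pr), cutoff)
  oracle <- oracle_poly_crossings(pr, cutoff)
  expect_length(cand, length(oracle))
  expect_equal(cand, oracle, tolerance = 0.001)
  # the degree-6 smoothing shifts the crossing ~117 nm past the junction
  expect_equal(cand, 1545.3, tolerance = 1e-4)

  # stepped profile (cone, plateau, cone, plateau): two ordered candidates
  g2 <- cilium_geometry(3600, 250,
                        tip_profile = cbind(c(0, 600, 1400, 2200),
                                            c(0, 150, 150, 250)))
  pr2 <- make_profile(g2, step = 25)
  cand2 <- find_transition_candidates(fit_profile_poly(pr2), cutoff)
  oracle2 <- oracle_poly_crossings(pr2, cutoff)
  expect_equal(cand2, oracle2, tolerance = 0.001)
  expect_gte(length(cand2), 2)
  expect_true(!is.unsorted(cand2))
})

test_that("tip_length classifies degenerate morphologies", {
  cyl <- make_profile(cilium_geometry(2500, 250), step = 50)
  tm <- tip_length(cyl)
  expect_equal(tm$tip_length_nm, 0)
  expect_equal(tm$status, "no_taper")

  full <- 2 * tan(5 * pi / 180) * 2000
  cone <- cilium_geometry(2000, full,
                          tip_profile = cbind(c(0, 2000), c(0, full)))
  tm2 <- tip_length(make_profile(cone, step = 50))
  expect_equal(tm2$status, "all_taper")
  expect_equal(tm2$tip_length_nm, 2000)
})

test_that("tip_length selects the sustained candidate and reports all", {
  pr <- make_profile(cone_cylinder_geometry(5, junction_nm = 1428.8,
                                            total_length = 2500), step = 50)
  tm <- tip_length(pr)
  expect_equal(tm$status, "ok")
  expect_true(tm$tip_length_nm %in% tm$candidates_nm)
  expect_equal(tm$tip_length_nm,
               oracle_poly_crossings(pr, slope_cutoff())[1],
               tolerance = 0.001)
  # operator override picks an explicit candidate
  tma <- tip_length(pr, candidate = 1)
  expect_equal(tma$tip_length_nm, tm$candidates_nm[1])
  expect_error(tip_length(pr, candidate = 5), "candidate index")
})

test_that("tip_length scales linearly with the geometry", {
  g <- cone_cylinder_geometry(5, junction_nm = 1000, total_length = 2000)
  base <- tip_length(make_profile(g, step = 25))$tip_length_nm
  for (k in c(0.5, 2, 3)) {
    gk <- cilium_geometry(2000 * k, g$full_diameter * k,
                          tip_profile = g$tip_profile * k)
    tk <- tip_length(make_profile(gk, step = 25 * k))$tip_length_nm
    expect_equal(tk, k * base, tolerance = 0.002)
  }
})

test_that("profile fits refuse evaluation outside their domain", {
  pr <- make_profile(cone_cylinder_geometry(5, total_length = 2500),
                     step = 50)
  fit <- fit_profile_poly(pr)
  expect_error(predict(fit, 3000), "outside")
  expect_error(predict(fit, -5), "outside")
})
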