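# Shared fixture builders. Everything is generated in code; no binary data.

# Fig 2-like regrowing cilium: 2 um tip region tapering 75 -> 250 nm,
# then 1 um of mature shaft.
fig2_geometry <- function(ftc = 0) {
  cilium_geometry(3000, 250, tip_profile = cbind(c(0, 2000), c(75, 250)),
                  ftc_bulge_diameter = ftc)
}

render_fig2 <- function(noise_sd = 0, seed = 1L, pixel_size = 2) {
  render_micrograph(fig2_geometry(),
                    render_spec(pixel_size = pixel_size,
                                image_shape = c(512, 1800),
                                noise_sd = noise_sd, seed = seed))
}

eval_rational_for_test <- function(cv, t) predict(cv, t)

withr_like_tempdir <- function() {
  d <- tempfile("ciliatip_")
  dir.create(d)
  d
}

# Independent profile-fit oracle: R's lm() on an orthogonal polynomial basis
# with the slope-cutoff crossing located on a dense grid.
oracle_poly_crossings <- function(profile, cutoff, degree = 6,
                                  grid_step = 0.05) {
  ok <- profile$flag == "ok"
  df <- data.frame(s = profile$arclength_nm[ok], d = profile$diameter_nm[ok])
  fm <- lm(d ~ poly(s, degree), df)
  sg <- seq(min(df$s), max(df$s), by = grid_step)
  dv <- diff(predict(fm, data.frame(s = sg))) / grid_step
  idx <- which(dv[-1] < cutoff & dv[-length(dv)] >= cutoff)
  sg[idx + 1]
}
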