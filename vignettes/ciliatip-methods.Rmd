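---
title: "Measuring ciliary tip regions and regrowth kinetics with ciliatip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ciliary tip regions and regrowth kinetics with ciliatip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliatip)
```

## The measurement problem

Motile cilia regrowing after deciliation are not uniform cylinders: the
distal end is a tapering, structurally immature *tip region* — microtubule
doublets end at staggered positions, the diameter narrows from the mature
200--300 nm shaft down to 60--75 nm, and a bulge of the flagellar tip
complex (FTC) sometimes caps the very end. In negative-stain electron
micrographs this morphology is visible as a dark silhouette, and the
obvious quantitative question — *how long is the tip region, and how does
that length evolve during regrowth?* — needs an objective, reproducible
boundary definition rather than an operator's eyeball.

`ciliatip` implements that definition end to end:

1. **Preprocessing.** Contrast inversion (`invert_contrast()`, the affine
   reflection `max + min - v`) turns the dark silhouette bright;
   `bandpass_filter()` removes both fine stain texture and slowly varying
   background so that the cilium's edges dominate.
2. **Diameter profiling.** Along an operator-drawn centerline polyline
   (distal tip first), `measure_widths()` samples intensity perpendicular
   to the local axis by bilinear interpolation and localizes the two
   outermost half-maximum edge crossings; their separation, in nm, is the
   local diameter. Points without two resolvable edges are flagged
   `no_edge`; windows leaving the image are `truncated`. Flags are never
   silently converted to zero diameters.
3. **Tip delimitation.** `fit_profile_poly()` fits a degree-six
   least-squares polynomial to the diameter profile; `tip_length()`
   computes its analytic derivative and finds every arclength where the
   slope falls below `slope_cutoff(1.5)` = 2·tan(1.5°) ≈ 0.052 — a cone
   opening 1.5° per side. The boundary between tip region and mature shaft
   is the selected down-crossing; everything distal to it is tip.
4. **Kinetics.** Tip-region length over regrowth time is fitted with a
   rational "quotient of trinomials" curve
   \[
   L(t) = \frac{a t^3 + b t^2 + c t}{d t^3 + e t^2 + f t + g},
   \]
   which starts at zero, rises to an interior maximum, passes an
   inflection and settles at the asymptote \(L_\infty = a/d\)
   (`fit_rational()`, `curve_features()`). Whole-cilium length is fitted
   with the two-parameter balance-point model
   \(dL/dt = D\,(L_\infty - L)/L\) (`fit_balance_point()`), whose solution
   has the closed-form inverse
   \(t(L) = \frac1D\left(L_\infty\ln\frac{L_\infty}{L_\infty-L} - L\right)\).

A synthetic-data generator (`cilium_geometry()`, `render_micrograph()`,
`make_tip_kinetics()`, `make_full_kinetics()`) produces ground-truth
geometries, rendered micrographs and kinetics tables with the statistical
structure the analysis assumes, so every stage is testable without access
to the original micrographs.

## Worked example

```{r pipeline}
rend <- render_micrograph(
  cilium_geometry(3000, 250, tip_profile = cbind(c(0, 2000), c(75, 250))),
  render_spec(pixel_size = 2, image_shape = c(512, 1800),
              noise_sd = 0.02, seed = 1))
prep <- bandpass_filter(invert_contrast(rend$micrograph))
prof <- measure_widths(prep, rend$polyline)
tip_length(prof)
```

The rendered cilium has a 2000 nm tip region by construction; the pipeline
recovers it to within a few percent.

```{r kinetics}
tk <- make_tip_kinetics(kinetics_truth("tetrahymena", seed = 1))
fit <- fit_rational(tk)
fit$features
```

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `half_angle_deg` | 1.5 | degrees/side | boundary definition; `2*tan(1.5°)` rounds to 0.052 |
| `degree` | 6 | — | smoothing polynomial for the profile |
| `step` | 25 | nm | profile sampling interval |
| `half_window` | 400 | nm | perpendicular window; covers 300 nm shafts with margin |
| `small_px`, `large_px` | 3, 40 | px | band-pass limits, FWHM convention |
| `noise_sd` (tip kinetics) | 300 | nm | per-cilium spread of tip lengths |
| `n_per_time` | 30 | cilia | per sampled regrowth time |
| sampling times | 20…360 | min | nine regrowth times |

The printed cutoff value 0.052 corresponds to the 1.5° half-angle; the
package always computes the cutoff from the angle rather than hard-coding
a rounded constant (an alternative printed value, 0.0532, is settable via
`slope_cutoff()`'s argument if an analysis needs to reproduce it).

Band-pass limits are not universal: they assume roughly 1--4 nm/px images
where sub-3 px structure is stain texture and 40 px-scale structure is
background. They are configurable through `pipeline_config()`.

## Numerical choices

**Profile fitting.** The degree-six fit is least squares, not
interpolation — an interpolant through dozens of noisy points cannot have
degree six. Arclength is rescaled to \([-1, 1]\) before fitting for
conditioning; coefficients are reported in the nm basis. The derivative is
taken analytically from the fitted coefficients, never by finite
differences of raw data, and cutoff crossings are found by polynomial root
isolation (reported to 0.1 nm).

**Candidate selection.** All cutoff down-crossings are reported as
candidates. The default `last_sustained` policy selects the largest
candidate beyond which the fitted slope stays below the cutoff out to the
proximal end of the profile — a deterministic stand-in for the operator
step of accepting the transition that agrees with the micrograph. An
explicit `candidate` index reproduces an operator override. Whether the
distal-most or proximal-most crossing is "the" boundary is genuinely open;
the policy is a documented choice, and `"first"`/`"last"` are available.

**Edge criterion.** The half-maximum threshold lies midway between a
background floor (10th percentile of the perpendicular window) and a core
level. The core level is the larger of the 90th percentile of the whole
window and of the samples nearest the centerline: the global quantile
tracks wide shafts and the edge ridges of band-passed images, while the
central one keeps narrow tips — which occupy well under 10% of a 800 nm
window — from collapsing into the background. Edges are accepted only from
above-threshold runs at least 1 px wide that reach near-core intensity,
which rejects sub-resolution noise blips and the residual ripple of the
zero-mean band-passed background. Structures narrower than about 2 px
cannot be resolved and are flagged, which is why measured profiles lose
their first few points at a sharp tip.

**Rational-curve closure.** Features `(t_max, L_max, L_inf)` fix four of
the seven coefficients (with the scale pinned by `d = 1`). The remaining
freedom is closed by a deterministic rule that *suppresses the leading
`1/t` tail term* (`b = L_inf · e`), making the curve approach its
asymptote like \(1/t^2\) — the fastest settling this family admits once
the overshooting peak is pinned. This matches the observed biology (tip
maturation is essentially complete a few peak-times after the peak) and,
importantly, makes the asymptote statistically identifiable: with slower
tails the curve is still far above \(L_\infty\) at the last sampled time,
and simulation shows the Cramér–Rao bound for \(L_\infty\) under the
default design then exceeds 200 nm. With the canonical closure the bound
is ≈ 90 nm and the fitted asymptote lands within a few tens of nm of the
truth in typical runs.

**Fitting the rational model.** `fit_rational()` is Levenberg–Marquardt on
the shape chart `(log t_max, log L_max, logit(L_inf/L_max))`, which spans
the d = 1 family while keeping the denominator root-free on the positive
axis. Fits start from a deterministic ladder of seven initializations
derived from the empirical time-point means, and the best converged
objective wins; per-start diagnostics and the iteration trace are kept in
the returned object. `free_shape = TRUE` additionally frees the three
denominator shape factors; this is provided for completeness, but in the
full family the asymptote is only weakly identified from a finite sampling
window (near-identical residual sums with asymptotes anywhere between 0
and the tail height), so the canonical closure is the default. Fits use
every per-cilium record by default; `fit_means = TRUE` switches to
time-point means. Weighting by per-time scatter is deliberately not
applied.

**Balance-point model.** The growth law `dL/dt = D (L_inf - L)/L` is the
classic balance-point form — assembly slows with length, disassembly is
constant — and is adopted here as a modeling assumption; the fitting code
isolates it behind `balance_point_length()` so an alternative ODE could be
slotted in. Evaluation inverts the closed-form `t(L)` per time point with
`uniroot` at machine tolerance.

## What the synthetic generator does and does not emulate

The renderer draws an ideal filament silhouette: a filled band whose local
width equals the geometry's diameter, on a straight or constant-curvature
centerline, with a hard intensity step, optional FTC ellipse, linear
background gradient and white Gaussian noise. Anti-aliasing is off so that
band widths are countable in pixels. It does **not** model stain
granularity, microtubule-doublet substructure, membranes, partial staining
or defocus — so passing the render-based tests demonstrates that the
measurement chain is geometrically correct and noise-tolerant, not that it
is robust to every negative-stain artifact. Kinetics tables are Gaussian
scatter (truncated at zero) around the exact model curves; real per-cilium
variance structure is unknown, and the default spreads (300 nm tip,
400 nm full length) are assumptions chosen to look like published error
bars, not measured values.

Default simulated experiments use nine sampling times between 20 and 360
minutes with 30 cilia per time; the species defaults are
(t_max 135 min, L_max 2020 nm, L_inf 1070 nm, plateau 6.5 µm) for
*Tetrahymena* and (150 min, 1280 nm, 680 nm, 10.7 µm) for
*Chlamydomonas*, with full-length rate constants set so 90% of the plateau
is reached at 120 and 240 minutes respectively.

## Known limitations

* **Smoothing bias of the boundary.** A degree-six polynomial rounds sharp
  taper-to-shaft corners, shifting the cutoff crossing proximally. The
  shift grows with the taper slope and with profile length: for a gentle
  3° cone it is within ±70 nm, and for the shallow Fig-2-like morphology
  (slope ≈ 0.09) the end-to-end error stays inside 10%; but for steep 5°
  and especially 10° cones it reaches one to several hundred nm
  (e.g. ≈ +117 nm for a 5° cone with a 1429 nm junction in a 2500 nm
  profile, ≈ +250 nm for a 10° cone with a 2000 nm junction). This is a
  property of the published definition itself, not of the implementation —
  the identical shift is produced by an independent `lm()`-based oracle —
  and should be kept in mind when comparing absolute tip lengths across
  morphologies with very different taper angles.
* **Asymptote uncertainty.** Even with the canonical closure, the
  asymptote of the rational curve is the feature most sensitive to
  sampling noise (lower bound ≈ 90 nm sd under the default design);
  peak position and height are far better determined (≈ 4 min, ≈ 33 nm).
* **Manual centerlines.** Tracing is out of scope by design; profile
  quality depends on the drawn polyline, and the measured length is the
  length *along the drawn centerline*.
* The profile measurement assumes an approximately straight perpendicular
  cross-section; strongly curled cilia violate this.
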