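Package: ciliatip
Title: Ciliary Tip-Region Morphometry and Regrowth Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the tapering tip region of regrowing cilia from
    negative-stain electron micrographs and fits growth-kinetics models to
    regeneration time courses. Extracts calibrated diameter profiles along a
    user-drawn centerline by perpendicular half-maximum edge detection,
    fits a degree-six polynomial to each profile and delimits the tip region
    where the fitted slope falls below a 1.5-degree-per-side cutoff, and fits
    a rational (quotient-of-trinomials) model to tip-length time courses and
    a balance-point ordinary differential equation to whole-cilium lengths.
    Includes a synthetic-data generator that renders ground-truth micrographs
    and kinetics tables so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
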