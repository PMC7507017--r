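Package: germspline
Title: Monotone Smoothing Splines and Continuous Indices for Seed Germination Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits nonnegative, nondecreasing optimal smoothing splines (absolute
    germination distribution functions, AGDFs) to cumulative seed-germination
    counts, computes the continuous germination index (CGI) as the area under
    the fitted spline, and computes the classical discrete germination indices
    (total germination, mean germination time, coefficient of velocity of
    germination, germination index, LT50). Indices are compared by how well
    they predict the germination curves in a function-on-scalar regression
    with pointwise and global coefficients of determination. Includes the
    Kader hypothetical germination scenarios as a built-in data set and a
    binomial Hill-curve cohort simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    splines,
    pracma,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
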