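Package: menisize
Title: Three-Dimensional Meniscus Allograft Sizing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for sizing meniscus allografts from triangulated surface
    models of the knee menisci. Implements root-aligned oriented-bounding-box
    morphometry (width, length, height), rigid superimposition of meniscus
    surfaces by the iterative closest point algorithm with mean and maximum
    (Hausdorff) surface distances, the radiographic Pollard sizing rule and
    two-dimensional width/length sizing, a parametric generator of synthetic
    meniscus banks calibrated to published population statistics, and a
    leave-one-out validation pipeline that compares allograft selection by
    3D shape matching against conventional two-dimensional sizing methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
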