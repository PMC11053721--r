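Package: truedent
Title: Spatial Trueness Evaluation of 3D-Printed Dental Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to evaluate the spatial trueness of photopolymer 3D-printed
    dental models against their design data using a structurized dental model:
    parametric generation of maxillary and mandibular reference models built
    from cuboid simulated dental crowns on a horseshoe base, STL import/export
    with named surface regions, best-fit (iterative closest point) rigid
    registration, signed surface-deviation analysis with root-mean-square
    summaries and 21-segment colour difference maps, form tolerances (flatness,
    parallelism and perpendicularity against the base plane), a virtual caliper
    for 96 named linear feature sizes with relative-error aggregation, and a
    synthetic deformation generator (shrinkage, warpage, surface noise) for
    closed-loop validation without a physical printer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    grDevices,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
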