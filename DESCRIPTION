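Package: subtendon
Title: Achilles Sub-Tendon Mechanics: Geometry, Finite Elements, and Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying load sharing between the three sub-tendons of
    the human Achilles tendon (lateral gastrocnemius, medial gastrocnemius,
    soleus). Provides parametric three-sub-tendon geometries lofted into
    quadratic tetrahedral meshes, a geometrically nonlinear compressible
    neo-Hookean finite-element solver with a switchable sliding interface
    (frictionless, Coulomb frictional, bonded), the displacement and von
    Mises stress outcome measures used to characterise sub-tendon sliding,
    analysis of uniaxial tensile tests to failure, nonparametric group
    statistics (exact Mann-Whitney, Kruskal-Wallis), normalized
    musculotendinous-junction displacement from stimulation trials, a
    noncentral-t a priori sample-size computation, and seeded synthetic-data
    generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    tibble,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
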