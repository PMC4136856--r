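Package: corridorscape
Title: Occupancy-Based Wildlife Corridor Planning on Raster Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning wildlife movement corridors across fragmented
    landscapes from detection/non-detection survey data. Implements the
    single-season occupancy model with imperfect detection, AIC-based
    all-subsets model selection with Akaike-weight model averaging, habitat
    suitability mapping with ROC/AUC validation against independent sign
    transects, least-cost-path corridor identification on raster cost
    surfaces, circuit-theory connectivity (graph Laplacian, current density,
    omnidirectional buffered maps), and comparison of landscape-management
    scenarios (forest restoration, residence relocation, road tunnels) with
    two-way ANOVA and Holm-corrected paired t-tests. Includes a synthetic
    valley-landscape generator with known ground truth so the full pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
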