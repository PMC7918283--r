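Package: colweb
Title: Self-Assembly and Polygon Statistics of Collagen-IV-Like 2D Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained simulation and structural analysis of
    two-dimensional biopolymer networks such as the collagen IV meshwork of
    basement membranes. Molecules are bead-spring worm-like chains with
    attractive patchy head groups; self-assembly is driven by Langevin
    dynamics through a melt-cool protocol with an intermediate
    constant-pressure stage. The analysis suite converts bead snapshots into
    node/edge networks, assigns polygon faces by a Delaunay-merge algorithm
    on the periodic cell, and computes ring statistics: polygon edge-count
    distributions and their maximum-entropy reference model, the shape
    regularity coefficient, polygon-size assortativity, coordination-number
    moments, and the (mu2(k), r) network landscape. Includes builders for
    idealised honeycomb and square nets, pre-tangled molecule templates,
    Poisson-Voronoi calibration fixtures, and a parameter-scan driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    interp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
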