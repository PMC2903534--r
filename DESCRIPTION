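Package: moranmod
Title: Modified Moran's I and Monte Carlo Tests for Global Disease Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global spatial-clustering tests for regional disease counts:
    classic Moran's I, a modified Moran's I that carries the spatial weight
    function into the variance term, and Oden's I_pop which adjusts for
    population heterogeneity. Weight schemes include 0/1 adjacency weights and
    population-density-adjusted exponential weights whose bandwidth is the
    distance to the most nearest neighbors whose cumulative population stays
    within a user-set fraction of the total. Inference is by Monte Carlo
    simulation under the constant-risk multinomial null. Includes generators
    for lattice geographies and local-cluster, spiral, and west-east linear
    relative-risk surfaces, plus a power-study runner, GAL adjacency import
    and export, tidy() and glance() methods, ggplot2 autoplot() methods, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
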