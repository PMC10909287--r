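Package: dynaccess
Title: Static Versus Dynamic Population Accessibility to Emergency Departments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring population accessibility to emergency
    departments over a travel-time road network and for quantifying where and
    when residential (static) population data over- or underestimates
    population shares relative to mobile-network-derived (dynamic) population
    data. Includes road-graph construction with intersection splitting and
    closest-facility routing, fusion of a homogeneous residential grid with a
    variable-resolution dynamic grid, travel-time band summaries, temporal
    static/dynamic share ratios, catchment-level difference analysis with
    global Moran's I (inverse-distance weights), one-way ANOVA and Tukey HSD,
    and a synthetic-scenario generator emulating commuting and vacation
    population redistribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
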