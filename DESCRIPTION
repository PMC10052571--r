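Package: maizecanopy
Title: Phytomer-Based 3D Maize Canopy Photosynthesis and Heterosis Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds parametric three-dimensional maize canopies from
    per-phytomer morphological descriptors, computes hourly direct and
    diffuse photosynthetically active radiation (PAR) interception and
    sunlit leaf area per leaf facet with a virtual-wall boundary, evaluates
    and fits Ye's leaf photosynthetic light-response model, integrates leaf
    photosynthesis to canopy assimilation, daily biomass, intercepted PAR
    and radiation use efficiency (RUE) over a 60-day post-silking window,
    and decomposes hybrid-parent differences (heterosis) in yield and RUE
    into canopy-structure and leaf-photosynthesis contributions by trait
    swapping. A synthetic-data module generates cultivar phytomer tables,
    light-response observations and diurnal weather with the rank trends
    and cultivar contrasts of the field study the model emulates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
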