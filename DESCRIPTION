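Package: reefwave
Title: Wavelet-Based Multiscale Structural Complexity of Reef Elevation Models
Version: 0.1.0
Authors@R: person("COSTALAB", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Decomposes high-resolution seafloor digital elevation models (DEMs)
    into fine-scale and broad-scale topographic components with a row-wise
    maximal overlap discrete wavelet transform (MODWT, Daubechies family), and
    turns each component into a per-pixel Ra roughness raster: digital local
    complexity (DLC, attributable to live benthic cover) and digital global
    complexity (DGC, the underlying calcareous reef matrix). Includes a digital
    chain-method rugosity analog, rasterization of digitized coral-colony
    polygons onto the DEM grid, per-group complexity extraction, the
    accompanying nonparametric statistical battery (Mann-Whitney U,
    Kruskal-Wallis, Dunn's post-hoc with Bonferroni correction, log-cover
    regression), and a seeded synthetic reefscape generator for end-to-end
    validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
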