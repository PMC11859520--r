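Package: borealmc
Title: Monte Carlo Photon Transport for Imaging Woody Debris in Boreal Lakes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelized Monte Carlo simulation of photon transport in boreal lake
    water containing submerged woody-debris cylinders, driven by a bio-optical
    model of lake absorption and chlorophyll scattering. Builds spectral
    reflectance images as seen from above the surface, measures Michelson-type
    image contrast of the debris with its spread, sweeps wavelength,
    chlorophyll concentration and debris depth, and applies a 10 percent
    contrast cut-off to recommend imaging wavelengths. Inherent optical
    properties combine a bundled pure-water absorption table (Hale and Querry,
    1973), colored-dissolved-organic-matter and pigment components for four
    boreal lake presets, a chlorophyll scattering law, and Henyey-Greenstein
    scattering with closed-form inverse-CDF sampling. The transport kernel is
    written in C++ with counter-based per-photon random streams so results are
    bit-reproducible for a given seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
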