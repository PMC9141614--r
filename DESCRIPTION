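Package: greenexposure
Title: Street-View Green Space Exposure Inequity Analysis for 15-Minute Cities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses inequity in eye-level green space exposure at the
    residential-community scale under the 15-minute-city planning concept.
    Computes the Green View Index (GVI) from street-view label images,
    aggregates point GVI to communities within walking-time buffers
    (minutes times 72 m/min), scores inequity with the location-entropy
    (location quotient) statistic relating green exposure to rental price,
    and detects exposure-inequity clusters with bivariate global and local
    Moran's I under conditional permutation inference. A synthetic-city
    generator (street grid, label images with planted green fractions,
    community tessellation, prices with a planted spatial association)
    makes the whole pipeline testable without any external data.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
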