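Package: careaccess
Title: Spatial Accessibility and Equity of Aged-Care Institutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gravity-style (potential-model) spatial accessibility for
    aged-care institutions on gridded demand surfaces, including a
    competition-adjusted variant with facility-scale service radii and
    quality-tier travel limits, Lorenz-curve and Gini-coefficient equity
    assessment over administrative units, weighted kernel-density summaries
    of facility point patterns, a deterministic synthetic-city generator,
    and readers/writers for CSV, GeoJSON and ESRI ASCII grid inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
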