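Package: clinicplan
Title: Spatial Accessibility Analysis and Clinic Location Planning for
    Specialist Health Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures spatial accessibility of a patient population to
    specialist clinics using a precomputed area-to-facility driving-time
    matrix: nearest-clinic drive times, patient-weighted threshold coverage,
    per-clinic reach tables, and before/after evaluation of candidate clinic
    locations. Includes patient cohort selection with small-area linkage and
    lost-to-follow-up flagging, small-cell masking with complementary
    suppression for public outputs, choropleth GeoJSON export, a five-section
    reproducible report builder, and a seeded synthetic data generator that
    emulates the input bundle (area polygons, sociodemographic attributes,
    travel-time matrix, concordance, patient records) so the whole pipeline
    runs without access to private data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
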