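Package: ventscore
Title: Bench Scoring of Pressure-Support Ventilator Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate non-invasive pressure-support ventilators on a
    lung-model bench. Segments airway pressure/flow recordings into breaths,
    extracts ten performance parameters (trigger time, inspiratory and
    expiratory T90, maximum pressure drop, IPAP/EPAP errors, tidal volume,
    peak-flow rising ratio, leak settle times, oxygen-delivery accuracy),
    maps them to unit-interval scores through per-phenotype range tables, and
    aggregates them with analytic-hierarchy-process (AHP) weights into
    criterion and overall device scores. Includes a single-compartment lung
    and ventilator simulator emulating four COVID-19 respiratory phenotypes
    with configurable device imperfections, so the whole pipeline can be
    exercised without bench hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
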