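Package: snaudit
Title: School Neighbourhood Built-Environment Audit Scoring and Spatial Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for micro-scale and macro-scale assessment of school
    neighbourhood built environments. Implements a hierarchical streetscape
    audit scoring engine (items to valence sub-scales to section, grand and
    cross-domain scores) with a configurable scoring scheme, street-network
    service-area (buffer) construction with segment extraction and
    inclusion/exclusion/extension protocol rules, macro-scale walkability
    metrics (intersection density, residential density, land-use-mix entropy
    and a composite z-score walkability index), inter-rater reliability
    (intraclass correlation with exact F-based confidence intervals and
    Cicchetti classification) and odd-versus-even street-side concordance
    statistics for validating condensed one-side-per-segment audit protocols.
    A seeded synthetic-city generator emulates street grids, residences,
    land use and two-sided, two-rater audit data for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
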