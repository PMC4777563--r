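Package: pcekit
Title: Person-Centred Episodes of Care from Multi-Sector Health Administrative Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Constructs person-centred episodes of care (PCE) from linked
    multi-sector health-administrative encounter records. Episodes are anchored
    on an acute hospital admission and extended by a rolling 30-day window over
    subsequent institutional care, with community care attached over the episode
    span. Each episode is assigned one of twelve mutually exclusive clinical
    groupings from the anchor admission via a configurable diagnosis-prefix
    hierarchy. Per-sector costs are attributed inside versus outside episodes
    with exact conservation, and cohort- and episode-level summary tables are
    produced, including high-cost cohort selection by expenditure percentile and
    the usual-provider-of-care continuity index. A seeded synthetic-claims
    generator with planted episode ground truth supports end-to-end testing
    without access to real administrative holdings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
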