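Package: energyscape
Title: Energetic Seascapes for Juvenile Albacore from Linked Additive Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links four additive smooth regressions (diel depth, metabolic
    movement cost, heat increment of feeding, and energy ingested) into daily
    energy-balance seascapes for juvenile albacore tuna. Provides seeded
    synthetic generators for archival-tag records, laboratory respirometry and
    feeding-trial tables, and gridded monthly ocean fields; extraction of the
    heat increment of feeding from 1-min body-temperature traces; daily track
    energetics from tag positions; projection of per-cell daily kJ balance onto
    gridded fields with a sea-surface-temperature thermal-envelope habitat
    mask; habitat-area and area-weighted balance-change summaries across a
    climate-model ensemble; and propagation of model-coefficient uncertainty
    by posterior simulation through the full chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    zoo,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
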