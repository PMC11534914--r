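Package: mobadmit
Title: Community Mobility Indices and Trauma Outpatient Admissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to relate smartphone-derived community mobility reports to
    daily trauma outpatient admissions. Reads Google-style (long,
    percent-change-from-baseline) and Apple-style (wide, baseline-indexed)
    mobility CSV dialects and daily admission counts, fills sporadic gaps by
    seasonal-split linear interpolation, computes a leisure-related composite
    mobility index and baseline-matched outpatient indices, and estimates
    their association by Pearson correlation (Fisher-z intervals) and simple
    least-squares regression. Includes lockdown-period summary tables against
    matched previous-year intervals and a seeded synthetic-data generator that
    emulates lockdown suppression with compliance decay, so the full pipeline
    is testable without access to hospital records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
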