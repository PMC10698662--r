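Package: nightfit
Title: Agreement Analysis Between Chatbot Sleep Diaries and Wearable Sleep Records
Version: 0.1.0
Authors@R:
    person("KM", "Data Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for method-agreement studies that compare self-reported sleep
    diaries (collected through a button-driven chatbot) with per-night sleep
    records from a wrist-worn tracker. Provides wrap-aware clock-time
    arithmetic and anchored (circular) means of times of day, readers and
    writers for the three raw record streams, a calibrated synthetic cohort
    generator with a ground-truth ledger, the cleaning/matching/inclusion
    rules typical of such studies (ordering checks, AM/PM error exclusion,
    day caps, minimum-day inclusion), Bland-Altman limits of agreement overall
    and by stratum, rounding-tendency (digit-preference) profiles, and
    threshold-coverage statistics with mean-difference and sleep-quality bias
    corrections. A config-driven pipeline orchestrates simulation through
    report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
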