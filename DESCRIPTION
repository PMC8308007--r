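Package: elemrisk
Title: Dietary Exposure and Health Risk Assessment for Trace Elements in
    Protein Powder Supplements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for screening-level human health risk assessment of
    trace-element concentrations measured in food supplements by ICP-MS.
    Covers dilution back-calculation from instrument readings to
    original-sample concentrations, handling of left-censored (below limit
    of quantification) and above-calibration-range results, estimated daily
    intake (EDI), non-carcinogenic hazard quotients and hazard index
    (HQ/HI), slope-factor based cancer risk (CR), instrument quality
    control rules (spike and reference-material recoveries, resolution
    transmission gates), and a synthetic panel generator for end-to-end
    testing. Ships a packaged reference panel of 36 commercial protein
    powder samples with serving masses and a toxicological reference table
    (oral reference doses and cancer slope factors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
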