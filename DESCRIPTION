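Package: eradrank
Title: Prioritizing Islands for Invasive Mammal Eradication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for ranking islands by the conservation
    benefit of eradicating invasive mammals. Computes per-island Current
    Conservation Risk (the sum over breeding highly threatened vertebrates of
    extinction risk x irreplaceability x maximum invasive-impact severity),
    Potential Conservation Risk under technical eradication-feasibility rules,
    and the Eradication Benefit used as the primary island ranking. Includes
    family-level impact imputation, expert-timeframe aggregation for
    socio-political feasibility, sensitive-island masking, benefit summaries,
    a seeded generator of synthetic island/species/invasive datasets, and a
    brute-force scoring oracle used as independent test ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    jsonlite,
    withr
Config/testthat/edition: 3
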