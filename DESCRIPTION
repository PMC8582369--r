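Package: cbfbfish
Title: Interpretation of CBFB Break-Apart FISH, Karyotype and RT-PCR
    Results in inv(16)/t(16;16) AML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clinical cytogenomics interpretation of CBFB
    break-apart FISH testing in acute myeloid leukemia with
    inv(16)(p13.1q22)/t(16;16)(p13.1;q22). Parses ISCN 2020 karyotype and
    "nuc ish" nomenclature into typed models, classifies interphase FISH
    signal patterns under validated cutoffs, integrates FISH with
    CBFB-MYH11 RT-PCR into confirmation, concordance and discordance-cause
    calls, detects apparent and cryptic additional chromosome 16
    aberrations, applies standard and re-defined complex-karyotype rules,
    predicts detectability by NGS-based methods, and tabulates cohorts
    with chi-square comparisons. Includes a seeded synthetic-cohort
    generator so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
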