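Package: pvsignal
Title: Disproportionality Analysis for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal detection for pharmacovigilance databases of individual
    case safety reports (ICSRs). Builds report-level 2x2 contingency tables
    for drug-event pairs, computes the reporting odds ratio (ROR) with its
    Woolf 95 percent confidence interval, applies the signal-of-
    disproportionate-reporting (SDR) decision rule with minimum-case and
    zero-cell conventions, and stratifies antibacterial signals by ATC
    level-5 code and WHO AWaRe group. Includes a synthetic ICSR generator
    with known ground-truth association structure for method validation,
    line-listing readers and writers, label-knowledge annotation, and an
    end-to-end screening pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    stringr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
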