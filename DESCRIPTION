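Package: rootscn
Title: Boolean and Continuous Gene Regulatory Network Models of the
    Arabidopsis Root Stem Cell Niche
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic synchronous Boolean network engine with exhaustive
    and sampled attractor/basin analysis, node clamping for in silico loss- and
    gain-of-function mutants, single-output rule-flip robustness scans, and
    Derrida criticality analysis.  Ships four alternative single-cell models of
    the Arabidopsis thaliana root stem cell niche (variants A, A', B, B' over
    the PLT/auxin/ARF/Aux-IAA/SHR/SCR/JKD/MGP/WOX5(/CLEX) nodes), a Glass-type
    logistic ODE counterpart with steady-state enumeration and stability
    classification, and a four-cell coupled meta-network (40 variables) with
    mobility-augmented rules that recovers the spatial patterning of the niche.
    A seeded random Boolean network generator and the annealed Derrida map
    provide synthetic validation data for every engine component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
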