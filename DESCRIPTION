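Package: csiscreen
Title: Drought-Tolerance Screening with Stress Indices, a Composite
    Selection Index and GT/GGE Biplots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for screening stress-tolerant genotypes in
    multi-environment yield trials of biparental populations such as
    recombinant inbred lines (RILs). Computes nine classical
    tolerance/susceptibility indices (SSI, RSI, TOL, MP, YSI, HM, GMP,
    STI, YI) from paired non-stress/stress yields, learns a composite
    selection index (CSI) as a correlation-weighted linear combination of
    the indices significantly associated with yield under both water
    regimes, ranks genotypes, and detects transgressive segregants
    relative to the parents. A rank-2 singular-value-decomposition biplot
    engine provides genotype-by-trait and genotype-by-environment views
    with tester-focused and symmetrical scalings, which-won-where sector
    maps and ideal-tester rankings. A stochastic RIL trial simulator with
    known genetic ground truth supports validation of the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
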