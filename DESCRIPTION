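Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection in spontaneous
    reporting databases. Implements the Information Component (IC), a
    shrinkage log2 observed-to-expected reporting ratio with a Bayesian
    credibility interval derived from a gamma posterior on the rate ratio,
    and reporting odds ratios (ROR) with Woolf confidence intervals.
    Provides a MedDRA-like five-level adverse-event dictionary model with
    hierarchy traversal, an individual case safety report (ICSR) data store
    with report-level 2x2 contingency counting, a staged scan over the
    hierarchy (system organ class screen, drill-down, between-drug
    comparisons, dose-stratified analyses), paper-style descriptive
    summaries, and a synthetic spontaneous-report generator with planted
    drug-event signals of known strength for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
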