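Package: tmaretest
Title: Test-Retest Reliability of Immunostain Panels on Duplicate Tissue Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing test-retest reliability of breast cancer
    biomarker immunostains (CK cocktail, ER, PR, HER2, CK 5/6, EGFR, Ki67)
    scored on duplicate tissue microarrays. Implements core-to-TMA
    aggregation rules, a surrogate molecular-phenotype classifier
    (Luminal A/B, HER2-enriched, basal-like) with explicit missing-marker
    semantics, percent concordance and Cohen's kappa with asymptotic and
    bootstrap confidence intervals under documented missing-pair policies,
    and a synthetic TMA-study generator (stratified sampling, block
    retrieval loss, per-core staining noise and tissue dropout) for
    property-based validation, including demonstration of the
    kappa-prevalence paradox. Ships a 30-case, 6-decade reference panel
    table as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
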