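Package: spillcea
Title: Family Health Spillovers in Cost-Effectiveness Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for internalizing family health spillovers in
    extra-welfarist economic evaluation. Implements multiplier effects on
    the streams of health generated and displaced by funding a health care
    intervention, a spillover-adjusted cost-effectiveness decision rule,
    portfolio funding analysis under graded spillover information,
    marginal-benefit equilibrium analysis with welfare triangles, and
    estimation of condition-specific utility decrements (and hence
    multipliers) from patient and carer health-status records. Includes a
    synthetic patient-carer cohort generator so the full estimation
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
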