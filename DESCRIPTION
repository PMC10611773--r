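Package: mrbridge
Title: Two-Sample Bidirectional Mendelian Randomisation with Colocalisation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An offline toolkit for two-sample, bidirectional Mendelian
    randomisation from GWAS summary statistics: reading and harmonising
    summary-statistic tables, instrument selection with LD clumping and
    proxy lookup, five causal estimators (Wald ratio, multiplicative
    random-effects IVW, MR-Egger, weighted median, weighted mode),
    heterogeneity and pleiotropy diagnostics (Cochran's Q, I-squared,
    MR-PRESSO, funnel data), single-causal-variant colocalisation via
    Wakefield approximate Bayes factors, minimum-detectable-odds-ratio
    power calculations for binary outcomes, and a synthetic
    summary-statistic generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
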