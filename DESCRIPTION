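Package: mozage
Title: Transcriptional Age Grading of Anopheles Mosquitoes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the adult age of Anopheles gambiae
    mosquitoes from gene expression. Implements the full age-grading
    workflow: screening of age-informative transcripts from factorial
    microarray designs (signal filtering, percentile-shift normalization,
    per-gene two-way ANOVA with Benjamini-Hochberg correction, and
    correlation/fold-change candidate filters), logcontrast (delta-Ct)
    normalization of triplicate qRT-PCR measurements against a reference
    gene, a redundancy-variate calibration model (the linear combination
    of expression measures maximizing correlation with known age),
    inverse-regression age prediction with nonparametric bootstrap
    confidence intervals, and leave-one-out cross-validation with bias
    diagnostics. A synthetic-data module generates microarray matrices
    and Ct tables with known ground truth so the whole pipeline is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
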