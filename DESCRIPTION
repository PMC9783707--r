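Package: pipscore
Title: Pharmacogenomic Interaction Probability Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes pharmacogenomic interaction probability (PIP) scores:
    the probability that a patient's medication list will yield at least one
    evidence-based, actionable drug-gene, drug-drug-gene, or drug-gene-gene
    interaction given population phenotype prevalences. Includes a documented
    open knowledge-base format with a calibrated demo knowledge base, a
    categorical phenoconversion model that combines area-under-the-curve
    change categories for co-medication, an interaction detector for
    genotyped patients, a synthetic cohort simulator, and validation
    statistics (interaction rate versus mean score, one-proportion z-test,
    number needed to test, severity and clinical-area tabulations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
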