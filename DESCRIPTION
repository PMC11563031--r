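Package: admixkit
Title: F-Statistics and Admixture Graph Fitting for Allele Frequency Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates f2-, f3-, f4- and D-statistics from per-population
    allele frequency panels with weighted block-jackknife standard errors
    and covariance matrices; represents admixture graphs (population trees
    with admixture events) and computes exact expected f-statistics as
    admixture-weighted path overlaps; fits branch lengths and mixture
    proportions of a user-specified topology by generalized least squares;
    and diagnoses fit quality, residuals and parameter identifiability.
    Includes a drift-based allele-frequency simulator with canned example
    scenarios, EIGENSTRAT and frequency-table readers, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
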