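Package: grstriage
Title: Genetic Risk Score Triage and Exact Statistics for Monogenic Diabetes Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Implements the analysis chain used to screen paediatric diabetes
    clinic populations for monogenic (single-gene) diabetes, with an emphasis
    on recessively inherited causes in consanguineous populations: a weighted
    type 1 diabetes genetic risk score over 30 susceptibility SNPs with
    centile-calibrated low/moderate/high categories; triage of children for
    gene-panel testing from the risk category and islet autoantibody status;
    zygosity-based inheritance classification of confirmed cases; prevalence
    estimation with Clopper-Pearson exact intervals; and exact small-sample
    inference for clinical selection criteria (two-tailed Fisher tests,
    conditional maximum-likelihood odds ratios with exact confidence
    intervals, exact Mann-Whitney and two-sample Kolmogorov-Smirnov tests).
    A synthetic cohort generator emulates the screened population so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
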