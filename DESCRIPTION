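Package: melcea
Title: Markov Cohort Cost-Effectiveness Model of Adjuvant Ipilimumab
    Versus High-Dose Interferon in Resected Melanoma
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A four-state Markov cohort model comparing adjuvant ipilimumab
    (3 mg/kg) with high-dose interferon alfa-2b in resected high-risk
    melanoma. Calibrates monthly transition probabilities to overall- and
    progression-free-survival target curves, simulates the cohort with
    half-cycle correction and 3% discounting, attaches 2020 USD costs and
    health utilities from either a healthcare or a societal perspective,
    and reports incremental cost-effectiveness ratios with one-way,
    threshold-price and probabilistic sensitivity analyses (cost-
    effectiveness acceptability curves via net monetary benefit).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
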