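Package: dilisignal
Title: Disproportionality Signal Detection for Drug-Induced Liver Injury
    in Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for quantifying the association
    between systemic antifungal drugs (triazoles and echinocandins) and
    drug-induced liver injury (DILI) in FAERS-style spontaneous
    adverse-event reporting data. Reads and writes quarterly-extract
    report tables, deduplicates case versions, selects DILI cases through
    a MedDRA preferred-term dictionary and an antifungal drug lexicon, and
    computes four 2x2 disproportionality statistics (reporting odds ratio,
    proportional reporting ratio, information component, empirical
    Bayesian geometric mean) with their interval bounds and signal
    criteria. Includes demographic, time-to-onset and outcome/mortality
    summaries and a seeded synthetic report generator with known
    ground-truth signal structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
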