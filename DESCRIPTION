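Package: CLNMscore
Title: Clinical Risk-Factor Scoring for Central Compartment Lymph Node
    Metastasis in Papillary Thyroid Cancer
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a maximum-likelihood discriminant scoring model for
    predicting central compartment (level VI) lymph node metastasis (CLNM)
    in papillary thyroid cancer from six categorical clinical risk factors
    (sex, age, tumor diameter, capsular invasion, multifocality, tumor
    location). Per-category scores are fitted from class-conditional
    frequency tables via the transform (log10 P + 1) x 10, patients are
    classified by comparing positive- and negative-class score totals, and
    performance is summarised with per-class and mean coincidence rates.
    Includes a seeded synthetic-cohort generator under the model's
    class-conditional independence assumption, an exact enumeration oracle
    for expected classifier performance, delimited-text readers/writers,
    bundled reference frequency and score tables, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'CLNMscore-package.R'
    'scheme.R'
    'frequency-table.R'
    'score-table.R'
    'scoring.R'
    'evaluation.R'
    'synthetic.R'
    'io.R'
    'cli.R'
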