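Package: trialmetrics
Title: Disease-Specific Research Productivity of Cancer Hospitals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines clinical-trial registry records and MEDLINE-style
    publication records to quantify disease-specific clinical research
    productivity of cancer hospitals. Trials and publications are assigned
    to diseases with a keyword/bounded-gap-regex lexicon and MeSH terms,
    institutions are unified through a synonym dictionary, and per
    (institution, disease) pairs the package aggregates Phase II trial
    registrations and summed 2012 journal impact factors into a normalized
    composite productivity score with competition-ranked top-k tables,
    appearance tallies, rank-score curves, and per-disease least-squares
    regressions of summed impact factor on registrations. A synthetic-corpus
    generator with known ground truth makes every pipeline stage testable
    without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, xml2, yaml
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'phase.R'
    'io-registry.R'
    'io-medline.R'
    'io-tables.R'
    'institutions.R'
    'lexicon.R'
    'query.R'
    'metrics.R'
    'regression.R'
    'synthetic.R'
    'pipeline.R'
    'fixtures.R'
    'trialmetrics-package.R'
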