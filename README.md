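# trialmetrics

Disease-specific clinical research productivity of cancer hospitals,
computed from local trial-registry and MEDLINE-style publication corpora.

Whole-institution productivity rankings hide where specific diseases are
actually being studied: a center that is tenth overall may lead the field
in, say, cervical cancer. `trialmetrics` is for bibliometricians and
clinical-research analysts who want a reproducible, auditable pipeline
from raw records to per-disease rankings. For each *(institution,
disease)* pair over a fixed window (2008–2013 by default) it computes:

* **Registrations** — Phase II trials led by the institution, found by
  multi-label keyword/bounded-gap-regex classification of registry
  records (legacy ClinicalTrials.gov full-study XML);
* **Summed impact factor (SIF)** — the sum of 2012 journal impact
  factors over published Phase II trial reports matched by affiliation
  synonyms, publication type, date window and MeSH term (MEDLINE
  tagged-field text or PubMed XML);

and combines them into the composite score

```
Score(i, d) = ( SIF(i,d) / max_i SIF(i,d)
              + Reg(i,d) / max_i Reg(i,d) ) * 50        # in [0, 100]
```

ranked per disease with competition ranking (ties share a rank, top-10
lists extend through ties). Per-disease least-squares regressions of SIF
on registrations quantify how redundant the two components are.
Institution names are unified through an exact-match synonym dictionary
(no fuzzy matching — "Washington University" must never merge with
"University of Washington"). A synthetic-corpus generator with exact
ground truth makes the whole pipeline testable offline.

## Worked example

The composite score at the heart of the package, on published numbers:
an institution with cervical-cancer Phase II SIF 7.993 (disease maximum
10.329) and 1 registration (disease maximum 2):

```r
library(trialmetrics)
roundHalfUp(scorePair(7.993, 10.329, 1, 2))
#> [1] 63.69
```

i.e. `(0.774 + 0.5) * 50 = 63.69` — strong on publication impact,
middling on registrations.

End to end on a synthetic corpus with known truth:

```r
corp <- generateCorpus(generatorConfig(seed = 7, distractorFraction = 0,
                                       unresolvedFraction = 0))
corp$bundle
#> CorpusBundle: 94 trial(s), 95 publication(s), 40 journal IF(s)

m      <- compileLexicon(corp$lexicon)
labels <- classifyTrials(corp$bundle@trials, m)
res    <- resolveInstitution(corp$bundle@trials$lead_institution_raw,
                             corp$dictionary)
reg <- countRegistrations(corp$bundle@trials, labels, res,
                          canonicalInstitutions(corp$dictionary),
                          lexiconDiseases(corp$lexicon),
                          phase = "P2", window = c(2008, 2013))
sif <- summedImpactFactor(corp$bundle@publications, corp$dictionary,
                          corp$lexicon, corp$bundle@impactFactors,
                          phase = "P2", window = c(2008, 2013))
sb <- buildScoreboard(sif, reg)
sb
#> Scoreboard: 8 institution(s) x 7 disease(s), phase P2

topKWithTies(sb, "breast", 3)
#>                institution    score rank
#> 3 Prairie General Hospital 80.95971    1
#> 2        Harborview Clinic 66.66667    2
#> 1 Riverbend Medical Center 50.00000    3
```

The recovered scoreboard equals `expectedScoreboard(corp$truth, "P2")`
cellwise — the end-to-end oracle the test suite asserts.

`runPipeline()` (or `inst/scripts/run_pipeline.R` from a shell) executes
the same stages from a YAML config and writes the full report bundle:
overall table, per-disease top-10 tables, appearance tally, rank-score
curve data, regression table, full per-phase matrices, and audit reports
(unclassified sample, unresolved names, unknown journals).

## Layout

* `R/` — domain classes (S4), readers/writers, classification,
  resolution, metrics, regression, generator, pipeline.
* `inst/extdata/` — transcribed published tables and small editable
  example lexicon/synonym tables.
* `vignettes/disease-productivity.Rmd` — the model, its assumptions and
  the design choices, in detail.
* `tests/testthat/` — unit, property and acceptance suites.
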