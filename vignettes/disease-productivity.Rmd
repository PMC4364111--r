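---
title: "Measuring disease-specific clinical research productivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring disease-specific clinical research productivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialmetrics)
```

## The problem and the model

Research-oriented cancer hospitals treat and study patients across many
diagnoses, but productivity comparisons are usually made at the whole-
institution level, where a few very large centers dominate everything.
`trialmetrics` quantifies productivity per *(institution, disease)* pair
from two complementary observables over a fixed time window:

* **Registrations** — Phase II trials registered in a ClinicalTrials.gov-
  style registry with that institution as lead. Registration is forward-
  looking evidence of activity.
* **Summed impact factor (SIF)** — for published Phase II trial reports
  attributed to the institution and disease, the sum of the 2012 impact
  factors of the publishing journals (three trials published in journals
  with IF 1, 2 and 3 give SIF 6). Publication is retrospective evidence.

Phase II is the scoring stratum because Phase I trials are substantially
under-reported and Phase III trials are multi-centric, making single-
institution attribution unreliable. The two measures are combined into a
composite score per disease:

$$\mathrm{Score}(i, d) = \left(
  \frac{\mathrm{SIF}(i,d)}{\max_i \mathrm{SIF}(i,d)} +
  \frac{\mathrm{Reg}(i,d)}{\max_i \mathrm{Reg}(i,d)}
  \right) \times 50,$$

so the score lies in $[0, 100]$, with 100 attained exactly when an
institution holds both per-disease maxima. Per-disease regressions of SIF
on registrations (ordinary least squares; two-sided $t$ test on $n-2$
degrees of freedom) quantify how redundant the two components are —
correlations are generally modest, which is the justification for keeping
both terms.

## Pipeline stages and their assumptions

**Disease assignment (trials).** Trial title, condition strings and
description are concatenated and searched for each disease's literal
keywords (case-insensitive substrings) and an optional bounded-gap
regular expression such as `gastric.{1,100}cancer`, which detects
"cancer" within 100 characters after "gastric". Matching is deliberately
naive — no stemming, no NLP — so the classification is auditable pattern
by pattern; `classifyTrial()` records which pattern fired. Text is
whitespace-normalized before matching so the gap bound is measured in
normalized characters; dot does not match newlines. Keyword matching is
plain substring by default because registry capitalization and wording is
inconsistent; a word-boundary mode (`wordBoundary = TRUE`) is available
where embedded matches (e.g. "amelanomatous" containing "melanoma")
matter. Classification is multi-label: a trial mentioning both breast and
ovarian keywords counts for both diseases.

**Disease assignment (publications).** Publications are matched by MeSH
descriptor equality against each disease's MeSH terms (any MeSH term by
default; a major-topic-only flag exists, since indexing practice does not
settle the choice). The pan-cancer category accepts any descriptor
containing the configured umbrella stem ("Neoplasms") or equal to any
lexicon disease term — the latter covers descriptors like "Melanoma"
that do not carry the stem.

**Institution resolution.** Free-text names are casefolded,
punctuation-stripped and whitespace-collapsed, then looked up *exactly*
in a synonym dictionary. No fuzzy matching: the dominant known error mode
of this design is a missing synonym, which is visible and curable (the
pipeline writes an unresolved-names report), whereas fuzzy matching would
silently merge distinct centers — "Washington University" (St. Louis)
versus "University of Washington" (Seattle) is the canonical collision
that full-string matching keeps apart. Unresolved trials stay in corpus
totals but contribute to no institution.

**Aggregation.** Counts and SIF are accumulated per (institution,
disease) for one phase stratum and year window. Combined phase labels
(Phase I/II, Phase II/III) count toward each constituent stratum by
default — a Phase I/II trial is evidence of Phase II activity — with a
`"highest"` policy available that assigns them only to their highest
constituent. The `all_cancer` column counts every trial once,
classifiable or not, so the overall ranking is not hostage to lexicon
coverage. Start dates given as "Month YYYY" resolve to the first of the
month (deterministic and monotone with the true dates); undated trials
are excluded from windowed counts but retained in the corpus. Journals
absent from the impact-factor table contribute 0 and are logged, never
dropped silently.

**Scoring and ranking.** A term with a zero disease maximum contributes
0 rather than NaN, keeping scores total and bounded. Scores are ranked
per disease with competition ranking (ties share a rank; the next rank
skips), and top-10 lists extend through ties at the cut — published
blocks of 11-13 rows show that convention. Within a tie, ordering is
alphabetical for determinism. Ranking always uses unrounded scores;
reported values round half-up to 2 decimals, the precision of the
published tables (base R's round-half-even would disagree on exact
halves). Diseases with essentially no activity (`maxReg < 1` or
`maxSif <= 0`) are dropped from ranking — the published analysis likewise
set aside five very low-activity cancers; the floor is configurable.

**Regression.** `regressXY()` wraps `stats::lm`; a disease with constant
registrations is excluded with a warning rather than fit. Summary spread
is reported with both the sample (n−1, the default shown) and population
(n) denominators, since printed summaries rarely say which was used.

## The synthetic-data generator

`generateCorpus()` emulates the structure of the real sources so every
stage is testable offline with exact ground truth: Poisson trial counts
per (institution, disease, phase); keywords injected verbatim (or, for
regex-bearing diseases, occasionally as a gap variant only the regex can
detect); lead institutions drawn from synonym variants; publications with
the phase's publication-type string, the disease's major-topic MeSH term,
and affiliations embedding a synonym; log-normal impact factors (heavy
right tail, as real IF lists show — any positive distribution would do
for the oracle tests); distractor trials (side effects, risk factors,
unlisted diseases) carrying no lexicon pattern; and out-of-dictionary
sponsors at a controlled rate. Defaults — window 2008-2013, eight
institutions, six diseases, per-phase means `c(P1 = 0.5, P2 = 1.0,
P3 = 0.4)`, 1.2 publications per trial, `meanlog 1 / sdlog 0.8` impact
factors, 15% distractors, 5% unresolved — give corpora of a few hundred
records, large enough to exercise every code path and small enough that
the full suite runs in under a minute. Generation is a pure function of
the config (seed included) and restores the caller's RNG state.

What the generator does *not* emulate: real-world market shares and
disease prevalence, lexicon near-misses (real registry text can mention a
disease without any listed keyword), synonym gaps, and MeSH indexing
noise. Passing recovery tests therefore demonstrates that the *pipeline*
is faithful — not that any particular lexicon or dictionary is complete
for live registry data. The shipped example lexicon and synonym table are
editable starting points, not curated instruments.

```{r example}
corp <- generateCorpus(generatorConfig(seed = 7, distractorFraction = 0,
                                       unresolvedFraction = 0))
m <- compileLexicon(corp$lexicon)
labels <- classifyTrials(corp$bundle@trials, m)
res <- resolveInstitution(corp$bundle@trials$lead_institution_raw,
                          corp$dictionary)
reg <- countRegistrations(corp$bundle@trials, labels, res,
                          canonicalInstitutions(corp$dictionary),
                          lexiconDiseases(corp$lexicon),
                          phase = "P2", window = c(2008, 2013))
sif <- summedImpactFactor(corp$bundle@publications, corp$dictionary,
                          corp$lexicon, corp$bundle@impactFactors,
                          phase = "P2", window = c(2008, 2013))
sb <- buildScoreboard(sif, reg)
topKWithTies(sb, "breast", 3)
all.equal(matrixValues(sb)[, colnames(matrixValues(expectedScoreboard(corp$truth, "P2")))],
          matrixValues(expectedScoreboard(corp$truth, "P2")))
```

## Numerical and design choices

* **Rounding**: half-up at 2 decimals for display only (with a `1e-9`
  guard against binary representation of exact halves); all internal
  comparisons, maxima and ranks use full precision.
* **Ties**: competition ranking everywhere; alphabetical order inside a
  tie.
* **Degenerate inputs**: empty corpora produce header-only reports and
  all-zero matrices; zero maxima produce zero score terms; constant-
  registration diseases are excluded from regression with a warning;
  unknown phase strings normalize to `"NA"` with a warning, never an
  error.
* **Matrix CSVs** are written with `%.17g`, so a write-read-write cycle
  is byte-identical.
* **Affiliation matching** treats every affiliation line of a
  publication as eligible (not only the first author's), and a
  publication matching two institutions' synonym sets counts for both —
  institution-level attribution of multi-center papers is inherently
  plural.
* **Problem sizes in the tests**: property suites use panels of 8-50
  institutions, 1000 randomized tie-handling draws, and 200-replicate
  coverage checks at $n = 50$ — the published design size per disease.

## Known limitations

The lexicon and synonym dictionary shipped as examples are reconstructed
from in-text examples and are far smaller than a curated instrument;
substantive use requires supplying full tables via `readTable()`. MeSH
umbrella membership is approximated by the stem/equality rule above, not
by the real MeSH tree. Impact factor is a journal-level proxy with known
pathologies (field size, review articles); it is used here because it is
the measure the composite score is defined on, not an endorsement. No
multiple-testing correction is applied to the per-disease regressions,
matching the analysis the score was designed around.
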