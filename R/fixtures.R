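## Access to the published-table fixtures shipped under inst/extdata.

#' Published overall-productivity table (transcribed)
#'
#' The 50-institution overall (pan-cancer) table: Phase II summed impact
#' factor, Phase II registrations, and the printed composite score, as
#' published. Used to check that [buildScoreboard()] reproduces the
#' printed score column from the printed inputs.
#'
#' @return data.frame with columns `institution`, `score`, `sif`,
#'   `registrations`.
#' @export
overallProductivityTable <- function() {
    utils::read.csv(system.file("extdata", "table1_overall_published.csv",
                                package = "trialmetrics"),
                    stringsAsFactors = FALSE)
}

#' Published disease-specific top-10 lists (transcribed)
#'
#' The published top-10-with-ties ranking blocks for 25 cancer diagnoses.
#'
#' @return data.frame with columns `disease`, `institution`, `score`.
#' @export
diseaseRankTable <- function() {
    utils::read.csv(system.file("extdata", "table2_disease_ranks_published.csv",
                                package = "trialmetrics"),
                    stringsAsFactors = FALSE)
}

#' Example disease lexicon
#'
#' A small editable lexicon reconstructed from published in-text examples
#' (urothelial/bladder/ureteral keywords, the gastric bounded-gap regex,
#' the cervical MeSH term); the full published keyword table is a
#' supplementary file users can substitute via [readTable()].
#'
#' @return A [DiseaseLexicon-class].
#' @export
exampleLexicon <- function() {
    readTable(system.file("extdata", "example_lexicon.csv",
                          package = "trialmetrics"), "lexicon")
}

#' Example institution synonym dictionary
#'
#' Illustrates the synonym layout, including the
#' "Washington University" vs "University of Washington" distinction that
#' exact full-string matching is designed to preserve.
#'
#' @return A [SynonymDictionary-class].
#' @export
exampleSynonyms <- function() {
    readTable(system.file("extdata", "example_synonyms.csv",
                          package = "trialmetrics"), "synonyms")
}
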