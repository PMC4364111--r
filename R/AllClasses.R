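#' @import methods
NULL

## Closed phase vocabulary used throughout the package.  Combined labels
## (P1_2, P2_3) are first-class tokens; stratum membership is decided by
## phaseMatches(), not by rewriting the label.
PHASE_LEVELS <- c("NA", "EARLY_1", "P1", "P1_2", "P2", "P2_3", "P3", "P4")

TRIAL_COLUMNS <- c("trial_id", "title", "conditions", "description",
                   "start_date", "phase_label", "lead_institution_raw",
                   "enrollment", "status", "funding_source")

PUBLICATION_COLUMNS <- c("pmid", "journal_title", "pub_year", "pub_types",
                         "mesh_terms", "affiliations")

#' Empty trial table
#'
#' Returns a zero-row data.frame with the trial-record schema used across
#' the package: one row per registry entry, with list-columns for the
#' free-text condition strings. `phase_label` is drawn from the closed
#' vocabulary `c("NA", "EARLY_1", "P1", "P1_2", "P2", "P2_3", "P3", "P4")`.
#'
#' @return A zero-row data.frame with columns `trial_id`, `title`,
#'   `conditions` (list of character), `description`, `start_date` (Date),
#'   `phase_label`, `lead_institution_raw`, `enrollment`, `status`,
#'   `funding_source`.
#' @export
emptyTrials <- function() {
    data.frame(
        trial_id = character(0),
        title = character(0),
        conditions = I(list()),
        description = character(0),
        start_date = as.Date(character(0)),
        phase_label = character(0),
        lead_institution_raw = character(0),
        enrollment = integer(0),
        status = character(0),
        funding_source = character(0),
        stringsAsFactors = FALSE
    )
}

#' Empty publication table
#'
#' Zero-row data.frame with the MEDLINE-style publication schema: one row
#' per citation, list-columns for publication types, MeSH terms (major-topic
#' asterisk convention preserved in the raw strings) and affiliation lines.
#'
#' @return A zero-row data.frame with columns `pmid`, `journal_title`,
#'   `pub_year`, `pub_types`, `mesh_terms`, `affiliations`.
#' @export
emptyPublications <- function() {
    data.frame(
        pmid = character(0),
        journal_title = character(0),
        pub_year = integer(0),
        pub_types = I(list()),
        mesh_terms = I(list()),
        affiliations = I(list()),
        stringsAsFactors = FALSE
    )
}

validateTrials <- function(trials) {
    msg <- character(0)
    if (!is.data.frame(trials))
        return("trials must be a data.frame")
    missing <- setdiff(TRIAL_COLUMNS, names(trials))
    if (length(missing))
        return(paste0("trials lacks column(s): ", paste(missing, collapse = ", ")))
    if (nrow(trials)) {
        if (anyNA(trials$trial_id) || any(!nzchar(trials$trial_id)))
            msg <- c(msg, "trial_id must be nonempty")
        if (anyDuplicated(trials$trial_id))
            msg <- c(msg, "trial_id must be unique within a corpus")
        bad <- setdiff(unique(trials$phase_label), PHASE_LEVELS)
        if (length(bad))
            msg <- c(msg, paste0("phase_label outside the closed vocabulary: ",
                                 paste(bad, collapse = ", ")))
        if (!inherits(trials$start_date, "Date"))
            msg <- c(msg, "start_date must be a Date (NA allowed)")
        if (any(trials$enrollment < 0L, na.rm = TRUE))
            msg <- c(msg, "enrollment must be nonnegative")
    }
    msg
}

validatePublications <- function(pubs) {
    msg <- character(0)
    if (!is.data.frame(pubs))
        return("publications must be a data.frame")
    missing <- setdiff(PUBLICATION_COLUMNS, names(pubs))
    if (length(missing))
        return(paste0("publications lacks column(s): ",
                      paste(missing, collapse = ", ")))
    if (nrow(pubs)) {
        if (anyNA(pubs$pmid) || any(!nzchar(pubs$pmid)))
            msg <- c(msg, "pmid must be nonempty")
        if (anyDuplicated(pubs$pmid))
            msg <- c(msg, "pmid must be unique within a corpus")
        yr <- pubs$pub_year
        if (any(!is.na(yr) & (yr < 1000L | yr > 9999L)))
            msg <- c(msg, "pub_year must be a 4-digit year")
    }
    msg
}

#' DiseaseLexicon: keyword/regex/MeSH lexicon for disease assignment
#'
#' One entry per disease: up to eight literal keyword phrases matched as
#' case-insensitive substrings, an optional bounded-gap regular expression
#' (e.g. `"gastric.{1,100}cancer"`, which fires when "cancer" occurs within
#' 100 characters after "gastric"), and one or more MeSH descriptors used
#' on the publication side. The `allCancerMesh` umbrella term defines the
#' pan-cancer publication category: a citation belongs to it when any of
#' its MeSH descriptors contains the umbrella term (case-insensitively).
#'
#' @slot entries data.frame with columns `disease` (character), `keywords`
#'   (list of character), `regex` (character, `NA` when absent), `mesh`
#'   (list of character).
#' @slot allCancerMesh length-1 character, the umbrella MeSH stem.
#' @export
setClass("DiseaseLexicon",
    representation(entries = "data.frame", allCancerMesh = "character"),
    prototype(
        entries = data.frame(disease = character(0),
                             keywords = I(list()), regex = character(0),
                             mesh = I(list()), stringsAsFactors = FALSE),
        allCancerMesh = "Neoplasms"
    )
)

setValidity("DiseaseLexicon", function(object) {
    e <- object@entries
    msg <- character(0)
    need <- c("disease", "keywords", "regex", "mesh")
    missing <- setdiff(need, names(e))
    if (length(missing))
        return(paste0("entries lacks column(s): ", paste(missing, collapse = ", ")))
    if (anyDuplicated(e$disease))
        msg <- c(msg, "disease ids must be unique")
    if (nrow(e)) {
        nkw <- vapply(e$keywords, length, 1L)
        if (any(nkw == 0L & is.na(e$regex)))
            msg <- c(msg, "every entry needs >= 1 keyword or a gap regex")
        if (any(nkw > 8L))
            msg <- c(msg, "at most 8 keywords per entry")
        if (any(vapply(e$mesh, length, 1L) == 0L))
            msg <- c(msg, "every entry needs >= 1 MeSH term")
    }
    if (length(object@allCancerMesh) != 1L || !nzchar(object@allCancerMesh))
        msg <- c(msg, "allCancerMesh must be a single nonempty string")
    if (length(msg)) msg else TRUE
})

#' Construct a DiseaseLexicon
#'
#' @param disease character vector of disease identifiers.
#' @param keywords list of character vectors (<= 8 literal phrases each).
#' @param regex character vector of bounded-gap patterns, `NA` where absent.
#' @param mesh list of character vectors of MeSH descriptors.
#' @param allCancerMesh umbrella MeSH stem for the pan-cancer category.
#' @return A [DiseaseLexicon-class] object.
#' @examples
#' lex <- diseaseLexicon("gastric", list("gastric cancer"),
#'                       "gastric.{1,100}cancer", list("Stomach Neoplasms"))
#' @export
diseaseLexicon <- function(disease, keywords, regex = NA_character_,
                           mesh, allCancerMesh = "Neoplasms") {
    if (length(regex) == 1L && length(disease) > 1L)
        regex <- rep(regex, length(disease))
    entries <- data.frame(disease = as.character(disease),
                          keywords = I(keywords),
                          regex = as.character(regex),
                          mesh = I(mesh),
                          stringsAsFactors = FALSE)
    new("DiseaseLexicon", entries = entries, allCancerMesh = allCancerMesh)
}

#' SynonymDictionary: free-text institution name -> canonical institution
#'
#' Holds the canonical institution panel and an exact (post-normalization)
#' lookup from synonym to canonical id. Every canonical id maps to itself.
#' Raw synonym strings are retained for affiliation substring matching on
#' the publication side.
#'
#' @slot canonicalIds character vector of canonical institution ids.
#' @slot mapping named character vector: normalized synonym -> canonical id.
#' @slot raw data.frame with columns `synonym`, `canonical` (raw forms).
#' @export
setClass("SynonymDictionary",
    representation(canonicalIds = "character", mapping = "character",
                   raw = "data.frame"))

setValidity("SynonymDictionary", function(object) {
    msg <- character(0)
    if (anyDuplicated(object@canonicalIds))
        msg <- c(msg, "canonical ids must be unique")
    if (anyDuplicated(names(object@mapping)))
        msg <- c(msg, "normalized synonyms must be unique")
    if (!all(object@mapping %in% object@canonicalIds))
        msg <- c(msg, "mapping values must be canonical ids")
    selfkeys <- normalizeName(object@canonicalIds)
    if (!all(selfkeys %in% names(object@mapping)))
        msg <- c(msg, "every canonical id must map to itself")
    if (length(msg)) msg else TRUE
})

#' ImpactFactorTable: normalized journal title -> impact factor
#'
#' Lookup is insensitive to case, surrounding whitespace, and a trailing
#' period of the journal title (the dominant drift between MEDLINE journal
#' titles and published impact-factor lists).
#'
#' @slot factors named numeric vector keyed by normalized journal title.
#' @export
setClass("ImpactFactorTable", representation(factors = "numeric"))

setValidity("ImpactFactorTable", function(object) {
    msg <- character(0)
    if (length(object@factors)) {
        if (is.null(names(object@factors)) || any(!nzchar(names(object@factors))))
            msg <- c(msg, "factors must be named by journal key")
        if (anyDuplicated(names(object@factors)))
            msg <- c(msg, "journal keys must be unique after normalization")
        if (any(object@factors < 0, na.rm = TRUE))
            msg <- c(msg, "impact factors must be >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' CorpusBundle: trials + publications + impact factors
#'
#' Container tying together the three inputs of the pipeline. See
#' [emptyTrials()] and [emptyPublications()] for the record schemas.
#'
#' @slot trials data.frame of trial records.
#' @slot publications data.frame of publication records.
#' @slot impactFactors an [ImpactFactorTable-class].
#' @export
setClass("CorpusBundle",
    representation(trials = "data.frame", publications = "data.frame",
                   impactFactors = "ImpactFactorTable"),
    prototype(trials = NULL, publications = NULL,
              impactFactors = new("ImpactFactorTable", factors = numeric(0))))

setValidity("CorpusBundle", function(object) {
    msg <- c(validateTrials(object@trials),
             validatePublications(object@publications))
    if (length(msg)) msg else TRUE
})

#' Construct a CorpusBundle
#' @param trials trial data.frame (see [emptyTrials()]).
#' @param publications publication data.frame (see [emptyPublications()]).
#' @param impactFactors an [ImpactFactorTable-class] or named numeric vector.
#' @return A [CorpusBundle-class].
#' @export
corpusBundle <- function(trials = emptyTrials(),
                         publications = emptyPublications(),
                         impactFactors = impactFactorTable(numeric(0))) {
    if (is.numeric(impactFactors))
        impactFactors <- impactFactorTable(impactFactors)
    new("CorpusBundle", trials = trials, publications = publications,
        impactFactors = impactFactors)
}

## Virtual parent for the two institution x disease aggregate matrices.
setClass("ProductivityMatrix",
    representation(values = "matrix", phase = "character", window = "numeric",
                   "VIRTUAL"))

validateProductivityMatrix <- function(object) {
    msg <- character(0)
    v <- object@values
    if (is.null(rownames(v)) && nrow(v) > 0)
        msg <- c(msg, "rows must be labelled by canonical institution id")
    if (is.null(colnames(v)) && ncol(v) > 0)
        msg <- c(msg, "columns must be labelled by disease id")
    if (any(v < 0, na.rm = TRUE))
        msg <- c(msg, "all entries must be >= 0")
    if (length(object@phase) != 1L ||
        !(object@phase %in% c(PHASE_LEVELS, "ALL")))
        msg <- c(msg, "phase must be one phase token or 'ALL'")
    if (length(object@window) %in% c(0L, 2L) == FALSE)
        msg <- c(msg, "window must be numeric(0) or c(start_year, end_year)")
    if (length(object@window) == 2L && object@window[1] > object@window[2])
        msg <- c(msg, "window start must be <= end")
    msg
}

#' CountMatrix: trial registrations per (institution, disease)
#'
#' Nonnegative integer counts of registered trials in one phase stratum and
#' date window. A multi-disease trial increments every one of its disease
#' columns; the `all_cancer` column counts each trial once, classifiable or
#' not.
#'
#' @slot values institution x disease integer matrix.
#' @slot phase phase token (or `"ALL"`) of the stratum.
#' @slot window numeric(2) year window, or numeric(0) for none.
#' @export
setClass("CountMatrix", contains = "ProductivityMatrix")

setValidity("CountMatrix", function(object) {
    msg <- validateProductivityMatrix(object)
    if (any(object@values != round(object@values), na.rm = TRUE))
        msg <- c(msg, "counts must be integers")
    if (length(msg)) msg else TRUE
})

#' SIFMatrix: summed impact factor per (institution, disease)
#'
#' Nonnegative reals: for each cell, the sum of the 2012 impact factors of
#' the journals of all matching published trials; 0 when no publication
#' matches.
#'
#' @slot values institution x disease numeric matrix.
#' @slot phase phase token (or `"ALL"`) of the stratum.
#' @slot window numeric(2) year window, or numeric(0) for none.
#' @export
setClass("SIFMatrix", contains = "ProductivityMatrix")

setValidity("SIFMatrix", function(object) {
    msg <- validateProductivityMatrix(object)
    if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix / SIFMatrix directly from a labelled matrix
#' @param values labelled institution x disease matrix.
#' @param phase phase token of the stratum (default `"P2"`).
#' @param window numeric(2) year window or numeric(0).
#' @return A [CountMatrix-class] (resp. [SIFMatrix-class]).
#' @export
countMatrix <- function(values, phase = "P2", window = numeric(0)) {
    storage.mode(values) <- "double"
    new("CountMatrix", values = values, phase = phase, window = as.numeric(window))
}

#' @rdname countMatrix
#' @export
sifMatrix <- function(values, phase = "P2", window = numeric(0)) {
    storage.mode(values) <- "double"
    new("SIFMatrix", values = values, phase = phase, window = as.numeric(window))
}

#' Scoreboard: composite productivity scores, maxima and ranks
#'
#' Per (institution, disease) composite score
#' `(SIF/maxSIF + Registrations/maxRegistrations) * 50` (a term with zero
#' disease maximum contributes 0), together with the per-disease maxima
#' and competition ranks (tied scores share a rank, the next rank skips).
#' Scores are stored unrounded; reporting rounds half-up to 2 decimals.
#'
#' @slot scores institution x disease numeric matrix in [0, 100].
#' @slot maxSif named per-disease maxima of summed impact factor.
#' @slot maxReg named per-disease maxima of registrations.
#' @slot ranks institution x disease integer competition ranks.
#' @slot phase phase stratum the scoreboard was built from.
#' @slot window year window.
#' @slot dropped disease ids removed by the activity floor.
#' @export
setClass("Scoreboard",
    representation(scores = "matrix", maxSif = "numeric", maxReg = "numeric",
                   ranks = "matrix", phase = "character", window = "numeric",
                   dropped = "character"))

setValidity("Scoreboard", function(object) {
    msg <- character(0)
    s <- object@scores
    if (any(s < -1e-9 | s > 100 + 1e-9, na.rm = TRUE))
        msg <- c(msg, "scores must lie in [0, 100]")
    if (!identical(dim(s), dim(object@ranks)))
        msg <- c(msg, "scores and ranks must have identical dimensions")
    if (!identical(colnames(s), names(object@maxSif)) ||
        !identical(colnames(s), names(object@maxReg)))
        msg <- c(msg, "maxima must be named by the score columns")
    if (length(msg)) msg else TRUE
})

setMethod("show", "DiseaseLexicon", function(object) {
    cat(sprintf("DiseaseLexicon with %d disease(s); all-cancer umbrella: '%s'\n",
                nrow(object@entries), object@allCancerMesh))
    if (nrow(object@entries))
        cat("  ", paste(utils::head(object@entries$disease, 8), collapse = ", "),
            if (nrow(object@entries) > 8) ", ..." else "", "\n", sep = "")
})

setMethod("show", "SynonymDictionary", function(object) {
    cat(sprintf("SynonymDictionary: %d canonical institution(s), %d synonym(s)\n",
                length(object@canonicalIds), length(object@mapping)))
})

setMethod("show", "ImpactFactorTable", function(object) {
    cat(sprintf("ImpactFactorTable with %d journal(s)\n", length(object@factors)))
})

setMethod("show", "CorpusBundle", function(object) {
    cat(sprintf("CorpusBundle: %d trial(s), %d publication(s), %d journal IF(s)\n",
                nrow(object@trials), nrow(object@publications),
                length(object@impactFactors@factors)))
})

setMethod("show", "CountMatrix", function(object) {
    cat(sprintf("CountMatrix [%d institution(s) x %d disease(s)], phase %s%s\n",
                nrow(object@values), ncol(object@values), object@phase,
                if (length(object@window))
                    sprintf(", window %d-%d", object@window[1], object@window[2])
                else ""))
})

setMethod("show", "SIFMatrix", function(object) {
    cat(sprintf("SIFMatrix [%d institution(s) x %d disease(s)], phase %s%s\n",
                nrow(object@values), ncol(object@values), object@phase,
                if (length(object@window))
                    sprintf(", window %d-%d", object@window[1], object@window[2])
                else ""))
})

setMethod("show", "Scoreboard", function(object) {
    cat(sprintf("Scoreboard: %d institution(s) x %d disease(s), phase %s\n",
                nrow(object@scores), ncol(object@scores), object@phase))
    if (length(object@dropped))
        cat("  dropped by activity floor:",
            paste(object@dropped, collapse = ", "), "\n")
})
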