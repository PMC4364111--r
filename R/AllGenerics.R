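#' Accessors for the aggregate containers
#'
#' `matrixValues()` returns the labelled institution x disease matrix of a
#' [CountMatrix-class], [SIFMatrix-class] or the score matrix of a
#' [Scoreboard-class]; `scoreRanks()` the per-disease competition ranks;
#' `diseaseMaxima()` the per-disease maxima used in the score
#' normalization.
#'
#' @param x the object.
#' @return `matrixValues`: a numeric matrix; `scoreRanks`: an integer
#'   matrix; `diseaseMaxima`: a list with elements `maxSif` and `maxReg`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))

#' @rdname accessors
#' @export
setMethod("matrixValues", "ProductivityMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("matrixValues", "Scoreboard", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("scoreRanks", function(x) standardGeneric("scoreRanks"))

#' @rdname accessors
#' @export
setMethod("scoreRanks", "Scoreboard", function(x) x@ranks)

#' @rdname accessors
#' @export
setGeneric("diseaseMaxima", function(x) standardGeneric("diseaseMaxima"))

#' @rdname accessors
#' @export
setMethod("diseaseMaxima", "Scoreboard",
          function(x) list(maxSif = x@maxSif, maxReg = x@maxReg))

#' @rdname accessors
#' @export
setGeneric("lexiconDiseases", function(x) standardGeneric("lexiconDiseases"))

#' @rdname accessors
#' @export
setMethod("lexiconDiseases", "DiseaseLexicon",
          function(x) x@entries$disease)

#' @rdname accessors
#' @export
setGeneric("canonicalInstitutions",
           function(x) standardGeneric("canonicalInstitutions"))

#' @rdname accessors
#' @export
setMethod("canonicalInstitutions", "SynonymDictionary",
          function(x) x@canonicalIds)

#' Tally top-k appearances and first ranks per institution
#'
#' Counts, per institution, the number of diseases in which it appears in
#' the top-`k` list (ties included) and the number of diseases in which it
#' is top-ranked (co-ranked firsts each count). Methods exist for a
#' [Scoreboard-class] and for an already-ranked long table
#' (`disease`, `institution`, `score`), e.g. a transcribed published
#' ranking.
#'
#' @param x a Scoreboard or a data.frame with columns `disease`,
#'   `institution`, `score`.
#' @param k the list depth (default 10).
#' @param ... passed to methods; the data.frame method accepts
#'   `institutions`, a character vector extending the tally to
#'   institutions that never appear.
#' @return data.frame with columns `institution`, `appearances`, `firsts`.
#' @export
setGeneric("appearanceTally", function(x, k = 10, ...)
    standardGeneric("appearanceTally"))
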