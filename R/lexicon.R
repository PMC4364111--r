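## Disease assignment. Keywords are case-insensitive literal substring
## tests (deliberately naive: no word boundaries unless asked for); the
## bounded-gap regex uses the common "." / "{m,n}" dialect with dot not
## matching newlines. Text is whitespace-normalized before matching so a
## 100-character gap is measured in normalized text.

normalizeMatchText <- function(text) {
    tolower(gsub("\\s+", " ", text))
}

#' Compile a DiseaseLexicon into a matcher
#'
#' Validates every gap regex up front (an invalid pattern raises an error
#' naming the disease) and lowercases keywords once; compilation is
#' independent of any input text.
#'
#' @param lexicon a [DiseaseLexicon-class].
#' @param wordBoundary if `TRUE`, keywords only match when not embedded in
#'   a longer alphabetic token (default `FALSE`: plain substring).
#' @return an object of class `"compiledLexicon"`.
#' @export
compileLexicon <- function(lexicon, wordBoundary = FALSE) {
    stopifnot(is(lexicon, "DiseaseLexicon"))
    e <- lexicon@entries
    entries <- lapply(seq_len(nrow(e)), function(i) {
        rx <- e$regex[i]
        if (!is.na(rx)) {
            ok <- tryCatch({suppressWarnings(grepl(rx, "", perl = TRUE)); TRUE},
                           error = function(err) err)
            if (!isTRUE(ok))
                stop(sprintf("invalid gap regex for disease '%s': %s",
                             e$disease[i], conditionMessage(ok)),
                     call. = FALSE)
        }
        kw <- tolower(e$keywords[[i]])
        kwPatterns <- NULL
        if (wordBoundary && length(kw))
            kwPatterns <- paste0("(?<![a-z])",
                                 vapply(kw, function(k)
                                     gsub("([][{}()*+?.\\^$|])", "\\\\\\1", k),
                                     character(1)),
                                 "(?![a-z])")
        list(disease = e$disease[i], keywords = kw,
             keywordPatterns = kwPatterns, regex = rx,
             mesh = e$mesh[[i]])
    })
    structure(list(entries = entries, wordBoundary = wordBoundary,
                   lexicon = lexicon),
              class = "compiledLexicon")
}

matchEntry <- function(entry, text, wordBoundary) {
    fired <- character(0)
    if (length(entry$keywords)) {
        if (wordBoundary) {
            hit <- vapply(entry$keywordPatterns, grepl, logical(1), x = text,
                          perl = TRUE)
        } else {
            hit <- vapply(entry$keywords, grepl, logical(1), x = text,
                          fixed = TRUE)
        }
        fired <- c(fired, entry$keywords[hit])
    }
    if (!is.na(entry$regex) &&
        grepl(entry$regex, text, ignore.case = TRUE, perl = TRUE))
        fired <- c(fired, entry$regex)
    fired
}

#' Classify a text against the compiled lexicon
#'
#' Multi-label by construction: returns every disease for which any
#' keyword or the gap regex matches. Empty text yields an empty set.
#'
#' @param text a single character string.
#' @param matcher a compiled lexicon from [compileLexicon()].
#' @return character vector of disease ids (possibly empty).
#' @examples
#' lex <- diseaseLexicon("urothelial",
#'     list(c("urothelial cancer", "bladder cancer", "ureteral cancer")),
#'     NA, list("Urinary Bladder Neoplasms"))
#' classifyText("A study in metastatic urothelial cancer",
#'               compileLexicon(lex))
#' @export
classifyText <- function(text, matcher) {
    stopifnot(inherits(matcher, "compiledLexicon"))
    if (is.na(text) || !nzchar(text)) return(character(0))
    norm <- normalizeMatchText(text)
    hits <- vapply(matcher$entries, function(entry)
        length(matchEntry(entry, norm, matcher$wordBoundary)) > 0L,
        logical(1))
    vapply(matcher$entries[hits], `[[`, character(1), "disease")
}

#' Classify one trial record
#'
#' Applies [classifyText()] to the single-space concatenation of the
#' title, all condition strings, and the description, and records which
#' patterns fired for audit.
#'
#' @param trial a one-row trial data.frame.
#' @param matcher a compiled lexicon.
#' @return list with `record_id`, `diseases` (character vector) and
#'   `matched_patterns` (data.frame `disease`, `pattern`).
#' @export
classifyTrial <- function(trial, matcher) {
    text <- paste(c(trial$title, trial$conditions[[1]], trial$description),
                  collapse = " ")
    norm <- normalizeMatchText(text)
    pats <- lapply(matcher$entries, matchEntry, text = norm,
                   wordBoundary = matcher$wordBoundary)
    n <- vapply(pats, length, 1L)
    diseases <- vapply(matcher$entries, `[[`, character(1), "disease")
    list(record_id = trial$trial_id,
         diseases = diseases[n > 0L],
         matched_patterns = data.frame(
             disease = rep(diseases, n),
             pattern = unlist(pats),
             stringsAsFactors = FALSE, row.names = NULL))
}

#' Classify all trials of a corpus
#'
#' @param trials trial data.frame.
#' @param matcher a compiled lexicon.
#' @return list (one element per trial) of character vectors of disease
#'   ids, named by `trial_id`.
#' @export
classifyTrials <- function(trials, matcher) {
    out <- lapply(seq_len(nrow(trials)), function(i)
        classifyTrial(trials[i, ], matcher)$diseases)
    names(out) <- trials$trial_id
    out
}

#' Does a publication belong to a disease (by MeSH)?
#'
#' TRUE iff any of the publication's MeSH descriptors equals
#' (case-insensitively) one of the disease's MeSH terms. For the special
#' id `"all_cancer"`, TRUE iff any descriptor falls under the configured
#' neoplasms umbrella: it contains the umbrella stem (e.g. "Neoplasms")
#' case-insensitively, or equals one of the lexicon's disease MeSH terms
#' (which are cancer terms by construction, covering descriptors like
#' "Melanoma" that do not carry the stem).
#'
#' @param pub a one-row publication data.frame.
#' @param lexicon a [DiseaseLexicon-class].
#' @param disease a disease id present in the lexicon, or `"all_cancer"`.
#' @param majorTopicOnly if `TRUE`, only major-topic MeSH terms count
#'   (default `FALSE`: any MeSH term).
#' @return logical(1).
#' @export
classifyPublication <- function(pub, lexicon, disease,
                                majorTopicOnly = FALSE) {
    terms <- pub$mesh_terms[[1]]
    if (majorTopicOnly) terms <- terms[meshIsMajor(terms)]
    if (!length(terms)) return(FALSE)
    desc <- tolower(meshDescriptor(terms))
    if (identical(disease, "all_cancer")) {
        allMesh <- tolower(unlist(lexicon@entries$mesh))
        return(any(grepl(tolower(lexicon@allCancerMesh), desc,
                         fixed = TRUE)) ||
               any(desc %in% allMesh))
    }
    e <- lexicon@entries
    i <- match(disease, e$disease)
    if (is.na(i)) stop("unknown disease id: ", disease)
    any(desc %in% tolower(e$mesh[[i]]))
}
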