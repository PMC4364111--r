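## PubMed-syntax query construction and its local-corpus analogue. The
## live registries are never contacted: queries are built in PubMed syntax
## for the record, and evaluated against local publication corpora by
## matchPublicationQuery().

QUERY_PHASE_LABEL <- c(
    EARLY_1 = "Clinical trial, Phase I",
    P1   = "Clinical trial, Phase I",
    P1_2 = "Clinical trial, Phase I/II",
    P2   = "Clinical trial, Phase II",
    P2_3 = "Clinical trial, Phase II/III",
    P3   = "Clinical trial, Phase III",
    P4   = "Clinical trial, Phase IV"
)

#' Build a PubMed-syntax query string
#'
#' Emits `"(s1[AD] OR s2[AD] OR ...) Y1:Y2[DP] <phase>[PT] <mesh>[MESH]"`,
#' with the phase and MeSH clauses omitted when the corresponding argument
#' is absent.
#'
#' @param institutionSynonyms character vector of affiliation synonyms
#'   (at least one).
#' @param diseaseMesh MeSH term for the disease clause, or `NULL`.
#' @param phase phase token for the publication-type clause, or `NULL`.
#' @param window integer vector `c(start_year, end_year)`.
#' @return length-1 character query string.
#' @examples
#' buildPubmedQuery(c("Barnes-Jewish Hospital", "Washington University",
#'                    "Alvin J. Siteman Cancer Center"),
#'                  "uterine cervical neoplasms", "P2", c(2008, 2013))
#' @export
buildPubmedQuery <- function(institutionSynonyms, diseaseMesh = NULL,
                             phase = NULL, window) {
    if (!length(institutionSynonyms))
        stop("at least one institution synonym is required")
    stopifnot(length(window) == 2L, window[1] <= window[2])
    q <- sprintf("(%s) %d:%d[DP]",
                 paste0(institutionSynonyms, "[AD]", collapse = " OR "),
                 as.integer(window[1]), as.integer(window[2]))
    if (!is.null(phase)) {
        if (!phase %in% names(QUERY_PHASE_LABEL))
            stop("no publication-type clause for phase token: ", phase)
        q <- paste0(q, " ", QUERY_PHASE_LABEL[[phase]], "[PT]")
    }
    if (!is.null(diseaseMesh))
        q <- paste0(q, " ", diseaseMesh, "[MESH]")
    q
}

#' Evaluate a query against one local publication record
#'
#' The local-corpus analogue of the PubMed search: TRUE iff (any synonym
#' occurs case-insensitively as a substring of any affiliation line) AND
#' (publication year within the window, inclusive) AND (phase absent, or
#' some publication type equals the phase's publication-type string,
#' case-insensitively) AND (disease absent, or [classifyPublication()] is
#' TRUE). Every affiliation line is eligible, not only the first.
#'
#' @param pub a one-row publication data.frame.
#' @param institutionSynonyms character vector of affiliation synonyms.
#' @param window integer `c(start_year, end_year)`.
#' @param phase phase token or `NULL`.
#' @param disease disease id (or `"all_cancer"`) or `NULL`.
#' @param lexicon a [DiseaseLexicon-class] (required when `disease` given).
#' @param majorTopicOnly passed to [classifyPublication()].
#' @return logical(1).
#' @export
matchPublicationQuery <- function(pub, institutionSynonyms, window,
                                  phase = NULL, disease = NULL,
                                  lexicon = NULL, majorTopicOnly = FALSE) {
    if (!length(institutionSynonyms))
        stop("at least one institution synonym is required")
    stopifnot(length(window) == 2L, window[1] <= window[2])
    affil <- tolower(pub$affiliations[[1]])
    if (!length(affil)) return(FALSE)
    syn <- tolower(institutionSynonyms)
    if (!any(vapply(syn, function(s) any(grepl(s, affil, fixed = TRUE)),
                    logical(1))))
        return(FALSE)
    yr <- pub$pub_year
    if (is.na(yr) || yr < window[1] || yr > window[2]) return(FALSE)
    if (!is.null(phase)) {
        pts <- tolower(pub$pub_types[[1]])
        if (!tolower(phasePubType(phase)) %in% pts) return(FALSE)
    }
    if (!is.null(disease)) {
        if (is.null(lexicon))
            stop("a lexicon is required for the disease clause")
        if (!classifyPublication(pub, lexicon, disease, majorTopicOnly))
            return(FALSE)
    }
    TRUE
}

#' Most recently started unclassified trials
#'
#' Returns the `n` trials without any assigned disease that have the
#' latest start dates (ties broken by `trial_id` ascending; trials without
#' a start date sort last). Mirrors a manual-audit workflow: reviewing the
#' most recent unclassified registrations to estimate what the lexicon
#' misses.
#'
#' @param trials trial data.frame.
#' @param classifications list of disease-label vectors as returned by
#'   [classifyTrials()] (same order/length as `trials`).
#' @param n number of trials to return; fewer available returns all.
#' @return a trial data.frame, ordered.
#' @export
sampleUnclassified <- function(trials, classifications, n) {
    stopifnot(n >= 1, length(classifications) == nrow(trials))
    unclassified <- vapply(classifications, length, 1L) == 0L
    sub <- trials[unclassified, , drop = FALSE]
    if (!nrow(sub)) return(sub)
    ## latest first; undated trials last; ties by trial_id ascending
    key <- ifelse(is.na(sub$start_date), -Inf, as.numeric(sub$start_date))
    sub <- sub[order(-key, sub$trial_id), , drop = FALSE]
    utils::head(sub, n)
}
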