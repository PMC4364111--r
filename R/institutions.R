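## Institution name resolution: exact lookup after normalization, never
## fuzzy — fuzzy matching would silently merge distinct centers, and
## full-string matching is what keeps "Washington University" (St. Louis)
## apart from "University of Washington" (Seattle).

#' Normalize an institution name
#'
#' Casefolds, replaces punctuation with spaces, collapses whitespace runs,
#' and trims. Idempotent.
#'
#' @param raw character vector of raw names.
#' @return character vector of normalized names.
#' @examples
#' normalizeName("Alvin J. Siteman Cancer Center ")
#' @export
normalizeName <- function(raw) {
    x <- tolower(as.character(raw))
    x <- gsub("[^a-z0-9]+", " ", x)
    trimws(x)
}

#' Construct a SynonymDictionary
#'
#' @param synonyms data.frame with columns `synonym` and `canonical`, one
#'   row per synonym; canonical ids are added as synonyms of themselves.
#' @return A [SynonymDictionary-class].
#' @examples
#' d <- synonymDictionary(data.frame(
#'     synonym = c("Alvin J. Siteman Cancer Center", "Washington University"),
#'     canonical = "Barnes-Jewish Hospital"))
#' resolveInstitution("washington university", d)
#' @export
synonymDictionary <- function(synonyms) {
    stopifnot(all(c("synonym", "canonical") %in% names(synonyms)))
    canonical <- unique(as.character(synonyms$canonical))
    raw <- rbind(
        data.frame(synonym = canonical, canonical = canonical,
                   stringsAsFactors = FALSE),
        data.frame(synonym = as.character(synonyms$synonym),
                   canonical = as.character(synonyms$canonical),
                   stringsAsFactors = FALSE))
    keys <- normalizeName(raw$synonym)
    dup <- duplicated(keys)
    raw <- raw[!dup, , drop = FALSE]
    keys <- keys[!dup]
    mapping <- stats::setNames(raw$canonical, keys)
    new("SynonymDictionary", canonicalIds = canonical, mapping = mapping,
        raw = raw)
}

#' Resolve a free-text institution name to its canonical id
#'
#' Exact lookup of the normalized name; anything not in the dictionary
#' returns `"UNRESOLVED"`. Unresolved records are excluded from
#' institution-level tallies but still counted in corpus totals.
#'
#' @param raw character vector of raw institution names.
#' @param dict a [SynonymDictionary-class].
#' @return character vector of canonical ids or `"UNRESOLVED"`.
#' @export
resolveInstitution <- function(raw, dict) {
    out <- unname(dict@mapping[normalizeName(raw)])
    out[is.na(out)] <- "UNRESOLVED"
    out
}

#' Raw synonym strings for one canonical institution
#'
#' Used to build affiliation clauses of publication queries.
#'
#' @param dict a [SynonymDictionary-class].
#' @param canonical a canonical institution id.
#' @return character vector of raw synonym strings (the canonical name
#'   first).
#' @export
institutionSynonyms <- function(dict, canonical) {
    if (!canonical %in% dict@canonicalIds)
        stop("unknown canonical institution: ", canonical)
    dict@raw$synonym[dict@raw$canonical == canonical]
}
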