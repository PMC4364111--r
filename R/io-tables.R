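## CSV readers for the lexicon, synonym, impact-factor and matrix schemas,
## and the matrix writer used for the full per-phase report tables.

#' Normalize a journal title for impact-factor lookup
#'
#' Casefolds, trims surrounding whitespace, and strips trailing periods —
#' the dominant sources of join failure between MEDLINE journal titles and
#' published impact-factor lists.
#'
#' @param x character vector of journal titles.
#' @return character vector of normalized keys.
#' @export
normalizeJournal <- function(x) {
    x <- tolower(trimws(as.character(x)))
    sub("\\.+$", "", x)
}

#' Construct an ImpactFactorTable
#'
#' @param factors numeric vector of impact factors named by journal title
#'   (titles are normalized with [normalizeJournal()]).
#' @return An [ImpactFactorTable-class].
#' @export
impactFactorTable <- function(factors) {
    if (length(factors)) names(factors) <- normalizeJournal(names(factors))
    factors <- factors[!duplicated(names(factors))]
    new("ImpactFactorTable", factors = factors)
}

#' Look up impact factors by journal title
#'
#' Journals absent from the table yield 0 (with a warning naming them), so
#' an unlisted journal never breaks an aggregation — it simply contributes
#' nothing.
#'
#' @param table an [ImpactFactorTable-class].
#' @param journals character vector of (raw) journal titles.
#' @param warn warn about unknown journals (default TRUE).
#' @return numeric vector of impact factors (0 for unknown journals).
#' @export
lookupImpactFactor <- function(table, journals, warn = TRUE) {
    keys <- normalizeJournal(journals)
    out <- unname(table@factors[keys])
    unknown <- is.na(out)
    if (any(unknown) && warn)
        warning("journal(s) missing from impact-factor table: ",
                paste(unique(journals[unknown]), collapse = ", "),
                call. = FALSE)
    out[unknown] <- 0
    out
}

TABLE_SCHEMAS <- list(
    lexicon = c("disease"),            # plus kw1..kw8, regex, mesh
    synonyms = c("synonym", "canonical"),
    impact_factors = c("journal", "if2012")
)

#' Read one of the pipeline's typed CSV tables
#'
#' @param source CSV file path with a header row.
#' @param schema one of `"lexicon"` (columns `disease`, `kw1`..`kw8`,
#'   `regex`, `mesh`; `mesh` holds `;`-separated descriptors),
#'   `"synonyms"` (`synonym`, `canonical`), `"impact_factors"`
#'   (`journal`, `if2012`), or `"matrix"` (first column = institution id,
#'   remaining columns one per disease).
#' @return for `"lexicon"` a [DiseaseLexicon-class]; for `"synonyms"` a
#'   [SynonymDictionary-class]; for `"impact_factors"` an
#'   [ImpactFactorTable-class]; for `"matrix"` a labelled numeric matrix.
#' @export
readTable <- function(source,
                      schema = c("lexicon", "synonyms", "impact_factors",
                                 "matrix")) {
    schema <- match.arg(schema)
    if (!file.exists(source))
        stop("table not found: ", source)
    df <- utils::read.csv(source, stringsAsFactors = FALSE,
                          check.names = FALSE)
    if (schema != "matrix") {
        need <- TABLE_SCHEMAS[[schema]]
        if (!all(need %in% names(df)))
            stop(sprintf("schema '%s' expects columns {%s}; found {%s}",
                         schema, paste(need, collapse = ", "),
                         paste(names(df), collapse = ", ")))
    }
    switch(schema,
        lexicon = {
            kwcols <- intersect(paste0("kw", 1:8), names(df))
            if (!"mesh" %in% names(df))
                stop("schema 'lexicon' expects a 'mesh' column")
            keywords <- lapply(seq_len(nrow(df)), function(i) {
                kw <- unlist(df[i, kwcols], use.names = FALSE)
                kw <- trimws(as.character(kw))
                kw[!is.na(kw) & nzchar(kw)]
            })
            mesh <- lapply(strsplit(as.character(df$mesh), ";", fixed = TRUE),
                           function(m) trimws(m[nzchar(trimws(m))]))
            rx <- if ("regex" %in% names(df)) as.character(df$regex)
                  else rep(NA_character_, nrow(df))
            rx[!is.na(rx) & !nzchar(trimws(rx))] <- NA_character_
            diseaseLexicon(df$disease, keywords, rx, mesh)
        },
        synonyms = synonymDictionary(df),
        impact_factors = impactFactorTable(
            stats::setNames(as.numeric(df$if2012), df$journal)),
        matrix = {
            m <- as.matrix(df[, -1, drop = FALSE])
            rownames(m) <- as.character(df[[1]])
            storage.mode(m) <- "double"
            m
        })
}

#' Write an institution x disease matrix as CSV
#'
#' One header row (first column `institution`), one row per institution,
#' values at full precision; [readTable()] with `schema = "matrix"` reads
#' it back losslessly.
#'
#' @param matrix labelled numeric matrix.
#' @param dest output file path.
#' @return `dest`, invisibly.
#' @export
writeMatrix <- function(matrix, dest) {
    vals <- as.data.frame(matrix, check.names = FALSE)
    ## %.17g guarantees a lossless double -> text -> double round trip
    vals[] <- lapply(vals, function(col) sprintf("%.17g", col))
    df <- data.frame(institution = rownames(matrix), vals,
                     check.names = FALSE, stringsAsFactors = FALSE)
    ok <- tryCatch({
        utils::write.csv(df, dest, row.names = FALSE)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
        stop("cannot write matrix to '", dest, "': ", conditionMessage(ok))
    invisible(dest)
}
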