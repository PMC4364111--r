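## MEDLINE tagged-field text: 4-character tag, "- ", value; continuation
## lines indented with 6 spaces; records separated by blank lines. The
## PubMed XML dialect is accepted as an alternative input. No installed R
## package parses the tagged format, so the parser lives here.

splitMedlineRecords <- function(lines) {
    blank <- grepl("^\\s*$", lines)
    grp <- cumsum(blank)
    recs <- split(lines[!blank], grp[!blank])
    recs[vapply(recs, length, 1L) > 0L]
}

parseMedlineRecord <- function(rl) {
    tagged <- grepl("^[A-Z0-9]{1,4} *- ", rl)
    ## fold continuation lines (6-space indent) into the preceding tag
    idx <- cumsum(tagged)
    keep <- idx > 0
    fields <- vapply(split(rl[keep], idx[keep]), function(chunk) {
        paste(trimws(sub("^[A-Z0-9]{1,4} *- ", "", chunk)), collapse = " ")
    }, character(1))
    tags <- sub("^([A-Z0-9]{1,4}) *- .*$", "\\1", rl[tagged])
    names(fields) <- NULL
    data <- split(fields, tags)[unique(tags)]
    names(data) <- unique(tags)
    data
}

#' Read MEDLINE-style publication records
#'
#' Accepts MEDLINE tagged-field text (`PMID-`, `JT  -`, `DP  -`, `PT  -`,
#' `MH  -`, `AD  -`) or PubMed XML. MeSH major-topic asterisks are kept in
#' the stored term strings (see [meshDescriptor()] / [meshIsMajor()]).
#' Citations lacking a PMID are skipped with a warning.
#'
#' @param source path to a tagged-text file (or PubMed XML file).
#' @return a publication data.frame (see [emptyPublications()]).
#' @export
readMedline <- function(source) {
    if (length(source) != 1L || !file.exists(source))
        stop("MEDLINE source not found: ", source)
    first <- readLines(source, n = 1L, warn = FALSE)
    if (length(first) && grepl("^\\s*<", first))
        return(readPubmedXML(source))
    lines <- readLines(source, warn = FALSE)
    recs <- splitMedlineRecords(lines)
    if (!length(recs)) return(emptyPublications())
    rows <- lapply(recs, function(rl) {
        d <- parseMedlineRecord(rl)
        if (is.null(d$PMID) || !nzchar(d$PMID[1])) {
            warning("citation without PMID skipped", call. = FALSE)
            return(NULL)
        }
        year <- suppressWarnings(as.integer(substr(d$DP[1], 1, 4)))
        data.frame(
            pmid = d$PMID[1],
            journal_title = if (is.null(d$JT)) NA_character_ else d$JT[1],
            pub_year = if (is.null(d$DP)) NA_integer_ else year,
            pub_types = I(list(if (is.null(d$PT)) character(0) else unname(d$PT))),
            mesh_terms = I(list(if (is.null(d$MH)) character(0) else unname(d$MH))),
            affiliations = I(list(if (is.null(d$AD)) character(0) else unname(d$AD))),
            stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(emptyPublications())
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

readPubmedXML <- function(source) {
    doc <- xml2::read_xml(source)
    arts <- xml2::xml_find_all(doc, "//PubmedArticle")
    if (!length(arts)) return(emptyPublications())
    rows <- lapply(arts, function(a) {
        pmid <- xmlTextOrNA(a, ".//MedlineCitation/PMID")
        if (is.na(pmid) || !nzchar(pmid)) {
            warning("citation without PMID skipped", call. = FALSE)
            return(NULL)
        }
        year <- suppressWarnings(as.integer(
            xmlTextOrNA(a, ".//JournalIssue/PubDate/Year")))
        mh <- vapply(xml2::xml_find_all(a, ".//MeshHeading"), function(h) {
            dn <- xml2::xml_find_first(h, "./DescriptorName")
            major <- identical(xml2::xml_attr(dn, "MajorTopicYN"), "Y")
            paste0(if (major) "*" else "", trimws(xml2::xml_text(dn)))
        }, character(1))
        data.frame(
            pmid = pmid,
            journal_title = xmlTextOrNA(a, ".//Journal/Title"),
            pub_year = year,
            pub_types = I(list(trimws(xml2::xml_text(
                xml2::xml_find_all(a, ".//PublicationType"))))),
            mesh_terms = I(list(mh)),
            affiliations = I(list(trimws(xml2::xml_text(
                xml2::xml_find_all(a, ".//AffiliationInfo/Affiliation"))))),
            stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(emptyPublications())
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write publication records as MEDLINE tagged-field text
#'
#' Inverse of [readMedline()] for the tagged dialect; records are blank-line
#' separated.
#'
#' @param pubs publication data.frame.
#' @param dest output file path.
#' @return `dest`, invisibly.
#' @export
writeMedline <- function(pubs, dest) {
    fmt <- function(tag, values) {
        values <- values[!is.na(values)]
        if (!length(values)) return(character(0))
        sprintf("%-4s- %s", tag, values)
    }
    blocks <- lapply(seq_len(nrow(pubs)), function(i) {
        r <- pubs[i, ]
        c(fmt("PMID", r$pmid),
          fmt("JT", r$journal_title),
          fmt("DP", if (is.na(r$pub_year)) NA_character_
                    else as.character(r$pub_year)),
          fmt("PT", r$pub_types[[1]]),
          fmt("MH", r$mesh_terms[[1]]),
          fmt("AD", r$affiliations[[1]]),
          "")
    })
    out <- unlist(blocks)
    writeLines(if (is.null(out)) character(0) else out, dest)
    invisible(dest)
}

#' MeSH term helpers
#'
#' Stored MeSH strings keep the MEDLINE conventions: a leading `*` (or a
#' `/*qualifier`) marks a major topic; `meshDescriptor()` strips the
#' asterisk and any qualifier, `meshIsMajor()` reports the flag.
#'
#' @param terms character vector of raw MeSH term strings.
#' @return `meshDescriptor`: character vector of descriptors;
#'   `meshIsMajor`: logical vector.
#' @export
meshDescriptor <- function(terms) {
    sub("/.*$", "", sub("^\\*", "", terms))
}

#' @rdname meshDescriptor
#' @export
meshIsMajor <- function(terms) {
    grepl("^\\*", terms) | grepl("/\\*", terms)
}
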