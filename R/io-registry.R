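## Readers/writers for the ClinicalTrials.gov legacy full-study XML dialect
## (one <clinical_study> element per record; files may hold one study or a
## <clinical_studies> wrapper with many).

#' Parse a registry date string
#'
#' Registry start dates come as `"Month YYYY"` or `"Month DD, YYYY"`.
#' A month-only date resolves to the first day of that month, which keeps
#' "most recently started" ordering deterministic and monotone with the
#' true dates. Unparseable or empty strings yield `NA`.
#'
#' @param x character vector of raw date strings.
#' @return a Date vector.
#' @export
parseRegistryDate <- function(x) {
    x <- trimws(as.character(x))
    out <- rep(as.Date(NA), length(x))
    full <- grepl("^[A-Za-z]+ +[0-9]{1,2}, +[0-9]{4}$", x)
    mon <- grepl("^[A-Za-z]+ +[0-9]{4}$", x)
    parseOne <- function(month_name, day, year) {
        m <- match(tolower(month_name), tolower(month.name))
        if (is.na(m)) return(as.Date(NA))
        as.Date(sprintf("%04d-%02d-%02d", as.integer(year), m, as.integer(day)))
    }
    for (i in which(full)) {
        parts <- regmatches(x[i],
            regexec("^([A-Za-z]+) +([0-9]{1,2}), +([0-9]{4})$", x[i]))[[1]]
        out[i] <- parseOne(parts[2], parts[3], parts[4])
    }
    for (i in which(mon)) {
        parts <- regmatches(x[i], regexec("^([A-Za-z]+) +([0-9]{4})$", x[i]))[[1]]
        out[i] <- parseOne(parts[2], 1L, parts[3])
    }
    out
}

xmlTextOrNA <- function(node, xpath) {
    hit <- xml2::xml_find_first(node, xpath)
    if (inherits(hit, "xml_missing")) NA_character_
    else trimws(xml2::xml_text(hit))
}

parseStudyNode <- function(study) {
    title <- xmlTextOrNA(study, "./brief_title")
    if (is.na(title)) title <- xmlTextOrNA(study, "./official_title")
    conditions <- trimws(xml2::xml_text(
        xml2::xml_find_all(study, "./condition")))
    desc <- c(xmlTextOrNA(study, "./brief_summary/textblock"),
              xmlTextOrNA(study, "./detailed_description/textblock"))
    desc <- paste(desc[!is.na(desc)], collapse = " ")
    enrol <- xmlTextOrNA(study, "./enrollment")
    data.frame(
        trial_id = xmlTextOrNA(study, "./id_info/nct_id"),
        title = title,
        conditions = I(list(conditions)),
        description = desc,
        start_date = parseRegistryDate(xmlTextOrNA(study, "./start_date")),
        phase_label = normalizePhase(xmlTextOrNA(study, "./phase")),
        lead_institution_raw = xmlTextOrNA(study, ".//lead_sponsor/agency"),
        enrollment = if (is.na(enrol)) NA_integer_ else as.integer(enrol),
        status = xmlTextOrNA(study, "./overall_status"),
        funding_source = xmlTextOrNA(study, ".//lead_sponsor/agency_class"),
        stringsAsFactors = FALSE)
}

#' Read registry records from legacy full-study XML
#'
#' Accepts a single XML file, a directory of XML files, or a `.zip` of
#' such files. Each `<clinical_study>` element becomes one trial record;
#' missing optional elements yield `NA` fields, never failure.
#'
#' @param source path to an XML file, a directory, or a zip archive.
#' @return a trial data.frame (see [emptyTrials()] for the schema).
#' @export
readRegistryXML <- function(source) {
    if (length(source) != 1L || !file.exists(source))
        stop("registry source not found: ", source)
    files <- source
    if (dir.exists(source)) {
        files <- list.files(source, pattern = "\\.xml$", full.names = TRUE,
                            ignore.case = TRUE)
        files <- sort(files)
    } else if (grepl("\\.zip$", source, ignore.case = TRUE)) {
        exdir <- tempfile("registry_zip_")
        utils::unzip(source, exdir = exdir)
        files <- sort(list.files(exdir, pattern = "\\.xml$",
                                 full.names = TRUE, recursive = TRUE,
                                 ignore.case = TRUE))
    }
    if (!length(files)) return(emptyTrials())
    recs <- lapply(files, function(f) {
        doc <- tryCatch(xml2::read_xml(f),
                        error = function(e) stop("malformed registry XML in '",
                                                 f, "': ", conditionMessage(e),
                                                 call. = FALSE))
        studies <- xml2::xml_find_all(doc, "//clinical_study")
        if (!length(studies)) return(emptyTrials())
        do.call(rbind, lapply(studies, parseStudyNode))
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    if (is.null(out)) emptyTrials() else out
}

xmlEscape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

formatRegistryDate <- function(d) {
    ifelse(is.na(d), NA_character_,
           paste(month.name[as.integer(format(d, "%m"))],
                 paste0(as.integer(format(d, "%d")), ","),
                 format(d, "%Y")))
}

PHASE_RAW_OUT <- c("NA" = "N/A", EARLY_1 = "Early Phase 1", P1 = "Phase 1",
                   P1_2 = "Phase 1/Phase 2", P2 = "Phase 2",
                   P2_3 = "Phase 2/Phase 3", P3 = "Phase 3", P4 = "Phase 4")

#' Write trial records as legacy full-study XML
#'
#' Inverse of [readRegistryXML()]: emits one file with a
#' `<clinical_studies>` root wrapping one `<clinical_study>` per record.
#' `NA` optional fields are omitted.
#'
#' @param trials trial data.frame.
#' @param dest output file path.
#' @return `dest`, invisibly.
#' @export
writeRegistryXML <- function(trials, dest) {
    tag <- function(name, value, indent = "    ") {
        if (length(value) != 1L || is.na(value)) return(character(0))
        sprintf("%s<%s>%s</%s>", indent, name, xmlEscape(value), name)
    }
    lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
               "<clinical_studies>")
    for (i in seq_len(nrow(trials))) {
        r <- trials[i, ]
        lines <- c(lines, "  <clinical_study>",
            "    <id_info>", tag("nct_id", r$trial_id, "      "), "    </id_info>",
            tag("brief_title", r$title),
            unlist(lapply(r$conditions[[1]], tag, name = "condition")),
            if (!is.na(r$description) && nzchar(r$description))
                c("    <brief_summary>",
                  tag("textblock", r$description, "      "),
                  "    </brief_summary>"),
            tag("start_date", formatRegistryDate(r$start_date)),
            tag("phase", unname(PHASE_RAW_OUT[r$phase_label])),
            "    <sponsors>", "      <lead_sponsor>",
            tag("agency", r$lead_institution_raw, "        "),
            tag("agency_class", r$funding_source, "        "),
            "      </lead_sponsor>", "    </sponsors>",
            tag("enrollment", if (is.na(r$enrollment)) NA_character_
                              else as.character(r$enrollment)),
            tag("overall_status", r$status),
            "  </clinical_study>")
    }
    lines <- c(lines, "</clinical_studies>")
    writeLines(lines, dest)
    invisible(dest)
}
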