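## Phase vocabulary handling: normalization of raw registry strings,
## stratum membership under the combined/highest policies, and the MEDLINE
## publication-type string for each token.

RAW_PHASE_MAP <- c(
    "early phase 1" = "EARLY_1",
    "phase 0"       = "EARLY_1",
    "phase 1"       = "P1",
    "phase 1/phase 2" = "P1_2",
    "phase 1 / phase 2" = "P1_2",
    "phase 1/2"     = "P1_2",
    "phase 2"       = "P2",
    "phase 2/phase 3" = "P2_3",
    "phase 2 / phase 3" = "P2_3",
    "phase 2/3"     = "P2_3",
    "phase 3"       = "P3",
    "phase 4"       = "P4",
    "n/a"           = "NA",
    "na"            = "NA"
)

PHASE_PUB_TYPE <- c(
    EARLY_1 = "Clinical Trial, Phase I",
    P1   = "Clinical Trial, Phase I",
    P1_2 = "Clinical Trial, Phase I/II",
    P2   = "Clinical Trial, Phase II",
    P2_3 = "Clinical Trial, Phase II/III",
    P3   = "Clinical Trial, Phase III",
    P4   = "Clinical Trial, Phase IV"
)

#' Normalize raw registry phase strings onto the closed vocabulary
#'
#' Mapping is total: every raw string maps to exactly one token; an
#' unrecognized string maps to `"NA"` with a warning, never an error.
#'
#' @param raw character vector of raw phase strings (e.g. `"Phase 2"`,
#'   `"Phase 1/Phase 2"`, `"N/A"`).
#' @return character vector of tokens from
#'   `c("NA","EARLY_1","P1","P1_2","P2","P2_3","P3","P4")`.
#' @examples
#' normalizePhase(c("Phase 2", "Phase 1/Phase 2", "N/A", "gibberish"))
#' @export
normalizePhase <- function(raw) {
    key <- tolower(trimws(as.character(raw)))
    key[is.na(key)] <- ""
    out <- unname(RAW_PHASE_MAP[key])
    out[key == ""] <- "NA"
    unknown <- is.na(out)
    if (any(unknown)) {
        warning(sprintf("unknown phase string(s) mapped to NA: %s",
                        paste(unique(raw[unknown]), collapse = ", ")),
                call. = FALSE)
        out[unknown] <- "NA"
    }
    out
}

#' Does a trial's phase label fall in a phase stratum?
#'
#' Under the default `"combined"` policy a combined label counts toward
#' each constituent stratum (a Phase I/II trial is evidence of both Phase I
#' and Phase II activity). Under `"highest"` it counts only toward its
#' highest constituent. The `"ALL"` stratum matches every label.
#'
#' @param label character vector of phase tokens.
#' @param stratum single phase token, or `"ALL"`.
#' @param policy `"combined"` (default) or `"highest"`.
#' @return logical vector.
#' @export
phaseMatches <- function(label, stratum, policy = c("combined", "highest")) {
    policy <- match.arg(policy)
    stopifnot(stratum %in% c(PHASE_LEVELS, "ALL"))
    if (stratum == "ALL") return(rep(TRUE, length(label)))
    constituents <- list(
        "NA" = "NA", EARLY_1 = "EARLY_1", P1 = "P1", P2 = "P2",
        P3 = "P3", P4 = "P4",
        P1_2 = c("P1", "P2"), P2_3 = c("P2", "P3"))
    if (policy == "highest")
        constituents <- list(
            "NA" = "NA", EARLY_1 = "EARLY_1", P1 = "P1", P2 = "P2",
            P3 = "P3", P4 = "P4", P1_2 = "P2", P2_3 = "P3")
    vapply(label, function(l) stratum %in% constituents[[l]], logical(1),
           USE.NAMES = FALSE)
}

#' MEDLINE publication-type string for a phase token
#'
#' @param phase a phase token with a publication-type equivalent
#'   (`EARLY_1` shares `"Clinical Trial, Phase I"`; `"NA"` has none).
#' @return length-1 character.
#' @export
phasePubType <- function(phase) {
    if (!phase %in% names(PHASE_PUB_TYPE))
        stop("no publication type for phase token: ", phase)
    unname(PHASE_PUB_TYPE[phase])
}
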