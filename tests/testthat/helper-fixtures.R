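# Small in-code builders shared across test files.

makeTrialRow <- function(trial_id = "NCT00000001",
                         title = "A study",
                         conditions = character(0),
                         description = "",
                         start_date = as.Date("2010-06-01"),
                         phase_label = "P2",
                         lead_institution_raw = "Lakeside Univ Hospital",
                         enrollment = NA_integer_,
                         status = NA_character_,
                         funding_source = NA_character_) {
    data.frame(trial_id = trial_id, title = title,
               conditions = I(list(conditions)), description = description,
               start_date = start_date, phase_label = phase_label,
               lead_institution_raw = lead_institution_raw,
               enrollment = enrollment, status = status,
               funding_source = funding_source, stringsAsFactors = FALSE)
}

makePubRow <- function(pmid = "100001",
                       journal_title = "Journal A",
                       pub_year = 2010L,
                       pub_types = "Clinical Trial, Phase II",
                       mesh_terms = "*Uterine Cervical Neoplasms",
                       affiliations = "Dept of Oncology, Lakeside Univ Hospital, USA") {
    data.frame(pmid = pmid, journal_title = journal_title,
               pub_year = pub_year, pub_types = I(list(pub_types)),
               mesh_terms = I(list(mesh_terms)),
               affiliations = I(list(affiliations)),
               stringsAsFactors = FALSE)
}

tinyLexicon <- function() {
    diseaseLexicon(
        disease = c("gastric", "urothelial", "cervical"),
        keywords = list("gastric cancer",
                        c("urothelial cancer", "bladder cancer",
                          "ureteral cancer"),
                        "cervical cancer"),
        regex = c("gastric.{1,100}cancer", NA, NA),
        mesh = list("Stomach Neoplasms", "Urinary Bladder Neoplasms",
                    "Uterine Cervical Neoplasms"))
}

# Independent splitter for PubMed-syntax query strings: parses the grammar
# back into components without reusing the builder.
parseQueryString <- function(q) {
    m <- regexec(paste0("^\\((.+?)\\) ([0-9]{4}):([0-9]{4})\\[DP\\]",
                        "( ([^][]+)\\[PT\\])?( ([^][]+)\\[MESH\\])?$"), q)
    parts <- regmatches(q, m)[[1]]
    if (!length(parts)) return(NULL)
    syn <- strsplit(parts[2], " OR ", fixed = TRUE)[[1]]
    list(synonyms = sub("\\[AD\\]$", "", syn),
         window = c(as.integer(parts[3]), as.integer(parts[4])),
         phaseLabel = if (nzchar(parts[6])) parts[6] else NULL,
         mesh = if (nzchar(parts[8])) parts[8] else NULL)
}

# Independent normal-equations oracle for the OLS fit.
normalEquationsFit <- function(x, y) {
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    syy <- sum((y - mean(y))^2)
    b <- sxy / sxx
    a <- mean(y) - b * mean(x)
    sse <- sum((y - a - b * x)^2)
    se <- sqrt(sse / (n - 2) / sxx)
    tstat <- b / se
    list(slope = b, intercept = a,
         r = sxy / sqrt(sxx * syy),
         r2 = sxy^2 / (sxx * syy),
         p_value = 2 * stats::pt(-abs(tstat), n - 2),
         stderr = se)
}

# Brute-force top-k-with-ties: sort descending, cut at the k-th sorted
# score, extend through ties at the cut.
bruteTopK <- function(scores, k) {
    ord <- order(-scores, names(scores))
    s <- scores[ord]
    cutoff <- if (length(s) <= k) min(s) else s[k]
    keep <- s >= cutoff
    data.frame(institution = names(s)[keep], score = unname(s[keep]),
               stringsAsFactors = FALSE)
}
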