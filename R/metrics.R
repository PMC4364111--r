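## Aggregation and the composite productivity score
##
##   Score(institution, disease) =
##       (SIF/maxSIF(disease) + Registrations/maxRegistrations(disease)) * 50
##
## with per-disease maxima over the institution panel; a term with zero
## disease maximum contributes 0, keeping the score total and bounded.
## Scores live unrounded internally; reporting rounds half-up to 2
## decimals (the precision of the published tables).

#' Round half-up
#'
#' Display rounding for scores: 0.005 rounds to 0.01 (base `round()` uses
#' round-half-even).
#'
#' @param x numeric vector (nonnegative in this package's use).
#' @param digits decimal places (default 2).
#' @return numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
    p <- 10^digits
    floor(x * p + 0.5 + 1e-9) / p
}

yearOf <- function(dates) as.integer(format(dates, "%Y"))

#' Count trial registrations per (institution, disease)
#'
#' Cell (i, d) counts trials with resolved institution i, disease d among
#' its labels, phase label in the stratum, and start year inside the
#' window. A multi-disease trial increments every one of its disease
#' columns. The `all_cancer` column counts each in-stratum trial once,
#' classifiable or not. Trials resolving to `"UNRESOLVED"` and trials
#' without a start date (when a window is given) contribute nothing.
#'
#' @param trials trial data.frame.
#' @param classifications list of disease-label vectors
#'   ([classifyTrials()] output, same order as `trials`).
#' @param resolutions character vector of canonical ids / `"UNRESOLVED"`
#'   per trial ([resolveInstitution()] output).
#' @param institutions character vector of canonical ids (matrix rows).
#' @param diseases character vector of disease ids (matrix columns; the
#'   `all_cancer` column is appended automatically).
#' @param phase phase stratum token (default `"P2"`) or `"ALL"`.
#' @param window integer `c(start_year, end_year)` or `NULL` for none.
#' @param phasePolicy `"combined"` (default) or `"highest"`, see
#'   [phaseMatches()].
#' @return a [CountMatrix-class].
#' @export
countRegistrations <- function(trials, classifications, resolutions,
                               institutions, diseases, phase = "P2",
                               window = NULL,
                               phasePolicy = c("combined", "highest")) {
    phasePolicy <- match.arg(phasePolicy)
    stopifnot(length(classifications) == nrow(trials),
              length(resolutions) == nrow(trials))
    cols <- c(diseases, "all_cancer")
    m <- matrix(0, nrow = length(institutions), ncol = length(cols),
                dimnames = list(institutions, cols))
    keep <- phaseMatches(trials$phase_label, phase, phasePolicy) &
        resolutions %in% institutions
    if (!is.null(window)) {
        yr <- yearOf(trials$start_date)
        keep <- keep & !is.na(yr) & yr >= window[1] & yr <= window[2]
    }
    for (i in which(keep)) {
        inst <- resolutions[i]
        for (d in intersect(classifications[[i]], diseases))
            m[inst, d] <- m[inst, d] + 1
        m[inst, "all_cancer"] <- m[inst, "all_cancer"] + 1
    }
    countMatrix(m, phase = phase,
                window = if (is.null(window)) numeric(0) else window)
}

#' Summed impact factor per (institution, disease)
#'
#' For each institution/disease pair, evaluates the publication query
#' (affiliation synonyms AND year window AND phase publication type AND
#' disease MeSH) against every publication and sums the impact factors of
#' the matching publications' journals. Journals absent from the table
#' contribute 0 and are reported in one warning. The `all_cancer` column
#' uses the lexicon's neoplasms umbrella instead of a disease MeSH term.
#'
#' @param publications publication data.frame.
#' @param dict a [SynonymDictionary-class] (affiliation synonyms per
#'   institution).
#' @param lexicon a [DiseaseLexicon-class].
#' @param ifTable an [ImpactFactorTable-class].
#' @param phase phase stratum token (publication-type clause), or `NULL`.
#' @param window integer `c(start_year, end_year)`.
#' @param majorTopicOnly only count major-topic MeSH terms (default
#'   `FALSE`).
#' @return a [SIFMatrix-class].
#' @export
summedImpactFactor <- function(publications, dict, lexicon, ifTable,
                               phase = "P2", window,
                               majorTopicOnly = FALSE) {
    institutions <- dict@canonicalIds
    diseases <- lexiconDiseases(lexicon)
    cols <- c(diseases, "all_cancer")
    m <- matrix(0, nrow = length(institutions), ncol = length(cols),
                dimnames = list(institutions, cols))
    n <- nrow(publications)
    if (n) {
        ifs <- lookupImpactFactor(ifTable, publications$journal_title)
        ## precompute per-publication clauses shared across pairs
        instHit <- vapply(institutions, function(inst) {
            syn <- tolower(institutionSynonyms(dict, inst))
            vapply(seq_len(n), function(j) {
                affil <- tolower(publications$affiliations[[j]])
                length(affil) > 0 &&
                    any(vapply(syn, function(s)
                        any(grepl(s, affil, fixed = TRUE)), logical(1)))
            }, logical(1))
        }, logical(n))
        instHit <- matrix(instHit, nrow = n,
                          dimnames = list(NULL, institutions))
        yr <- publications$pub_year
        inWindow <- !is.na(yr) & yr >= window[1] & yr <= window[2]
        phaseOk <- rep(TRUE, n)
        if (!is.null(phase)) {
            pt <- tolower(phasePubType(phase))
            phaseOk <- vapply(publications$pub_types,
                              function(p) pt %in% tolower(p), logical(1))
        }
        diseaseHit <- vapply(cols, function(d) {
            vapply(seq_len(n), function(j)
                classifyPublication(publications[j, ], lexicon, d,
                                    majorTopicOnly), logical(1))
        }, logical(n))
        diseaseHit <- matrix(diseaseHit, nrow = n,
                             dimnames = list(NULL, cols))
        base <- inWindow & phaseOk
        for (inst in institutions) {
            sel <- base & instHit[, inst]
            if (!any(sel)) next
            for (d in cols)
                m[inst, d] <- sum(ifs[sel & diseaseHit[, d]])
        }
    }
    sifMatrix(m, phase = if (is.null(phase)) "ALL" else phase,
              window = window)
}

#' Composite score for one (institution, disease) cell
#'
#' `(sif/maxSif + reg/maxReg) * 50`; a term whose disease maximum is zero
#' contributes 0. The unrounded value is returned; display rounding is
#' half-up to two decimals (see [roundHalfUp()]).
#'
#' @param sif summed impact factor of the cell.
#' @param maxSif per-disease maximum SIF (must be a true maximum).
#' @param reg registrations of the cell.
#' @param maxReg per-disease maximum registrations.
#' @return numeric(1) in [0, 100].
#' @examples
#' roundHalfUp(scorePair(7.993, 10.329, 1, 2))  # 63.69
#' @export
scorePair <- function(sif, maxSif, reg, maxReg) {
    stopifnot(maxSif >= 0, maxReg >= 0)
    if (sif > maxSif) stop("sif exceeds maxSif: maxima must be true maxima")
    if (reg > maxReg) stop("reg exceeds maxReg: maxima must be true maxima")
    term1 <- if (maxSif > 0) sif / maxSif else 0
    term2 <- if (maxReg > 0) reg / maxReg else 0
    (term1 + term2) * 50
}

competitionRank <- function(scores) {
    ## tied scores share a rank; the next rank skips by the tie size
    vapply(scores, function(s) 1L + sum(scores > s), integer(1))
}

#' Build the scoreboard from aligned SIF and count matrices
#'
#' Takes per-disease maxima over the institution panel, applies
#' [scorePair()] cellwise, and computes competition ranks per disease on
#' the unrounded scores. Diseases below the activity floor
#' (`maxReg >= 1` and `maxSif > 0` by default) are dropped from ranking;
#' the `all_cancer` column is exempt from the floor.
#'
#' @param sif a [SIFMatrix-class].
#' @param reg a [CountMatrix-class] with identical labels, phase and
#'   window.
#' @param activityFloor apply the floor (default `TRUE`).
#' @return a [Scoreboard-class].
#' @export
buildScoreboard <- function(sif, reg, activityFloor = TRUE) {
    s <- matrixValues(sif)
    r <- matrixValues(reg)
    if (!identical(dimnames(s), dimnames(r)))
        stop("SIF and count matrices must share institution/disease labels")
    maxSif <- apply(s, 2, max)
    maxReg <- apply(r, 2, max)
    dropped <- character(0)
    if (activityFloor && ncol(s)) {
        low <- (maxReg < 1 | maxSif <= 0) & colnames(s) != "all_cancer"
        dropped <- colnames(s)[low]
        s <- s[, !low, drop = FALSE]
        r <- r[, !low, drop = FALSE]
        maxSif <- maxSif[!low]
        maxReg <- maxReg[!low]
    }
    scores <- s
    for (d in seq_len(ncol(s)))
        scores[, d] <- vapply(seq_len(nrow(s)), function(i)
            scorePair(s[i, d], maxSif[d], r[i, d], maxReg[d]), numeric(1))
    ranks <- apply(scores, 2, competitionRank)
    if (!is.matrix(ranks))
        ranks <- matrix(ranks, nrow = nrow(scores),
                        dimnames = dimnames(scores))
    new("Scoreboard", scores = scores, maxSif = maxSif, maxReg = maxReg,
        ranks = ranks, phase = sif@phase, window = sif@window,
        dropped = dropped)
}

#' Top-k institutions for one disease, ties included
#'
#' All institutions with competition rank <= k (a tie at the k-th score is
#' therefore included in full, so the list may exceed `k` entries),
#' ordered by score descending with ties broken by institution name
#' ascending.
#'
#' @param scoreboard a [Scoreboard-class].
#' @param disease a disease id present in the scoreboard.
#' @param k list depth (default 10).
#' @return data.frame with columns `institution`, `score` (unrounded),
#'   `rank`.
#' @export
topKWithTies <- function(scoreboard, disease, k = 10) {
    stopifnot(k >= 1)
    if (!disease %in% colnames(scoreboard@scores))
        stop("unknown disease: ", disease)
    sc <- scoreboard@scores[, disease]
    rk <- scoreboard@ranks[, disease]
    keep <- rk <= k
    out <- data.frame(institution = rownames(scoreboard@scores)[keep],
                      score = sc[keep], rank = rk[keep],
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(-out$score, out$institution), , drop = FALSE]
}

#' @describeIn appearanceTally tally from a Scoreboard via
#'   [topKWithTies()] per (non-`all_cancer`) disease.
#' @export
setMethod("appearanceTally", "Scoreboard", function(x, k = 10, ...) {
    diseases <- setdiff(colnames(x@scores), "all_cancer")
    inst <- rownames(x@scores)
    appearances <- stats::setNames(integer(length(inst)), inst)
    firsts <- appearances
    for (d in diseases) {
        top <- topKWithTies(x, d, k)
        appearances[top$institution] <- appearances[top$institution] + 1L
        winners <- top$institution[top$rank == 1L]
        firsts[winners] <- firsts[winners] + 1L
    }
    data.frame(institution = inst, appearances = unname(appearances),
               firsts = unname(firsts), stringsAsFactors = FALSE,
               row.names = NULL)
})

#' @describeIn appearanceTally tally from a long ranked table (columns
#'   `disease`, `institution`, `score`), e.g. a transcribed published
#'   top-k listing; each disease block is taken as the top-k list, and a
#'   first is any institution attaining the block's maximum score.
#' @export
setMethod("appearanceTally", "data.frame",
          function(x, k = 10, institutions = NULL, ...) {
    stopifnot(all(c("disease", "institution", "score") %in% names(x)))
    inst <- sort(unique(c(x$institution, institutions)))
    appearances <- stats::setNames(integer(length(inst)), inst)
    firsts <- appearances
    for (d in unique(x$disease)) {
        block <- x[x$disease == d, , drop = FALSE]
        appearances[block$institution] <-
            appearances[block$institution] + 1L
        winners <- block$institution[block$score >= max(block$score) - 1e-9]
        firsts[winners] <- firsts[winners] + 1L
    }
    data.frame(institution = inst, appearances = unname(appearances),
               firsts = unname(firsts), stringsAsFactors = FALSE,
               row.names = NULL)
})

#' Rank-ordered score curves per disease
#'
#' For each (non-`all_cancer`) disease, the scores sorted descending with
#' their competition ranks — the long-format data behind a rank-score
#' overlay plot.
#'
#' @param scoreboard a [Scoreboard-class].
#' @return data.frame with columns `disease`, `rank`, `score`
#'   (unrounded), `institution`.
#' @export
rankScoreCurves <- function(scoreboard) {
    diseases <- setdiff(colnames(scoreboard@scores), "all_cancer")
    blocks <- lapply(diseases, function(d) {
        sc <- scoreboard@scores[, d]
        rk <- scoreboard@ranks[, d]
        ord <- order(-sc, rownames(scoreboard@scores))
        data.frame(disease = d, rank = rk[ord], score = sc[ord],
                   institution = rownames(scoreboard@scores)[ord],
                   stringsAsFactors = FALSE, row.names = NULL)
    })
    out <- do.call(rbind, blocks)
    if (is.null(out))
        out <- data.frame(disease = character(0), rank = integer(0),
                          score = numeric(0), institution = character(0))
    out
}
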