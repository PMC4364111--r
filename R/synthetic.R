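## Synthetic registry + publication corpora with known ground truth.
## Every pipeline stage (parsing, classification, resolution, aggregation,
## scoring) can then be checked against truth exactly, with no network
## access. The generator emulates the structure of the real data sources:
## per-(institution, disease, phase) Poisson trial counts, lexicon
## keywords injected verbatim into trial text, institution names drawn
## from synonym variants, distractor trials (side effects, risk factors,
## unlisted diseases) carrying no lexicon pattern, out-of-dictionary
## sponsors at a controlled rate, and log-normal journal impact factors
## (heavy right tail, as real impact-factor lists show).

#' Default generator lexicon
#'
#' Six diseases with collision-free keywords (no keyword is a substring of
#' another disease's text templates), one bounded-gap regex entry, and one
#' MeSH descriptor each.
#'
#' @return A [DiseaseLexicon-class].
#' @export
defaultGeneratorLexicon <- function() {
    diseaseLexicon(
        disease = c("breast", "lung", "melanoma", "gastric", "cervical",
                    "urothelial"),
        keywords = list(
            "breast cancer",
            "lung cancer",
            "melanoma",
            "gastric cancer",
            "cervical cancer",
            c("urothelial cancer", "bladder cancer", "ureteral cancer")),
        regex = c(NA, NA, NA, "gastric.{1,100}cancer", NA, NA),
        mesh = list("Breast Neoplasms", "Lung Neoplasms", "Melanoma",
                    "Stomach Neoplasms", "Uterine Cervical Neoplasms",
                    "Urinary Bladder Neoplasms"))
}

#' Default generator institution panel
#'
#' Eight fictional institutions, each with two or three synonym variants;
#' first words are distinct so no synonym can match another institution's
#' affiliation text.
#'
#' @return data.frame with columns `synonym`, `canonical`.
#' @export
defaultGeneratorInstitutions <- function() {
    data.frame(
        synonym = c("Lakeside Univ Hospital", "Lakeside Comprehensive Center",
                    "Riverbend Med Ctr", "Riverbend Oncology Institute",
                    "Harborview Clinical Center",
                    "Summit City Hosp",
                    "Prairie General",
                    "Oakmont Institute of Research",
                    "Bayshore Memorial",
                    "Founders Hill Med Center"),
        canonical = c("Lakeside University Hospital",
                      "Lakeside University Hospital",
                      "Riverbend Medical Center", "Riverbend Medical Center",
                      "Harborview Clinic",
                      "Summit City Hospital",
                      "Prairie General Hospital",
                      "Oakmont Institute",
                      "Bayshore Memorial Hospital",
                      "Founders Hill Medical Center"),
        stringsAsFactors = FALSE)
}

DISTRACTOR_TOPICS <- data.frame(
    topic = c("oral mucositis", "psoriasis", "neuroblastoma",
              "diabetes mellitus", "advanced solid tumors",
              "drug-drug pharmacokinetic interaction"),
    kind = c("side_effect", "risk_factor", "unlisted_disease",
             "non_oncology", "unspecified", "basic_research"),
    stringsAsFactors = FALSE)

#' Generator configuration
#'
#' Defaults define the simulated study conditions: a 2008-2013 window (the
#' surveyed period), eight institutions, six diseases, Poisson trial
#' counts with per-phase means `c(P1 = 0.5, P2 = 1.0, P3 = 0.4)` per
#' (institution, disease) — Phase II heaviest, as in registry data — 1.2
#' expected publications per registered trial, log-normal impact factors
#' (meanlog 1, sdlog 0.8: median ~2.7 with a heavy right tail), 15%
#' distractor trials and 5% out-of-dictionary sponsors (rates in line
#' with a manual audit of unclassified registry records).
#'
#' @param institutions synonym data.frame (`synonym`, `canonical`).
#' @param lexicon a [DiseaseLexicon-class].
#' @param window integer `c(start_year, end_year)`.
#' @param rates named per-phase Poisson means, or a 3-d array
#'   `[institution, disease, phase]`.
#' @param pubsPerTrial expected publications per registered trial.
#' @param ifLognormal `c(meanlog, sdlog)` of journal impact factors.
#' @param nJournals number of synthetic journals.
#' @param distractorFraction share of trials drawn from non-lexicon
#'   topics.
#' @param unresolvedFraction share of trials with out-of-dictionary
#'   sponsors.
#' @param seed integer RNG seed; a fixed seed reproduces the corpus
#'   exactly.
#' @return list of class `"generatorConfig"`.
#' @export
generatorConfig <- function(institutions = defaultGeneratorInstitutions(),
                            lexicon = defaultGeneratorLexicon(),
                            window = c(2008, 2013),
                            rates = c(P1 = 0.5, P2 = 1.0, P3 = 0.4),
                            pubsPerTrial = 1.2,
                            ifLognormal = c(meanlog = 1.0, sdlog = 0.8),
                            nJournals = 40,
                            distractorFraction = 0.15,
                            unresolvedFraction = 0.05,
                            seed = 20150317) {
    stopifnot(length(window) == 2L, window[1] <= window[2],
              all(rates >= 0), pubsPerTrial >= 0,
              distractorFraction >= 0, distractorFraction <= 1,
              unresolvedFraction >= 0, unresolvedFraction <= 1,
              nJournals >= 1)
    structure(list(institutions = institutions, lexicon = lexicon,
                   window = as.integer(window), rates = rates,
                   pubsPerTrial = pubsPerTrial, ifLognormal = ifLognormal,
                   nJournals = as.integer(nJournals),
                   distractorFraction = distractorFraction,
                   unresolvedFraction = unresolvedFraction,
                   seed = as.integer(seed)),
              class = "generatorConfig")
}

withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    force(expr)
}

ratesArray <- function(config, institutions, diseases) {
    r <- config$rates
    if (is.array(r) && length(dim(r)) == 3L) return(r)
    phases <- names(r)
    stopifnot(!is.null(phases), all(phases %in% PHASE_LEVELS))
    arr <- array(rep(r, each = length(institutions) * length(diseases)),
                 dim = c(length(institutions), length(diseases),
                         length(phases)),
                 dimnames = list(institutions, diseases, phases))
    arr
}

signalKeyword <- function(lexicon, disease) {
    e <- lexicon@entries
    i <- match(disease, e$disease)
    kw <- e$keywords[[i]]
    if (length(kw)) kw[1] else NA_character_
}

## gap-regex demo text: splice a filler word into the two-word keyword so
## only the bounded-gap regex (not the literal phrase) can fire
gapVariant <- function(keyword) {
    parts <- strsplit(keyword, " ", fixed = TRUE)[[1]]
    if (length(parts) < 2) return(keyword)
    paste(parts[1], "adenoid", paste(parts[-1], collapse = " "))
}

#' Generate a synthetic corpus with ground truth
#'
#' Trial counts per (institution, disease, phase) are Poisson; each signal
#' trial's text embeds a lexicon keyword of its true disease (or, for a
#' disease with a gap regex, occasionally a gap variant only the regex can
#' detect); the lead institution is drawn from that institution's synonym
#' variants. Publications are generated per trial with journals from a
#' synthetic log-normal impact-factor table, affiliations embedding an
#' institution synonym, the phase's publication-type string, and the
#' disease's (major-topic) MeSH term. Distractor trials carry no lexicon
#' pattern; unresolved trials carry out-of-dictionary sponsors. A fixed
#' seed reproduces the corpus exactly.
#'
#' @param config a [generatorConfig()].
#' @return list with elements `bundle` (a [CorpusBundle-class]), `truth`
#'   (see Details), `lexicon`, `dictionary` and `config`. `truth` is a
#'   list with 3-d arrays `counts` and `sif`
#'   (`[institution, disease, phase]`), a matrix `allCancerCounts`
#'   (`[institution, phase]`, including distractors), and the per-trial
#'   `labels` list.
#' @export
generateCorpus <- function(config) {
    stopifnot(inherits(config, "generatorConfig"))
    withSeed(config$seed, {
        dict <- synonymDictionary(config$institutions)
        institutions <- dict@canonicalIds
        diseases <- lexiconDiseases(config$lexicon)
        arr <- ratesArray(config, institutions, diseases)
        phases <- dimnames(arr)[[3]]
        counts <- array(stats::rpois(length(arr), arr), dim = dim(arr),
                        dimnames = dimnames(arr))

        journals <- sprintf("Synthetic Oncology Journal %02d",
                            seq_len(config$nJournals))
        ifs <- round(stats::rlnorm(config$nJournals,
                                   config$ifLognormal[[1]],
                                   config$ifLognormal[[2]]), 3)
        ifTable <- impactFactorTable(stats::setNames(ifs, journals))

        trialRows <- list()
        pubRows <- list()
        labels <- list()
        truthSif <- array(0, dim = dim(arr), dimnames = dimnames(arr))
        allCancer <- matrix(0L, length(institutions), length(phases),
                            dimnames = list(institutions, phases))
        trialN <- 0L
        pubN <- 0L
        e <- config$lexicon@entries

        makeDate <- function() {
            yr <- sample(seq(config$window[1], config$window[2]), 1L)
            as.Date(sprintf("%d-%02d-01", yr, sample(12, 1L)))
        }
        makeTrial <- function(id, title, conditions, description, phase,
                              sponsor) {
            data.frame(trial_id = id, title = title,
                       conditions = I(list(conditions)),
                       description = description,
                       start_date = makeDate(), phase_label = phase,
                       lead_institution_raw = sponsor,
                       enrollment = stats::rpois(1, 40) + 1L,
                       status = sample(c("Completed", "Recruiting",
                                         "Active, not recruiting"), 1L),
                       funding_source = sample(c("Other", "Industry",
                                                 "NIH"), 1L),
                       stringsAsFactors = FALSE)
        }

        for (i in seq_along(institutions)) {
            syn <- institutionSynonyms(dict, institutions[i])
            for (d in seq_along(diseases)) {
                kw <- signalKeyword(config$lexicon, diseases[d])
                hasRegex <- !is.na(e$regex[match(diseases[d], e$disease)])
                mesh <- e$mesh[[match(diseases[d], e$disease)]][1]
                for (p in seq_along(phases)) {
                    for (k in seq_len(counts[i, d, p])) {
                        trialN <- trialN + 1L
                        id <- sprintf("NCT%08d", trialN)
                        useGap <- hasRegex && stats::runif(1) < 0.2
                        phrase <- if (useGap) gapVariant(kw) else kw
                        title <- sprintf(
                            "A Study of Agent TM-%03d in Patients With %s",
                            trialN %% 1000L, phrase)
                        descr <- sprintf(
                            paste("This trial evaluates an investigational",
                                  "regimen for participants with %s,",
                                  "with response and safety endpoints."),
                            phrase)
                        trialRows[[trialN]] <- makeTrial(
                            id, title, phrase, descr, phases[p],
                            sample(syn, 1L))
                        labels[[id]] <- diseases[d]
                        allCancer[i, p] <- allCancer[i, p] + 1L

                        npub <- stats::rpois(1, config$pubsPerTrial)
                        for (q in seq_len(npub)) {
                            pubN <- pubN + 1L
                            j <- sample(config$nJournals, 1L)
                            pubRows[[pubN]] <- data.frame(
                                pmid = as.character(10000000L + pubN),
                                journal_title = journals[j],
                                pub_year = sample(seq(config$window[1],
                                                      config$window[2]), 1L),
                                pub_types = I(list(c("Journal Article",
                                    phasePubType(phases[p])))),
                                mesh_terms = I(list(c(paste0("*", mesh),
                                                      "Humans"))),
                                affiliations = I(list(sprintf(
                                    "Department of Oncology, %s, Springfield, USA",
                                    sample(syn, 1L)))),
                                stringsAsFactors = FALSE)
                            truthSif[i, d, p] <- truthSif[i, d, p] + ifs[j]
                        }
                    }
                }
            }
        }

        nSignal <- trialN
        nDistract <- round(config$distractorFraction /
                           max(1 - config$distractorFraction, 1e-12) * nSignal)
        for (k in seq_len(nDistract)) {
            trialN <- trialN + 1L
            t <- DISTRACTOR_TOPICS[1L + (k - 1L) %% nrow(DISTRACTOR_TOPICS), ]
            i <- sample(length(institutions), 1L)
            p <- sample(length(phases), 1L)
            trialRows[[trialN]] <- makeTrial(
                sprintf("NCT%08d", trialN),
                sprintf("A Supportive Care Study in Patients With %s",
                        t$topic),
                t$topic,
                sprintf("An observational evaluation of %s management.",
                        t$topic),
                phases[p],
                sample(institutionSynonyms(dict, institutions[i]), 1L))
            labels[[sprintf("NCT%08d", trialN)]] <- character(0)
            allCancer[i, p] <- allCancer[i, p] + 1L
        }

        nUnres <- round(config$unresolvedFraction /
                        max(1 - config$unresolvedFraction, 1e-12) * nSignal)
        outOfDict <- c("Community Oncology of Springfield",
                       "Regional Research Network",
                       "Coastal Physicians Group")
        for (k in seq_len(nUnres)) {
            trialN <- trialN + 1L
            d <- sample(length(diseases), 1L)
            kw <- signalKeyword(config$lexicon, diseases[d])
            trialRows[[trialN]] <- makeTrial(
                sprintf("NCT%08d", trialN),
                sprintf("A Community Study in Patients With %s", kw),
                kw,
                sprintf("A community-based study of %s.", kw),
                phases[sample(length(phases), 1L)],
                outOfDict[1L + (k - 1L) %% length(outOfDict)])
            labels[[sprintf("NCT%08d", trialN)]] <- diseases[d]
        }

        trials <- if (trialN) do.call(rbind, trialRows) else emptyTrials()
        pubs <- if (pubN) do.call(rbind, pubRows) else emptyPublications()
        rownames(trials) <- rownames(pubs) <- NULL

        list(bundle = corpusBundle(trials, pubs, ifTable),
             truth = list(counts = counts, sif = truthSif,
                          allCancerCounts = allCancer, labels = labels,
                          phases = phases),
             lexicon = config$lexicon, dictionary = dict, config = config)
    })
}

combineStratum <- function(arr, phase, policy = "combined") {
    phases <- dimnames(arr)[[3]]
    inStratum <- phases[phaseMatches(phases, phase, policy)]
    if (!length(inStratum))
        return(matrix(0, dim(arr)[1], dim(arr)[2],
                      dimnames = dimnames(arr)[1:2]))
    apply(arr[, , inStratum, drop = FALSE], c(1, 2), sum)
}

#' Ground-truth aggregate matrices
#'
#' Build the true [CountMatrix-class] / [SIFMatrix-class] for one phase
#' stratum directly from the generator's ground truth (no parsing or
#' classification involved).
#'
#' @param truth the `truth` element of [generateCorpus()] output.
#' @param phase phase stratum token (default `"P2"`).
#' @param window year window recorded on the matrices.
#' @param phasePolicy see [phaseMatches()].
#' @return a [CountMatrix-class] (resp. [SIFMatrix-class]) including the
#'   `all_cancer` column.
#' @export
trueCountMatrix <- function(truth, phase = "P2", window = numeric(0),
                            phasePolicy = "combined") {
    m <- combineStratum(truth$counts, phase, phasePolicy)
    phases <- colnames(truth$allCancerCounts)
    inStratum <- phases[phaseMatches(phases, phase, phasePolicy)]
    allc <- rowSums(truth$allCancerCounts[, inStratum, drop = FALSE])
    countMatrix(cbind(m, all_cancer = allc), phase = phase, window = window)
}

#' @rdname trueCountMatrix
#' @export
trueSifMatrix <- function(truth, phase = "P2", window = numeric(0),
                          phasePolicy = "combined") {
    m <- combineStratum(truth$sif, phase, phasePolicy)
    ## pan-cancer SIF: every signal publication carries a neoplasm MeSH
    sifMatrix(cbind(m, all_cancer = rowSums(m)), phase = phase,
              window = window)
}

#' Scoreboard implied by the ground truth
#'
#' The oracle for end-to-end tests: scores computed from the true count
#' and SIF matrices through the same [buildScoreboard()] used by the
#' pipeline.
#'
#' @param truth the `truth` element of [generateCorpus()] output.
#' @param phase phase stratum token (default `"P2"`).
#' @param window year window.
#' @param activityFloor passed to [buildScoreboard()].
#' @return a [Scoreboard-class].
#' @export
expectedScoreboard <- function(truth, phase = "P2", window = numeric(0),
                               activityFloor = TRUE) {
    buildScoreboard(trueSifMatrix(truth, phase, window),
                    trueCountMatrix(truth, phase, window),
                    activityFloor = activityFloor)
}

#' Write a corpus to disk in the formats the readers accept
#'
#' Emits `registry.xml` (legacy full-study XML), `medline.txt` (tagged
#' fields), `impact_factors.csv`, `lexicon.csv` and `synonyms.csv` under
#' `dir`.
#'
#' @param corpus the list returned by [generateCorpus()].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(registry = file.path(dir, "registry.xml"),
               medline = file.path(dir, "medline.txt"),
               impact_factors = file.path(dir, "impact_factors.csv"),
               lexicon = file.path(dir, "lexicon.csv"),
               synonyms = file.path(dir, "synonyms.csv"))
    writeRegistryXML(corpus$bundle@trials, paths["registry"])
    writeMedline(corpus$bundle@publications, paths["medline"])
    f <- corpus$bundle@impactFactors@factors
    utils::write.csv(data.frame(journal = names(f), if2012 = unname(f)),
                     paths["impact_factors"], row.names = FALSE)
    writeLexiconCSV(corpus$lexicon, paths["lexicon"])
    utils::write.csv(corpus$dictionary@raw, paths["synonyms"],
                     row.names = FALSE)
    invisible(paths)
}

#' Write a lexicon as the kw1..kw8/regex/mesh CSV
#'
#' @param lexicon a [DiseaseLexicon-class].
#' @param dest output CSV path.
#' @return `dest`, invisibly.
#' @export
writeLexiconCSV <- function(lexicon, dest) {
    e <- lexicon@entries
    kw <- t(vapply(e$keywords, function(k)
        c(k, rep("", 8L - length(k)))[1:8], character(8)))
    colnames(kw) <- paste0("kw", 1:8)
    df <- data.frame(disease = e$disease, kw,
                     regex = ifelse(is.na(e$regex), "", e$regex),
                     mesh = vapply(e$mesh, paste, character(1),
                                   collapse = ";"),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, dest, row.names = FALSE)
    invisible(dest)
}
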