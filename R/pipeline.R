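## End-to-end orchestration: read -> classify -> resolve -> aggregate ->
## score -> rank -> regress, with every report table written as CSV and a
## stage-by-stage record-count log on stderr.

#' Read a run configuration from YAML
#'
#' Fields: `registry`, `medline`, `lexicon`, `synonyms`,
#' `impact_factors` (input paths); `window` (two years); `phase` (scoring
#' stratum, default `"P2"`); `top_k` (default 10); `p_threshold` (default
#' 0.05); `output_dir`; `audit_n` (default 100); flags `word_boundary`,
#' `major_topic_only` (default `FALSE`), `phase_policy`
#' (`"combined"`/`"highest"`), `activity_floor` (default `TRUE`).
#'
#' @param path YAML file path.
#' @return a named list with defaults filled in.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("run config not found: ", path)
    fillRunConfig(yaml::read_yaml(path))
}

fillRunConfig <- function(config) {
    defaults <- list(phase = "P2", top_k = 10, p_threshold = 0.05,
                     audit_n = 100, word_boundary = FALSE,
                     major_topic_only = FALSE, phase_policy = "combined",
                     activity_floor = TRUE, output_dir = ".")
    for (nm in names(defaults))
        if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    config$window <- as.integer(unlist(config$window))
    config
}

stageLog <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full productivity pipeline
#'
#' Reads the corpus and lookup tables named in `config`, classifies and
#' resolves every trial, aggregates registrations and summed impact
#' factors for the scoring stratum, builds the scoreboard, and writes the
#' report bundle to `config$output_dir`: `table1_overall.csv` (overall
#' productivity), `table2_disease_ranks.csv` (top-k per disease, ties
#' included), `table3_appearances.csv`, `fig1_rank_scores.csv`,
#' `s3_regressions.csv`, `s4_registrations.csv` (counts by institution,
#' disease and phase), `s5_sif.csv`, and an audit set
#' (`audit_unclassified.csv`, `audit_unresolved.csv`,
#' `audit_unknown_journals.csv`). Scores are reported rounded half-up to
#' 2 decimals. Any stage error propagates with the failing stage named.
#'
#' @param config a run-config list ([readRunConfig()]) or a YAML path.
#' @return invisibly, a list with the scoreboard, matrices, regression
#'   output and the written file paths.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    config <- fillRunConfig(config)

    lexicon <- runStage("read_lexicon", readTable(config$lexicon, "lexicon"))
    dict <- runStage("read_synonyms", readTable(config$synonyms, "synonyms"))
    ifTable <- runStage("read_impact_factors",
                        readTable(config$impact_factors, "impact_factors"))
    trials <- runStage("read_registry", readRegistryXML(config$registry))
    pubs <- runStage("read_medline", readMedline(config$medline))
    stageLog("read", "%d trials, %d publications, %d journals, %d diseases",
             nrow(trials), nrow(pubs), length(ifTable@factors),
             nrow(lexicon@entries))

    matcher <- runStage("classify",
                        compileLexicon(lexicon, config$word_boundary))
    labels <- runStage("classify", classifyTrials(trials, matcher))
    nClassified <- sum(vapply(labels, length, 1L) > 0L)
    stageLog("classify", "%d classified + %d unclassified = %d trials",
             nClassified, nrow(trials) - nClassified, nrow(trials))

    resolutions <- runStage("resolve",
        resolveInstitution(trials$lead_institution_raw, dict))
    stageLog("resolve", "%d resolved, %d unresolved",
             sum(resolutions != "UNRESOLVED"),
             sum(resolutions == "UNRESOLVED"))

    window <- config$window
    phase <- config$phase
    emptyCorpus <- nrow(trials) == 0L && nrow(pubs) == 0L

    reg <- runStage("aggregate", countRegistrations(
        trials, labels, resolutions, canonicalInstitutions(dict),
        lexiconDiseases(lexicon), phase = phase, window = window,
        phasePolicy = config$phase_policy))
    unknownJournals <- character(0)
    sif <- runStage("aggregate", withCallingHandlers(
        summedImpactFactor(pubs, dict, lexicon, ifTable, phase = phase,
                           window = window,
                           majorTopicOnly = config$major_topic_only),
        warning = function(w) {
            if (grepl("impact-factor table", conditionMessage(w))) {
                unknownJournals <<- c(unknownJournals,
                    sub(".*: ", "", conditionMessage(w)))
                invokeRestart("muffleWarning")
            }
        }))
    stageLog("aggregate", "phase %s: %d registrations, total SIF %.2f",
             phase, sum(matrixValues(reg)[, "all_cancer"]),
             sum(matrixValues(sif)[, "all_cancer"]))

    sb <- runStage("score", buildScoreboard(sif, reg,
                                            activityFloor =
                                                config$activity_floor))
    regOut <- runStage("regress", suppressWarnings(
        perDiseaseRegressions(reg, sif, config$p_threshold)))
    stageLog("score", "%d disease(s) ranked, %d dropped by activity floor",
             ncol(matrixValues(sb)) - 1L, length(sb@dropped))

    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$output_dir, f)
    paths <- c(table1 = out("table1_overall.csv"),
               table2 = out("table2_disease_ranks.csv"),
               table3 = out("table3_appearances.csv"),
               fig1 = out("fig1_rank_scores.csv"),
               s3 = out("s3_regressions.csv"),
               s4 = out("s4_registrations.csv"),
               s5 = out("s5_sif.csv"),
               audit_unclassified = out("audit_unclassified.csv"),
               audit_unresolved = out("audit_unresolved.csv"),
               audit_unknown_journals = out("audit_unknown_journals.csv"))

    runStage("report", {
        sc <- matrixValues(sb)
        t1 <- data.frame(institution = rownames(sc),
                         score = roundHalfUp(sc[, "all_cancer"]),
                         sif = matrixValues(sif)[, "all_cancer"],
                         registrations = matrixValues(reg)[, "all_cancer"],
                         stringsAsFactors = FALSE, row.names = NULL)
        t1 <- t1[order(-t1$score, t1$institution), , drop = FALSE]
        if (emptyCorpus) t1 <- t1[0, , drop = FALSE]
        utils::write.csv(t1, paths["table1"], row.names = FALSE)

        diseases <- setdiff(colnames(sc), "all_cancer")
        t2 <- do.call(rbind, c(list(data.frame(disease = character(0),
                rank = integer(0), institution = character(0),
                score = numeric(0))),
            lapply(diseases, function(d) {
                top <- topKWithTies(sb, d, config$top_k)
                data.frame(disease = d, rank = top$rank,
                           institution = top$institution,
                           score = roundHalfUp(top$score),
                           stringsAsFactors = FALSE)
            })))
        utils::write.csv(t2, paths["table2"], row.names = FALSE)

        t3 <- appearanceTally(sb, k = config$top_k)
        if (emptyCorpus) t3 <- t3[0, , drop = FALSE]
        utils::write.csv(t3, paths["table3"], row.names = FALSE)

        f1 <- rankScoreCurves(sb)[, c("disease", "rank", "score")]
        utils::write.csv(f1, paths["fig1"], row.names = FALSE)

        utils::write.csv(regOut$results, paths["s3"], row.names = FALSE)

        s4 <- do.call(rbind, lapply(intersect(PHASE_LEVELS,
                                              unique(trials$phase_label)),
            function(p) {
                cm <- countRegistrations(trials, labels, resolutions,
                    canonicalInstitutions(dict), lexiconDiseases(lexicon),
                    phase = p, window = window,
                    phasePolicy = config$phase_policy)
                v <- matrixValues(cm)
                data.frame(institution = rep(rownames(v), ncol(v)),
                           disease = rep(colnames(v), each = nrow(v)),
                           phase = p, count = as.vector(v),
                           stringsAsFactors = FALSE)
            }))
        if (is.null(s4))
            s4 <- data.frame(institution = character(0),
                             disease = character(0), phase = character(0),
                             count = numeric(0))
        utils::write.csv(s4, paths["s4"], row.names = FALSE)

        v <- matrixValues(sif)
        s5 <- data.frame(institution = rep(rownames(v), ncol(v)),
                         disease = rep(colnames(v), each = nrow(v)),
                         phase = phase, sif = as.vector(v),
                         stringsAsFactors = FALSE)
        if (emptyCorpus) s5 <- s5[0, , drop = FALSE]
        utils::write.csv(s5, paths["s5"], row.names = FALSE)

        unc <- sampleUnclassified(trials, labels, config$audit_n)
        utils::write.csv(data.frame(trial_id = unc$trial_id,
                                    title = unc$title,
                                    start_date = unc$start_date,
                                    stringsAsFactors = FALSE),
                         paths["audit_unclassified"], row.names = FALSE)

        unres <- trials$lead_institution_raw[resolutions == "UNRESOLVED"]
        utils::write.csv(data.frame(name = sort(unique(unres))),
                         paths["audit_unresolved"], row.names = FALSE)

        utils::write.csv(data.frame(journal = sort(unique(unlist(
            strsplit(unknownJournals, ", ", fixed = TRUE))))),
            paths["audit_unknown_journals"], row.names = FALSE)
    })
    stageLog("report", "wrote %d files to %s", length(paths),
             config$output_dir)

    invisible(list(scoreboard = sb, registrations = reg, sif = sif,
                   regressions = regOut, paths = paths,
                   labels = labels, resolutions = resolutions))
}
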