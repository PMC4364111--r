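test_that("generation is a pure function of the config (seed included)", {
    cfg <- generatorConfig(seed = 171)
    c1 <- generateCorpus(cfg)
    c2 <- generateCorpus(cfg)
    expect_identical(c1$bundle@trials, c2$bundle@trials)
    expect_identical(c1$bundle@publications, c2$bundle@publications)
    expect_identical(c1$truth$counts, c2$truth$counts)
    ## and the serialized corpora are byte-identical
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeCorpus(c1, d1); writeCorpus(c2, d2)
    for (f in c("registry.xml", "medline.txt", "impact_factors.csv"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    ## generation does not disturb the caller's RNG stream
    set.seed(1); before <- stats::runif(1)
    set.seed(1); invisible(generateCorpus(cfg)); after <- stats::runif(1)
    expect_identical(before, after)
})

test_that("zero rates produce an empty corpus", {
    cfg <- generatorConfig(rates = c(P1 = 0, P2 = 0, P3 = 0),
                           distractorFraction = 0, unresolvedFraction = 0,
                           seed = 181)
    corp <- generateCorpus(cfg)
    expect_equal(nrow(corp$bundle@trials), 0L)
    expect_equal(nrow(corp$bundle@publications), 0L)
})

test_that("realized totals match the Poisson intensity within 4 sd", {
    cfg <- generatorConfig(distractorFraction = 0, unresolvedFraction = 0,
                           seed = 191)
    lambda <- 8 * 6 * sum(cfg$rates)  # institutions x diseases x rates
    total <- nrow(generateCorpus(cfg)$bundle@trials)
    expect_lt(abs(total - lambda), 4 * sqrt(lambda))
})

test_that("classification on clean corpora is perfect; distractors never
           classify (precision stays 1)", {
    clean <- generateCorpus(generatorConfig(distractorFraction = 0,
                                            unresolvedFraction = 0,
                                            seed = 201))
    m <- compileLexicon(clean$lexicon)
    got <- classifyTrials(clean$bundle@trials, m)
    want <- clean$truth$labels[clean$bundle@trials$trial_id]
    expect_equal(unname(lapply(got, sort)), unname(lapply(want, sort)))

    noisy <- generateCorpus(generatorConfig(distractorFraction = 0.3,
                                            seed = 202))
    got2 <- classifyTrials(noisy$bundle@trials, m)
    want2 <- noisy$truth$labels[noisy$bundle@trials$trial_id]
    for (id in names(got2)) {
        ## every predicted label is true: precision 1 even with distractors
        expect_true(all(got2[[id]] %in% want2[[id]]))
    }
    ## and every true label is found: recall 1 (keywords injected verbatim
    ## or via the gap variant the regex detects)
    for (id in names(got2))
        expect_true(all(want2[[id]] %in% got2[[id]]))
})

test_that("the pipeline-recovered matrices equal ground truth exactly on a
           clean corpus", {
    corp <- generateCorpus(generatorConfig(distractorFraction = 0,
                                           unresolvedFraction = 0,
                                           seed = 211))
    m <- compileLexicon(corp$lexicon)
    trials <- corp$bundle@trials
    labels <- classifyTrials(trials, m)
    res <- resolveInstitution(trials$lead_institution_raw, corp$dictionary)
    insts <- canonicalInstitutions(corp$dictionary)
    reg <- countRegistrations(trials, labels, res, insts,
                              lexiconDiseases(corp$lexicon), phase = "P2",
                              window = c(2008, 2013))
    sif <- summedImpactFactor(corp$bundle@publications, corp$dictionary,
                              corp$lexicon, corp$bundle@impactFactors,
                              phase = "P2", window = c(2008, 2013))
    wantReg <- trueCountMatrix(corp$truth, "P2", window = c(2008, 2013))
    wantSif <- trueSifMatrix(corp$truth, "P2", window = c(2008, 2013))
    expect_equal(matrixValues(reg)[insts, ], matrixValues(wantReg)[insts, ])
    expect_equal(matrixValues(sif)[insts, ], matrixValues(wantSif)[insts, ],
                 tolerance = 1e-9)
    ## and the scoreboards coincide cellwise
    sb <- buildScoreboard(sif, reg)
    esb <- expectedScoreboard(corp$truth, "P2", window = c(2008, 2013))
    expect_equal(matrixValues(sb)[insts, colnames(matrixValues(esb))],
                 matrixValues(esb)[insts, ], tolerance = 1e-9)
})

test_that("adding distractors leaves disease scores unchanged", {
    base <- generatorConfig(distractorFraction = 0, unresolvedFraction = 0,
                            seed = 221)
    noisy <- generatorConfig(distractorFraction = 0.25,
                             unresolvedFraction = 0, seed = 221)
    cClean <- generateCorpus(base)
    cNoisy <- generateCorpus(noisy)
    ## same seed: the signal block is identical, distractors are appended
    runDiseases <- function(corp) {
        m <- compileLexicon(corp$lexicon)
        trials <- corp$bundle@trials
        labels <- classifyTrials(trials, m)
        res <- resolveInstitution(trials$lead_institution_raw,
                                  corp$dictionary)
        sb <- buildScoreboard(
            summedImpactFactor(corp$bundle@publications, corp$dictionary,
                               corp$lexicon, corp$bundle@impactFactors,
                               phase = "P2", window = c(2008, 2013)),
            countRegistrations(trials, labels, res,
                               canonicalInstitutions(corp$dictionary),
                               lexiconDiseases(corp$lexicon), phase = "P2",
                               window = c(2008, 2013)))
        v <- matrixValues(sb)
        v[, colnames(v) != "all_cancer", drop = FALSE]
    }
    expect_equal(runDiseases(cNoisy), runDiseases(cClean),
                 tolerance = 1e-9)
})

test_that("a truth with one dominant institution per disease scores it 100", {
    corp <- generateCorpus(generatorConfig(seed = 231))
    truth <- corp$truth
    dom <- dimnames(truth$counts)[[1]][1]
    truth$counts[1, , ] <- apply(truth$counts, c(2, 3), max) + 1
    truth$sif[1, , ] <- apply(truth$sif, c(2, 3), max) + 1
    sb <- expectedScoreboard(truth, "P2")
    sc <- matrixValues(sb)
    for (d in setdiff(colnames(sc), "all_cancer"))
        expect_equal(sc[dom, d], 100)
})
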