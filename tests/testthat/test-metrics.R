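test_that("registration counting enumerates labels, phases and windows", {
    insts <- c("A", "B")
    diseases <- c("breast", "ovarian")
    trials <- rbind(
        makeTrialRow("NCT1", start_date = as.Date("2010-03-01")),
        makeTrialRow("NCT2", start_date = as.Date("2007-03-01")),
        makeTrialRow("NCT3", start_date = as.Date("2011-05-01"),
                     phase_label = "P1_2"),
        makeTrialRow("NCT4", start_date = as.Date("2012-01-01"),
                     phase_label = "P3"),
        makeTrialRow("NCT5", start_date = as.Date("2012-01-01")))
    labels <- list(c("breast", "ovarian"), "breast", "breast", "breast",
                   character(0))
    res <- c("A", "A", "B", "A", "B")
    cm <- countRegistrations(trials, labels, res, insts, diseases,
                             phase = "P2", window = c(2008, 2013))
    v <- matrixValues(cm)
    ## NCT1 multi-label increments both columns; NCT2 outside window;
    ## NCT3 is Phase I/II (counts under combined policy); NCT4 wrong phase;
    ## NCT5 unclassified counts only in all_cancer
    expect_equal(v["A", "breast"], 1)
    expect_equal(v["A", "ovarian"], 1)
    expect_equal(v["B", "breast"], 1)
    expect_equal(v["A", "all_cancer"], 1)
    expect_equal(v["B", "all_cancer"], 2)
    ## highest-phase-only policy still counts P1_2 as Phase II evidence
    vh <- matrixValues(countRegistrations(trials, labels, res, insts,
        diseases, phase = "P2", window = c(2008, 2013),
        phasePolicy = "highest"))
    expect_equal(vh["B", "breast"], 1)
    ## but P2_3 moves to Phase III under the highest policy
    t6 <- makeTrialRow("NCT6", start_date = as.Date("2010-01-01"),
                       phase_label = "P2_3")
    v6c <- matrixValues(countRegistrations(rbind(trials, t6),
        c(labels, list("breast")), c(res, "A"), insts, diseases,
        phase = "P2", window = c(2008, 2013)))
    v6h <- matrixValues(countRegistrations(rbind(trials, t6),
        c(labels, list("breast")), c(res, "A"), insts, diseases,
        phase = "P2", window = c(2008, 2013), phasePolicy = "highest"))
    expect_equal(v6c["A", "breast"] - v["A", "breast"], 1)
    expect_equal(v6h["A", "breast"], vh["A", "breast"])
    ## empty corpus gives an all-zero matrix
    z <- countRegistrations(emptyTrials(), list(), character(0), insts,
                            diseases, window = c(2008, 2013))
    expect_true(all(matrixValues(z) == 0))
})

test_that("label-count conservation holds on generated corpora", {
    corp <- generateCorpus(generatorConfig(seed = 77))
    trials <- corp$bundle@trials
    labels <- corp$truth$labels[trials$trial_id]
    res <- resolveInstitution(trials$lead_institution_raw, corp$dictionary)
    cm <- countRegistrations(trials, labels, res,
                             canonicalInstitutions(corp$dictionary),
                             lexiconDiseases(corp$lexicon),
                             phase = "ALL", window = c(2008, 2013))
    v <- matrixValues(cm)
    inPanel <- res != "UNRESOLVED"
    expect_equal(sum(v[, colnames(v) != "all_cancer"]),
                 sum(vapply(labels[inPanel], length, 1L)))
    expect_equal(sum(v[, "all_cancer"]), sum(inPanel))
})

test_that("summed impact factor adds matching journals' factors", {
    lex <- tinyLexicon()
    dict <- synonymDictionary(data.frame(
        synonym = c("Lakeside Univ Hospital", "Riverbend Med Ctr"),
        canonical = c("Lakeside", "Riverbend")))
    ift <- impactFactorTable(c("Journal A" = 1, "Journal B" = 2,
                               "Journal C" = 3))
    pubs <- rbind(
        makePubRow("1", "Journal A", 2010L,
                   mesh_terms = "*Stomach Neoplasms"),
        makePubRow("2", "Journal B", 2011L,
                   mesh_terms = "*Stomach Neoplasms"),
        makePubRow("3", "Journal C", 2012L,
                   mesh_terms = "*Stomach Neoplasms"))
    sm <- summedImpactFactor(pubs, dict, lex, ift, phase = "P2",
                             window = c(2008, 2013))
    expect_equal(matrixValues(sm)["Lakeside", "gastric"], 6)
    expect_equal(matrixValues(sm)["Riverbend", "gastric"], 0)
    expect_equal(matrixValues(sm)["Lakeside", "all_cancer"], 6)
    ## unlisted journal contributes 0 with a warning
    pubs2 <- makePubRow("9", "Obscure Journal", 2010L,
                        mesh_terms = "*Stomach Neoplasms")
    expect_warning(
        sm2 <- summedImpactFactor(pubs2, dict, lex, ift, phase = "P2",
                                  window = c(2008, 2013)),
        "Obscure Journal")
    expect_equal(matrixValues(sm2)["Lakeside", "gastric"], 0)
})

test_that("the composite score matches its definition and bounds", {
    expect_equal(roundHalfUp(scorePair(7.993, 10.329, 1, 2)), 63.69)
    expect_equal(scorePair(5, 5, 7, 7), 100)
    expect_equal(scorePair(0, 10, 0, 5), 0)
    ## zero maxima contribute zero, not NaN
    expect_equal(scorePair(0, 0, 1, 2), 25)
    expect_equal(scorePair(0, 0, 0, 0), 0)
    expect_error(scorePair(11, 10, 1, 2), "true maxima")
    expect_error(scorePair(1, 10, 3, 2), "true maxima")
})

test_that("scoreboard construction normalizes by column maxima and ranks", {
    sif <- sifMatrix(matrix(c(10, 5), 2, 1,
                            dimnames = list(c("A", "B"), "d")))
    reg <- countMatrix(matrix(c(2, 2), 2, 1,
                              dimnames = list(c("A", "B"), "d")))
    sb <- buildScoreboard(sif, reg)
    expect_equal(unname(matrixValues(sb)[, "d"]), c(100, 75))
    expect_equal(unname(scoreRanks(sb)[, "d"]), c(1L, 2L))
    ## all-zero matrices produce all-zero scores (floor drops the column,
    ## so disable the floor for this degenerate check)
    z <- matrix(0, 2, 1, dimnames = list(c("A", "B"), "d"))
    sbz <- buildScoreboard(sifMatrix(z), countMatrix(z),
                           activityFloor = FALSE)
    expect_true(all(matrixValues(sbz) == 0))
    ## label mismatch is an alignment error
    bad <- countMatrix(matrix(c(2, 2), 2, 1,
                              dimnames = list(c("A", "C"), "d")))
    expect_error(buildScoreboard(sif, bad), "labels")
})

test_that("scores are scale-invariant, monotone and bounded", {
    set.seed(91)
    for (rep in 1:20) {
        n <- 12; k <- 4
        s <- matrix(stats::rexp(n * k, 1 / 50), n, k,
                    dimnames = list(paste0("I", 1:n), paste0("d", 1:k)))
        r <- matrix(stats::rpois(n * k, 4), n, k, dimnames = dimnames(s))
        sb <- buildScoreboard(sifMatrix(s), countMatrix(r),
                              activityFloor = FALSE)
        sc <- matrixValues(sb)
        expect_true(all(sc >= 0 & sc <= 100 + 1e-9))
        ## scale invariance: rescaling one disease's SIF column
        s2 <- s; s2[, 2] <- s2[, 2] * 7.3
        sb2 <- buildScoreboard(sifMatrix(s2), countMatrix(r),
                               activityFloor = FALSE)
        expect_equal(matrixValues(sb2)[, 2], sc[, 2], tolerance = 1e-12)
        ## monotonicity: raising a non-maximal cell never lowers its score
        i <- which.min(s[, 1])
        s3 <- s; s3[i, 1] <- min(s3[i, 1] + 1, max(s3[, 1]))
        sb3 <- buildScoreboard(sifMatrix(s3), countMatrix(r),
                               activityFloor = FALSE)
        expect_gte(matrixValues(sb3)[i, 1], sc[i, 1] - 1e-12)
        ## score 100 iff both maxima attained (both positive here)
        hits <- which(sc > 100 - 1e-9)
        for (h in hits) {
            ii <- (h - 1) %% n + 1; dd <- (h - 1) %/% n + 1
            expect_equal(s[ii, dd], max(s[, dd]))
            expect_equal(r[ii, dd], max(r[, dd]))
        }
    }
})

test_that("the activity floor drops diseases with no registrations or SIF", {
    s <- cbind(d1 = c(5, 1), d2 = c(0, 0), all_cancer = c(5, 1))
    r <- cbind(d1 = c(1, 0), d2 = c(2, 1), all_cancer = c(3, 1))
    rownames(s) <- rownames(r) <- c("A", "B")
    sb <- buildScoreboard(sifMatrix(s), countMatrix(r))
    expect_equal(sb@dropped, "d2")
    expect_setequal(colnames(matrixValues(sb)), c("d1", "all_cancer"))
})

test_that("top-k with ties equals the brute-force oracle", {
    ## forced example: ranks 1,2,2,4 cut at k=3 keeps exactly 3
    sif <- sifMatrix(matrix(c(100, 50, 50, 10), 4, 1,
                            dimnames = list(c("A", "B", "C", "D"), "d")))
    reg <- countMatrix(matrix(c(0, 0, 0, 0), 4, 1,
                              dimnames = list(c("A", "B", "C", "D"), "d")))
    sb <- buildScoreboard(sif, reg, activityFloor = FALSE)
    top <- topKWithTies(sb, "d", 3)
    expect_equal(top$institution, c("A", "B", "C"))
    expect_equal(top$rank, c(1L, 2L, 2L))

    set.seed(101)
    for (rep in 1:1000) {
        n <- sample(5:20, 1)
        vals <- sample(c(0, 25, 50, 50, 75, 100, runif(3, 0, 100)), n,
                       replace = TRUE)
        names(vals) <- sprintf("I%02d", seq_len(n))
        k <- sample(1:12, 1)
        s <- matrix(vals, n, 1, dimnames = list(names(vals), "d"))
        r <- matrix(0, n, 1, dimnames = list(names(vals), "d"))
        sb <- buildScoreboard(sifMatrix(s), countMatrix(r),
                              activityFloor = FALSE)
        got <- topKWithTies(sb, "d", k)
        want <- bruteTopK(matrixValues(sb)[, "d"], k)
        expect_equal(got$institution, want$institution)
        expect_equal(got$score, want$score)
    }
})

test_that("appearance tallies count top-10 membership and co-firsts", {
    ## single disease, single institution
    one <- buildScoreboard(
        sifMatrix(matrix(3, 1, 1, dimnames = list("A", "d"))),
        countMatrix(matrix(1, 1, 1, dimnames = list("A", "d"))))
    t1 <- appearanceTally(one)
    expect_equal(t1$appearances, 1L)
    expect_equal(t1$firsts, 1L)
    ## co-firsts inflate: sum of firsts >= number of active diseases
    set.seed(111)
    n <- 8; k <- 5
    s <- matrix(stats::rexp(n * k, 1 / 20), n, k,
                dimnames = list(paste0("I", 1:n), paste0("d", 1:k)))
    r <- matrix(stats::rpois(n * k, 3) + 1, n, k, dimnames = dimnames(s))
    sb <- buildScoreboard(sifMatrix(s), countMatrix(r))
    tal <- appearanceTally(sb, k = 3)
    expect_gte(sum(tal$firsts), ncol(matrixValues(sb)) - 1L)
    expect_true(all(tal$firsts <= tal$appearances))
    expect_true(all(tal$appearances <= ncol(matrixValues(sb)) - 1L))
    ## enumeration oracle for firsts
    for (d in setdiff(colnames(matrixValues(sb)), "all_cancer")) {
        sc <- matrixValues(sb)[, d]
        winners <- names(sc)[sc == max(sc)]
        for (w in winners)
            expect_gte(tal$firsts[tal$institution == w], 1L)
    }
})

test_that("rank-score curves are nonincreasing and start at 100 when one
           institution holds both maxima", {
    set.seed(121)
    n <- 10; k <- 4
    s <- matrix(stats::rexp(n * k, 1 / 20), n, k,
                dimnames = list(paste0("I", 1:n), paste0("d", 1:k)))
    r <- matrix(stats::rpois(n * k, 3) + 1, n, k, dimnames = dimnames(s))
    ## force a dominant institution in disease 1
    s[1, 1] <- max(s[, 1]) + 1; r[1, 1] <- max(r[, 1]) + 1
    sb <- buildScoreboard(sifMatrix(s), countMatrix(r))
    curves <- rankScoreCurves(sb)
    for (d in unique(curves$disease)) {
        blk <- curves[curves$disease == d, ]
        expect_true(all(diff(blk$score) <= 1e-9))
        expect_true(all(diff(blk$rank) >= 0))
    }
    d1 <- curves[curves$disease == "d1", ]
    expect_equal(d1$score[1], 100)
    expect_equal(d1$rank[1], 1L)
})
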