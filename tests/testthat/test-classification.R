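test_that("keywords match as substrings and the gap regex honours its bound", {
    m <- compileLexicon(tinyLexicon())
    ## regex fires across a gap the literal phrase cannot cover
    expect_equal(classifyText("gastric adenoid cancer", m), "gastric")
    ## 150 filler characters exceed the {1,100} bound
    far <- paste0("gastric ", strrep("x", 150), " cancer")
    expect_equal(classifyText(far, m), character(0))
    near <- paste0("gastric ", strrep("x", 50), " cancer")
    expect_equal(classifyText(near, m), "gastric")
    ## keyword list behaves as a case-insensitive OR
    expect_equal(classifyText("A study of METASTATIC BLADDER CANCER", m),
                 "urothelial")
    expect_equal(classifyText("", m), character(0))
})

test_that("whitespace is normalized before the gap is measured", {
    m <- compileLexicon(tinyLexicon())
    ## 200 raw characters of whitespace collapse to one space
    txt <- paste0("gastric", strrep(" ", 200), "cancer")
    expect_equal(classifyText(txt, m), "gastric")
})

test_that("invalid gap regex fails at compilation, naming the disease", {
    lex <- diseaseLexicon("broken", list("kw"), "(", list("Mesh"))
    expect_error(compileLexicon(lex), "broken")
})

test_that("word-boundary mode is stricter than substring mode", {
    lex <- diseaseLexicon("melanoma", list("melanoma"), NA, list("Melanoma"))
    expect_equal(classifyText("amelanomatous lesion", compileLexicon(lex)),
                 "melanoma")
    expect_equal(classifyText("amelanomatous lesion",
                              compileLexicon(lex, wordBoundary = TRUE)),
                 character(0))
    expect_equal(classifyText("with melanoma present",
                              compileLexicon(lex, wordBoundary = TRUE)),
                 "melanoma")
})

test_that("trials classify from title, conditions and description jointly", {
    m <- compileLexicon(tinyLexicon())
    t1 <- makeTrialRow(conditions = "Bladder Cancer",
                       title = "A dose-finding study",
                       description = "Evaluation of agent X.")
    expect_equal(classifyTrial(t1, m)$diseases, "urothelial")
    t2 <- makeTrialRow(title = "Management of oral mucositis",
                       conditions = "Oral Mucositis")
    expect_equal(classifyTrial(t2, m)$diseases, character(0))
    t3 <- makeTrialRow(title = "gastric cancer and cervical cancer cohort")
    expect_setequal(classifyTrial(t3, m)$diseases, c("gastric", "cervical"))
    res <- classifyTrial(t3, m)
    expect_setequal(unique(res$matched_patterns$disease), res$diseases)
})

test_that("adding a keyword never removes a label (monotonicity)", {
    set.seed(11)
    base <- tinyLexicon()
    grown <- diseaseLexicon(
        disease = base@entries$disease,
        keywords = list(c("gastric cancer", "stomach cancer"),
                        base@entries$keywords[[2]],
                        base@entries$keywords[[3]]),
        regex = base@entries$regex,
        mesh = base@entries$mesh)
    texts <- c("stomach cancer follow-up", "bladder cancer and more",
               "gastric adenoid cancer", "nothing relevant",
               "cervical cancer screening")
    mb <- compileLexicon(base); mg <- compileLexicon(grown)
    for (tx in texts)
        expect_true(all(classifyText(tx, mb) %in% classifyText(tx, mg)))
})

test_that("classification distributes over concatenation with a safe joiner", {
    m <- compileLexicon(tinyLexicon())
    pieces <- c("gastric cancer cohort", "bladder cancer arm",
                "no disease here", "cervical cancer trial")
    for (a in pieces) for (b in pieces) {
        joined <- paste(a, "#", b)  # '#' occurs in no pattern alphabet
        expect_setequal(classifyText(joined, m),
                        union(classifyText(a, m), classifyText(b, m)))
    }
})

test_that("publication MeSH classification is exact match, umbrella for all_cancer", {
    lex <- tinyLexicon()
    pub <- makePubRow(mesh_terms = "*Uterine Cervical Neoplasms")
    expect_true(classifyPublication(pub, lex, "cervical"))
    expect_false(classifyPublication(pub, lex, "gastric"))
    expect_true(classifyPublication(pub, lex, "all_cancer"))
    expect_false(classifyPublication(makePubRow(mesh_terms = "Humans"),
                                     lex, "all_cancer"))
    nomesh <- makePubRow(); nomesh$mesh_terms <- I(list(character(0)))
    expect_false(classifyPublication(nomesh, lex, "cervical"))
    expect_error(classifyPublication(pub, lex, "prostate"), "unknown disease")
    ## major-topic-only mode ignores non-starred terms
    minor <- makePubRow(mesh_terms = "Uterine Cervical Neoplasms")
    expect_true(classifyPublication(minor, lex, "cervical"))
    expect_false(classifyPublication(minor, lex, "cervical",
                                     majorTopicOnly = TRUE))
})

test_that("query strings follow the published grammar and parse back", {
    q <- buildPubmedQuery(c("Barnes-Jewish Hospital", "Washington University",
                            "Alvin J. Siteman Cancer Center"),
                          "uterine cervical neoplasms", "P2", c(2008, 2013))
    expect_equal(q, paste("(Barnes-Jewish Hospital[AD] OR",
                          "Washington University[AD] OR",
                          "Alvin J. Siteman Cancer Center[AD])",
                          "2008:2013[DP] Clinical trial, Phase II[PT]",
                          "uterine cervical neoplasms[MESH]"))
    expect_equal(buildPubmedQuery("X", window = c(2008, 2013)),
                 "(X[AD]) 2008:2013[DP]")
    expect_error(buildPubmedQuery(character(0), window = c(2008, 2013)),
                 "at least one")

    ## round-trip through the independent splitter
    cases <- list(
        list(syn = c("A Hosp", "B Center"), mesh = "stomach neoplasms",
             phase = "P1", window = c(2009, 2011)),
        list(syn = "Solo Clinic", mesh = NULL, phase = NULL,
             window = c(2008, 2013)),
        list(syn = c("X", "Y"), mesh = NULL, phase = "P2_3",
             window = c(2010, 2012)))
    for (cs in cases) {
        q <- buildPubmedQuery(cs$syn, cs$mesh, cs$phase, cs$window)
        p <- parseQueryString(q)
        expect_equal(p$synonyms, cs$syn)
        expect_equal(p$window, cs$window)
        expect_equal(p$mesh, cs$mesh)
        if (is.null(cs$phase)) expect_null(p$phaseLabel)
        else expect_match(p$phaseLabel, "^Clinical trial, Phase")
    }
})

test_that("local query matching equals the conjunction of its four clauses", {
    lex <- tinyLexicon()
    syn <- c("Lakeside Univ Hospital", "Lakeside Comprehensive Center")
    window <- c(2008, 2013)
    set.seed(21)
    meshes <- c("Stomach Neoplasms", "Uterine Cervical Neoplasms", "Humans")
    affils <- c("Dept of Oncology, Lakeside Univ Hospital, USA",
                "Lakeside Comprehensive Center, Floor 2",
                "Riverbend Med Ctr, Elsewhere")
    pts <- list("Clinical Trial, Phase II",
                c("Journal Article", "Clinical Trial, Phase I"),
                "Journal Article")
    for (i in 1:50) {
        pub <- makePubRow(pmid = as.character(i),
                          pub_year = sample(2005:2015, 1),
                          pub_types = pts[[sample(3, 1)]],
                          mesh_terms = paste0("*", sample(meshes, 1)),
                          affiliations = sample(affils, 1))
        got <- matchPublicationQuery(pub, syn, window, phase = "P2",
                                     disease = "gastric", lexicon = lex)
        cl1 <- any(vapply(tolower(syn), function(s)
            any(grepl(s, tolower(pub$affiliations[[1]]), fixed = TRUE)),
            logical(1)))
        cl2 <- pub$pub_year >= window[1] && pub$pub_year <= window[2]
        cl3 <- "clinical trial, phase ii" %in% tolower(pub$pub_types[[1]])
        cl4 <- classifyPublication(pub, lex, "gastric")
        expect_identical(got, cl1 && cl2 && cl3 && cl4)
    }
    ## window violation alone is disqualifying
    pub <- makePubRow(pub_year = 2007L)
    expect_false(matchPublicationQuery(pub, syn, window, phase = "P2",
                                       disease = "cervical", lexicon = lex))
})

test_that("the unclassified audit sample is the latest-started subset", {
    m <- compileLexicon(tinyLexicon())
    n <- 200
    set.seed(31)
    trials <- do.call(rbind, lapply(seq_len(n), function(i)
        makeTrialRow(trial_id = sprintf("NCT%08d", i),
                     title = if (i %% 3 == 0) "gastric cancer study"
                             else "an unrelated record",
                     start_date = as.Date("2008-01-01") +
                         sample(0:2000, 1))))
    labels <- classifyTrials(trials, m)
    got <- sampleUnclassified(trials, labels, 25)
    expect_equal(nrow(got), 25L)
    ## oracle: filter, sort by (-date, id), take n
    unc <- trials[vapply(labels, length, 1L) == 0L, ]
    unc <- unc[order(-as.numeric(unc$start_date), unc$trial_id), ]
    expect_equal(got$trial_id, utils::head(unc$trial_id, 25))
    ## fewer than n available returns all
    few <- trials[1:5, ]; fewLab <- labels[1:5]
    expect_lte(nrow(sampleUnclassified(few, fewLab, 100)), 5L)
})
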