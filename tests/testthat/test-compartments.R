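test_that("score quartiles use type-7 interpolation over considered scores", {
    t13 <- ruleFixtures()$quartilesFromTree$tree   # scores .2 .4 .6 .8
    q <- scoreQuartiles(t13)
    expect_equal(q[["Q2"]], 0.5)
    expect_equal(q[["Q3"]], 0.65)
    # all equal, and a single score
    t1 <- mkTree(list(c(0.7, 0.7, 0.7)))
    expect_equal(unname(scoreQuartiles(t1)), c(0.7, 0.7))
    t2 <- mkTree(list(c(0.42)))
    expect_equal(unname(scoreQuartiles(t2)), c(0.42, 0.42))
})

test_that("the rule engine reproduces every hand-traced fixture", {
    fx <- ruleFixtures()
    expect_gte(length(fx), 12L)
    for (nm in names(fx)) {
        f <- fx[[nm]]
        sel <- suppressWarnings(identifyCompartments(f$tree, f$q))
        sel <- labelMinor(sel, f$tree)
        if (length(f$expect) == 0L) {
            expect_identical(nrow(sel), 0L, label = paste("fixture", nm))
        } else {
            got <- setNames(sel$label, sel$factor_id)
            expect_identical(got[order(names(got))],
                             f$expect[order(names(f$expect))],
                             label = paste("fixture", nm))
        }
    }
})

test_that("every emitted major passes the independent rule oracle", {
    fx <- ruleFixtures()
    for (nm in names(fx)) {
        f <- fx[[nm]]
        q <- if (is.null(f$q)) scoreQuartiles(f$tree) else f$q
        sel <- suppressWarnings(identifyCompartments(f$tree, f$q))
        for (i in which(sel$label == "major"))
            expect_true(oracleValidMajor(f$tree, sel$factor_id[i],
                                         q[["Q2"]], q[["Q3"]]),
                        label = paste(nm, sel$factor_id[i]))
    }
    # and on randomized trees
    set.seed(77)
    for (rep in 1:20) {
        nc <- sample(2:4, 1)
        chains <- lapply(seq_len(nc), function(i)
            round(runif(sample(3:7, 1)), 2))
        parents <- c(list(NULL), lapply(seq_len(nc - 1) + 1, function(i)
            list(1L, sample(seq_along(chains[[1]]), 1))))[seq_len(nc)]
        tr <- try(mkTree(chains, parents), silent = TRUE)
        if (inherits(tr, "try-error")) next
        q <- scoreQuartiles(tr)
        sel <- suppressWarnings(identifyCompartments(tr))
        for (i in which(sel$label == "major"))
            expect_true(oracleValidMajor(tr, sel$factor_id[i],
                                         q[["Q2"]], q[["Q3"]]))
        # determinism: identical tree, identical selection
        expect_identical(sel, suppressWarnings(identifyCompartments(tr)))
    }
})

test_that("final assembly copies weights verbatim from the runs of origin", {
    set.seed(55)
    g <- sprintf("g%03d", 1:30)
    s <- sprintf("s%02d", 1:8)
    mkRun <- function(k) {
        methods::new("NMFRun", kTilde = as.integer(k),
            factorIds = paste0(k, ".", seq_len(k)),
            geneWeights = matrix(runif(30 * k), 30, k,
                                 dimnames = list(g, NULL)),
            sampleWeights = matrix(runif(k * 8), k, 8,
                                   dimnames = list(NULL, s)),
            objective = 1)
    }
    tree <- newFactorTree()
    for (k in 2:5) tree <- addRun(tree, mkRun(k), nTop = 10)
    sel <- data.frame(factor_id = c("3.2", "5.1", "4.3"),
                      label = c("major", "major", "unstable"),
                      k = c(3L, 5L, 4L), score = c(0.9, 0.8, 0.7),
                      stringsAsFactors = FALSE)
    cs <- assembleCompartments(sel, tree)
    # unstable excluded by default; columns mix two different runs
    expect_identical(compartments(cs)$factor_id, c("3.2", "5.1"))
    expect_identical(colnames(geneWeights(cs)), c("D3.2", "D5.1"))
    expect_identical(unname(geneWeights(cs)[, 1]),
                     unname(tree@runs[["3"]]@geneWeights[, 2]))
    expect_identical(unname(sampleWeights(cs)[2, ]),
                     unname(tree@runs[["5"]]@sampleWeights[1, ]))
    # include unstable + annotation naming
    cs2 <- assembleCompartments(sel, tree, includeUnstable = TRUE,
                                annotations = c(`3.2` = "immune"))
    expect_identical(compartments(cs2)$name,
                     c("D3.2:immune", "D5.1", "D4.3"))
    expect_true(validObject(cs2))
    expect_error(assembleCompartments(sel[0, ], tree), "empty")
})
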