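test_that("factor similarity is the overlap fraction of equal-length lists", {
    a <- sprintf("g%03d", 1:250)
    expect_equal(factorSimilarity(a, a), 1)
    expect_equal(factorSimilarity(a, sprintf("h%03d", 1:250)), 0)
    b <- c(sprintf("g%03d", 1:25), sprintf("h%03d", 1:225))
    expect_equal(factorSimilarity(a, b), 0.1)
    expect_error(factorSimilarity(a, a[1:100]))
})

test_that("linking scores factors against the previous rank", {
    g <- function(o, n = 250) sprintf("g%05d", o + seq_len(n))
    mkRun <- function(k, lists) {
        W <- matrix(0.1, 10, k); H <- matrix(0.1, k, 4)
        run <- methods::new("NMFRun", kTilde = as.integer(k),
            factorIds = paste0(k, ".", seq_len(k)),
            geneWeights = W, sampleWeights = H, objective = 0)
        list(run = run, lists = lists)
    }
    tree <- newFactorTree()
    r2 <- mkRun(2, list(g(0), g(1000)))
    r3 <- mkRun(3, list(g(0),                      # identical to 2.1
                        c(g(1000, 150), g(5000, 100)),  # 0.6 with 2.2
                        c(g(1000, 20), g(6000, 230))))  # max sim 0.08
    for (r in list(r2, r3)) {
        tree <- addRun(tree, r$run)
        for (j in seq_along(r$lists))
            tree@topGenes[[r$run@factorIds[j]]] <- r$lists[[j]]
    }
    tree <- linkRuns(tree, 3)
    f <- tree@factors
    expect_equal(f$score[f$factor_id == "3.1"], 1.0)
    expect_identical(f$parent_id[f$factor_id == "3.1"], "2.1")
    expect_equal(f$score[f$factor_id == "3.2"], 0.6)
    expect_identical(f$parent_id[f$factor_id == "3.2"], "2.2")
    # below the 0.1 threshold: newly emerged, score = max similarity
    expect_equal(f$score[f$factor_id == "3.3"], 0.08)
    expect_true(is.na(f$parent_id[f$factor_id == "3.3"]))
    expect_true(f$newly_emerged[f$factor_id == "3.3"])
    # two children may share one parent
    tree2 <- tree
    r4 <- mkRun(4, list(c(g(0, 150), g(7000, 100)),
                        c(g(0, 150), g(8000, 100)),
                        g(9000), g(1000)))
    tree2 <- addRun(tree2, r4$run)
    for (j in seq_along(r4$lists))
        tree2@topGenes[[r4$run@factorIds[j]]] <- r4$lists[[j]]
    tree2 <- linkRuns(tree2, 4)
    f2 <- tree2@factors
    expect_identical(f2$parent_id[f2$factor_id %in% c("4.1", "4.2")],
                     c("3.1", "3.1"))
    expect_error(linkRuns(tree, 7), "present")
})

test_that("the rank schedule honors the start and stop rules exactly", {
    scripted <- function(m) {
        ks <- seq(2L, length.out = length(m))
        function(k) m[match(k, ks)]
    }
    # scripted sequence: stop after the 4th consecutive sub-0.5 run
    s1 <- scheduleK(scripted(c(0.8, 0.7, 0.4, 0.4, 0.4, 0.4, 0.9)),
                    kMax = 20)
    expect_identical(s1$executed, 2:7)
    expect_identical(s1$consideredStart, 2L)
    expect_identical(s1$consideredK, 2:7)
    expect_identical(s1$stopped, "lowscore")
    # consideration starts at the first median above 0.5
    s2 <- scheduleK(scripted(c(0.3, 0.6, 0.7, 0.4, 0.4, 0.4, 0.4)),
                    kMax = 20)
    expect_identical(s2$consideredStart, 3L)
    expect_identical(s2$consideredK, 3:8)
    # a recovery resets the streak
    s3 <- scheduleK(scripted(c(0.8, 0.4, 0.4, 0.4, 0.6, 0.4, 0.4,
                               0.4, 0.4)), kMax = 20)
    expect_identical(max(s3$executed), 10L)
    # all high up to the cap: warning, stopped = "cap"
    expect_warning(s4 <- scheduleK(scripted(rep(0.9, 50)), kMax = 12),
                   "cap")
    expect_identical(s4$stopped, "cap")
    expect_identical(max(s4$executed), 12L)
    # boundary: exactly 0.5 neither starts consideration nor counts
    # toward the stop streak
    s5 <- scheduleK(scripted(c(0.5, 0.5, 0.6, 0.4, 0.4, 0.4, 0.4)),
                    kMax = 20)
    expect_identical(s5$consideredStart, 4L)
    expect_identical(s5$stopped, "lowscore")
    # never considered
    s6 <- scheduleK(scripted(c(0.2, 0.2, 0.2, 0.2)), kMax = 20)
    expect_true(is.na(s6$consideredStart))
    expect_length(s6$consideredK, 0L)
})

test_that("branch enumeration is a forest over the considered ranks", {
    fx <- ruleFixtures()
    t8 <- fx$branchSplitTwoMajors$tree
    br <- CompartmentNMF:::treeBranches(t8)
    expect_length(br, 2L)
    expect_true(all(vapply(br, function(b) b[1] == "2.1", TRUE)))
    # every link joins adjacent ranks (validity) and each factor has
    # at most one parent
    f <- t8@factors
    expect_true(all(table(f$factor_id) == 1))
    expect_true(validObject(t8))
})

test_that("DOT export lists every factor and link", {
    fx <- ruleFixtures()
    tr <- fx$majorSimple$tree
    f <- tempfile(fileext = ".dot")
    exportTreeDot(tr, f)
    txt <- readLines(f)
    expect_true(any(grepl("digraph", txt)))
    expect_equal(sum(grepl("->", txt)),
                 sum(!is.na(tr@factors$parent_id)))
})
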