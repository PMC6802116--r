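test_that("multiplicative updates decrease the objective at every step", {
    set.seed(21)
    A <- matrix(rgamma(50 * 12, 2), 50, 12)
    for (i in 1:5) {
        W0 <- matrix(runif(50 * 3), 50, 3)
        H0 <- matrix(runif(3 * 12), 3, 12)
        tr <- multiplicativeNMF(A, W0, H0, steps = 10)$objective
        expect_length(tr, 11L)
        expect_true(all(diff(tr) <= 1e-9 * tr[-11]))
    }
})

test_that("an exactly rank-1 matrix is factorized to numerical zero", {
    set.seed(22)
    w <- runif(30, 0.5, 2); h <- runif(8, 0.5, 2)
    A <- outer(w, h)
    r <- innerNMF(A, 1, nmfParams(R = 1, seed = 1))
    expect_lt(r$objective / norm(A, "F"), 1e-8)
})

test_that("two-phase refinement honors its descent contracts", {
    set.seed(23)
    A <- matrix(rgamma(60 * 15, 2), 60, 15)
    r <- innerNMF(A, 3, nmfParams(R = 1, seed = 1), returnCandidates = TRUE)
    # the selected multiplicative candidate has the smallest residual
    expect_equal(r$muObjective, min(r$candidateObjectives))
    # ALS refinement never ends above the selected candidate
    expect_lte(r$objective, r$muObjective)
    expect_true(all(r$W >= 0) && all(r$H >= 0))
    expect_error(innerNMF(A, 20, nmfParams(R = 1)), "rank")
})

test_that("exclusive-weight ranking matches its brute-force oracle", {
    # raw differences on the documented toy: row (5,1) scores 4 for
    # factor 1, row (2,3) scores -1
    W <- rbind(c(5, 1), c(2, 3))
    S <- exclusiveScores(W, normalize = FALSE)
    expect_equal(S[, 1], c(4, -1))
    expect_equal(S[, 2], c(-4, 1))
    r <- rankExclusiveWeight(W, 1, normalize = FALSE)
    expect_identical(as.integer(r[1:2]), c(1L, 2L))
    # identical columns: all scores zero, ranking = input order
    W2 <- cbind(c(1, 2, 3), c(1, 2, 3))
    expect_identical(as.integer(rankExclusiveWeight(W2, 1)), 1:3)
    # single column: loadings themselves
    W3 <- cbind(c(0.3, 2, 1))
    expect_identical(as.integer(rankExclusiveWeight(W3, 1)), c(2L, 3L, 1L))
    # random matrices, both normalized and raw, vs the oracle
    set.seed(24)
    for (i in 1:10) {
        W4 <- matrix(runif(20 * 3), 20, 3)
        for (nz in c(TRUE, FALSE)) for (j in 1:3)
            expect_identical(as.integer(rankExclusiveWeight(W4, j, nz)),
                             bruteExclusiveRank(W4, j, nz))
    }
})

test_that("topFeatures returns names in oracle order", {
    set.seed(25)
    W <- matrix(runif(500 * 3), 500, 3,
                dimnames = list(sprintf("g%03d", 1:500), NULL))
    expect_identical(topFeatures(W, 2, n = 500),
                     rownames(W)[bruteExclusiveRank(W, 2)])
    expect_length(topFeatures(W, 1, n = 250), 250L)
})

test_that("column subsampling is sized, distinct and seed-deterministic", {
    A <- matrix(1:40, 4, 10, dimnames = list(NULL, paste0("s", 1:10)))
    set.seed(1); s1 <- subsampleColumns(A, 0.8)
    expect_identical(ncol(s1), 8L)
    expect_false(anyDuplicated(colnames(s1)) > 0)
    set.seed(1); s2 <- subsampleColumns(A, 0.8)
    expect_identical(s1, s2)
    expect_identical(subsampleColumns(A, 1), A)  # sorted draw = identity
    expect_error(subsampleColumns(A, 0.2, minColumns = 5), "below")
})

test_that("consensus accumulation counts pairs, duplicates and scales linearly", {
    C <- updateConsensus(NULL, list(c("a", "b")))
    expect_equal(C$counts["a", "a"], 1)
    expect_equal(C$counts["a", "b"], 1)
    expect_equal(C$counts["b", "a"], 1)
    # gene in the top set of two factors of one repetition:
    # diagonal increments twice
    C2 <- updateConsensus(NULL, list(c("a", "b"), c("a", "c")))
    expect_equal(C2$counts["a", "a"], 2)
    expect_equal(C2$counts["b", "b"], 1)
    expect_equal(C2$counts["b", "c"], 0)
    # linearity in repetitions
    sets <- list(c("a", "b"), c("c", "d"))
    C1 <- updateConsensus(NULL, sets)
    C5 <- updateConsensus(NULL, rep(sets, 5))
    expect_equal(C5$counts[C1$genes, C1$genes], 5 * C1$counts)
    # symmetry
    expect_identical(C5$counts, t(C5$counts))
})

test_that("consensus clustering recovers blocks and builds the seed", {
    blockSets <- c(rep(list(c("a1", "a2", "a3")), 10),
                   rep(list(c("b1", "b2")), 10),
                   rep(list(c("c1", "c2", "c3", "c4")), 10))
    C <- updateConsensus(NULL, blockSets)
    W <- clusterConsensusToSeed(C, 3)
    expect_identical(dim(W), c(9L, 3L))
    expect_true(all(W %in% c(1, 0.01)))
    expect_true(all(rowSums(W == 1) == 1))      # one high entry per gene
    expect_true(all(colSums(W == 1) >= 1))      # no empty cluster
    cl <- apply(W, 1, which.max)
    expect_length(unique(cl[c("a1", "a2", "a3")]), 1L)
    expect_length(unique(cl[c("b1", "b2")]), 1L)
    expect_length(unique(cl[c("c1", "c2", "c3", "c4")]), 1L)
    expect_length(unique(cl[c("a1", "b1", "c1")]), 3L)
    # K = 1: a single all-high column
    W1 <- clusterConsensusToSeed(C, 1)
    expect_true(all(W1 == 1))
    expect_error(clusterConsensusToSeed(updateConsensus(NULL,
                 list(c("x", "y"))), 5), "fewer")
})

test_that("seeded final NMF recovers a noiseless mixture deterministically", {
    sim <- simulateMixture(nFeatures = 300, nSamples = 24, kTrue = 3,
                           markersPerComp = 40, noiseSd = 0, seed = 31)
    A <- sim$A
    Wt <- geneWeights(sim$truth)
    seedM <- matrix(0.01, 3 * 40, 3,
                    dimnames = list(rownames(A)[1:120], NULL))
    for (k in 1:3) seedM[((k - 1) * 40 + 1):(k * 40), k] <- 1
    p <- nmfParams(R = 1, seed = 1)
    fit <- finalSeededNMF(A, seedM, p)
    expect_true(all(fit$W >= 0) && all(fit$H >= 0))
    for (k in 1:3)
        expect_gt(cor(fit$W[, k], Wt[, k]), 0.99)
    # determinism: same seed matrix, same result
    fit2 <- finalSeededNMF(A, seedM, p)
    expect_identical(fit$W, fit2$W)
    # descent contract vs the seed with its NNLS-optimal H
    W0 <- matrix(p$seedLow, nrow(A), 3, dimnames = list(rownames(A), NULL))
    W0[rownames(seedM), ] <- seedM
    H0 <- projectCompartmentWeights(W0, A)
    expect_lte(fit$objective, norm(A - W0 %*% H0, "F"))
    expect_error(finalSeededNMF(A, rbind(seedM,
        matrix(1, 1, 3, dimnames = list("absent", NULL))), p), "absent")
})

test_that("seed training yields a near block-diagonal consensus", {
    sim <- simulateMixture(nFeatures = 400, nSamples = 30, kTrue = 3,
                           markersPerComp = 30, noiseSd = 0.05, seed = 32)
    Ap <- suppressWarnings(filterExpressionFeatures(sim$A, nKeep = 5000))
    p <- nmfParams(R = 30, topGenesConsensus = 25, seed = 5)
    ts <- trainSeed(Ap, 3, p, seed = 5)
    C <- ts$consensus
    blk <- lapply(sim$truth@markerBlocks,
                  function(b) intersect(b, C$genes))
    within <- unlist(lapply(blk, function(b) C$counts[b, b]))
    between <- c(C$counts[blk[[1]], blk[[2]]],
                 C$counts[blk[[1]], blk[[3]]],
                 C$counts[blk[[2]], blk[[3]]])
    expect_gt(mean(within), 5 * max(mean(between), 1e-9))
    # the seed matrix separates the blocks
    cl <- apply(ts$seed, 1, which.max)
    for (b in blk) expect_length(unique(cl[b]), 1L)
})
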