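# Build a two-column weight matrix whose exclusive scores for
# column 1 are exactly `s` (column 2 zero), so the knee geometry can
# be controlled directly.
scoreMatrix <- function(s) {
    W <- cbind(pmax(s, 0), ifelse(s < 0, -s, 0))
    rownames(W) <- sprintf("g%03d", seq_along(s))
    W
}

test_that("the knee cuts the marker list where the curve bends", {
    # 3 high scores, then a sharp drop: chord distance peaks at rank 4,
    # markers = the first 3 (hand-computed: distances .288 at rank 3,
    # .368 at rank 4 on normalized axes)
    W <- scoreMatrix(c(1.0, 0.95, 0.9, 0.05, 0.04, 0.03))
    mk <- selectMarkers(W, 1)
    expect_identical(mk$feature, c("g001", "g002", "g003"))
    expect_true(all(mk$score > 0))
    expect_equal(mk$normScore[1], 1)
})

test_that("degenerate marker curves fall back to the minimal prefix", {
    # numerically straight curve: knee undefined, single top marker
    W <- scoreMatrix(seq(1, 0.1, length.out = 10))
    expect_identical(nrow(selectMarkers(W, 1)), 1L)
    # a single positive gene is the sole marker
    W2 <- scoreMatrix(c(0.8, -0.1, -0.2))
    expect_identical(selectMarkers(W2, 1)$feature, "g001")
    # no positive scores: empty with a warning
    W3 <- cbind(c(0, 0, 0), c(1, 2, 3))
    rownames(W3) <- paste0("g", 1:3)
    expect_warning(mk3 <- selectMarkers(W3, 1), "positive")
    expect_identical(nrow(mk3), 0L)
    expect_error(selectMarkers(W3[, 1, drop = FALSE], 1), "two")
})

test_that("markers are invariant to positive rescaling of the weights", {
    set.seed(66)
    W <- matrix(rgamma(200 * 3, 1), 200, 3,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
    W[1:20, 1] <- W[1:20, 1] + 5
    m1 <- selectMarkers(W, 1)$feature
    expect_identical(selectMarkers(W * 37.5, 1)$feature, m1)
    # per-column rescaling too (ranking is computed on unit-norm columns)
    W2 <- sweep(W, 2, c(0.01, 12, 3), "*")
    expect_identical(selectMarkers(W2, 1)$feature, m1)
})

test_that("KS enrichment matches hand-computed statistics and BH", {
    ranking <- paste0("g", 1:10)
    # set = exactly the top half: complete separation, D = 1
    r1 <- ksEnrichment(ranking, list(top = paste0("g", 1:5)))
    expect_equal(r1$D, 1)
    # alternating positions {1,3,5,7,9}: D = 0.2
    r2 <- ksEnrichment(ranking, list(alt = paste0("g", c(1, 3, 5, 7, 9))))
    expect_equal(r2$D, 0.2)
    # BH on p-values {0.01, 0.02, 0.03} -> all 0.03
    fake <- ksEnrichment(ranking, list(a = paste0("g", 1:5),
                                       b = paste0("g", c(1, 3, 5, 7, 9))))
    expect_equal(fake$q, p.adjust(fake$p, "BH"))
    expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
    # empty intersection: skipped with warning
    expect_warning(r3 <- ksEnrichment(ranking,
        list(good = paste0("g", 1:5), none = c("x1", "x2"))), "skipped")
    expect_identical(r3$set, "good")
})

test_that("permutation p-values agree with asymptotic ones for clear signals", {
    set.seed(71)
    ranking <- sprintf("g%03d", 1:100)
    gs <- list(top = ranking[1:10],                    # strong enrichment
               rnd = sample(ranking, 10))              # null set
    asym <- ksEnrichment(ranking, gs)
    perm <- withr::with_seed(72, ksEnrichment(ranking, gs,
                                              nPermutations = 400))
    expect_identical(perm$D, asym$D)                   # same statistic
    expect_lt(perm$p[1], 0.05)
    expect_gt(perm$p[2], 0.05)
    expect_true(all(perm$p > 0 & perm$p <= 1))
})

test_that("KS p-values are uniform under ranking shuffles", {
    set.seed(101)
    genes <- sprintf("g%04d", 1:2000)
    gs <- list(s = sample(genes, 200))
    p <- replicate(200, ksEnrichment(sample(genes), gs)$p)
    expect_true(all(p >= 0 & p <= 1))
    # duplicate p-values across shuffles are expected (discrete D)
    expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})
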