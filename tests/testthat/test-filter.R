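# row with mean m and sd 2*d/sqrt(3) over four samples
rowMS <- function(m, d) c(m - d, m + d, m - d, m + d)

test_that("expression filter keeps means above Q3 then the most variable", {
    # means 1..8: Q3 (type 7) = 6.25, so the expression step keeps
    # features 7 and 8; feature 7 is made more variable than 8
    A <- rbind(t(vapply(1:6, function(m) rowMS(m, 0.1), numeric(4))),
               rowMS(7, 2), rowMS(8, 1))
    dimnames(A) <- list(paste0("g", 1:8), paste0("s", 1:4))
    f2 <- filterExpressionFeatures(A, nKeep = 2)
    expect_identical(rownames(f2), c("g7", "g8"))
    expect_identical(f2[, ], A[c("g7", "g8"), ])   # exact sub-matrix
    # nKeep = 1 keeps the larger-SD survivor
    expect_identical(rownames(filterExpressionFeatures(A, nKeep = 1)), "g7")
})

test_that("expression filter saturates with a warning and keeps row order", {
    A <- rbind(t(vapply(1:6, function(m) rowMS(m, 0.1), numeric(4))),
               rowMS(7, 2), rowMS(8, 1))
    dimnames(A) <- list(paste0("g", 1:8), paste0("s", 1:4))
    expect_warning(fAll <- filterExpressionFeatures(A, nKeep = 5),
                   "keeping all")
    expect_identical(rownames(fAll), c("g7", "g8"))  # original order
})

test_that("zero-variance survivors rank last; all-constant errors", {
    # 9 low-mean features, then means 7, 8, 9; Q3 of the 12 means
    # falls below 7, so survivors are g10, g11 and the constant g12
    A <- rbind(t(vapply(rep(1, 9), function(m) rowMS(m, 0.1),
                        numeric(4))),
               rowMS(7, 1), rowMS(8, 2), c(9, 9, 9, 9))
    dimnames(A) <- list(paste0("g", 1:12), paste0("s", 1:4))
    f2 <- filterExpressionFeatures(A, nKeep = 2)
    expect_identical(rownames(f2), c("g10", "g11"))
    expect_false("g12" %in% rownames(f2))
    Aconst <- matrix(c(1, 1, 1, 1, 5, 5, 5, 5), 2, 4, byrow = TRUE,
                     dimnames = list(c("a", "b"), paste0("s", 1:4)))
    expect_error(filterExpressionFeatures(Aconst, nKeep = 1),
                 "constant|variable")
})

test_that("ATAC filter applies the mean/SD rule and saturates", {
    A <- rbind(c(1, 1, 1, 1), c(1, 1, 1, 1), c(5, 15, 5, 15))
    dimnames(A) <- list(paste0("L", 1:3), paste0("s", 1:4))
    # grand mean of locus means = 4; mean of locus SDs = 5.77/3
    f <- filterAtacLoci(A, nKeep = 8000)
    expect_identical(rownames(f), "L3")
    # all loci identical: empty survivor set
    Aid <- matrix(3, 4, 5, dimnames = list(paste0("L", 1:4),
                                           paste0("s", 1:5)))
    expect_error(filterAtacLoci(Aid), "uniform|no loci")
})

test_that("ATAC rank-sum reduction keeps loci strong on both criteria", {
    set.seed(7)
    A <- matrix(rpois(30 * 10, 5), 30, 10,
                dimnames = list(paste0("L", 1:30), paste0("s", 1:10)))
    A[1:10, ] <- A[1:10, ] + matrix(rpois(100, 40), 10)  # high mean+var
    f <- filterAtacLoci(A, nKeep = 4)
    expect_identical(nrow(f), 4L)
    expect_true(all(rownames(f) %in% paste0("L", 1:10)))
    mu <- rowMeans(A); sdv <- apply(A, 1, sd)
    surv <- which(mu > mean(mu) & sdv > mean(sdv))
    rs <- rank(mu[surv], ties.method = "first") +
          rank(sdv[surv], ties.method = "first")
    expect_setequal(rownames(f), names(sort(rs, decreasing = TRUE))[1:4])
})

test_that("SummarizedExperiment input is accepted transparently", {
    set.seed(19)
    A <- matrix(rgamma(40 * 6, 2), 40, 6,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:6)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = A))
    expect_identical(filterExpressionFeatures(se, nKeep = 5),
                     filterExpressionFeatures(A, nKeep = 5))
})

test_that("filtering is idempotent and returns exact sub-matrices", {
    set.seed(11)
    A <- matrix(rgamma(60 * 8, 2, 0.5), 60, 8,
                dimnames = list(paste0("g", 1:60), paste0("s", 1:8)))
    Af <- filterExpressionFeatures(A, nKeep = 10)
    expect_identical(filterExpressionFeatures(Af, nKeep = 10), Af)
    expect_true(all(rownames(Af) %in% rownames(A)))
    expect_identical(unclass(Af[, ]), unclass(A[rownames(Af), ]))
    Aa <- filterAtacLoci(A, nKeep = 12)
    expect_identical(filterAtacLoci(Aa, nKeep = 12), Aa)
})
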