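#' @useDynLib CompartmentNMF, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor median quantile rgamma rnorm rpois runif sd
#'   ks.test p.adjust setNames hclust cutree as.dist
#' @importFrom utils head read.delim write.table
NULL

# Coerce input to a validated non-negative numeric matrix with unique
# dimnames; accepts matrix, data.frame or SummarizedExperiment.
asInputMatrix <- function(x, what = "input matrix") {
    if (methods::is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, 1L)
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!is.matrix(x) || !is.numeric(x))
        stop(what, " must be a numeric matrix (or SummarizedExperiment)")
    validateNonNegative(x, what = what)
    x
}

validateNonNegative <- function(x, what = "matrix") {
    if (nrow(x) == 0L || ncol(x) == 0L)
        stop(what, " is empty")
    if (anyNA(x))
        stop(what, " contains missing values")
    neg <- which(x < 0, arr.ind = TRUE)
    if (nrow(neg)) {
        rn <- if (!is.null(rownames(x))) rownames(x)[neg[1L, 1L]]
              else neg[1L, 1L]
        cn <- if (!is.null(colnames(x))) colnames(x)[neg[1L, 2L]]
              else neg[1L, 2L]
        stop(sprintf("%s has a negative value at [%s, %s]: %g",
                     what, rn, cn, x[neg[1L, 1L], neg[1L, 2L]]))
    }
    if (!is.null(rownames(x)) && anyDuplicated(rownames(x)))
        stop(what, " has duplicated feature identifiers")
    if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
        stop(what, " has duplicated sample identifiers")
    invisible(x)
}

# Deterministically derive n child seeds from a master seed without
# disturbing the caller's RNG state.
deriveSeeds <- function(master, n) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, globalenv())
    })
    set.seed(as.integer(master %% .Machine$integer.max))
    sample.int(.Machine$integer.max - 1L, n)
}

# Run an expression under a local RNG seed, restoring state after.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    expr
}

# Maximum-sum assignment between rows and columns of a score matrix.
# Exhaustive over injective mappings for small problems (the usual
# case: K <= 8 compartments), greedy otherwise. Returns a two-column
# matrix of (row, col) index pairs.
assignMatch <- function(score) {
    nr <- nrow(score); nc <- ncol(score)
    if (nr == 0L || nc == 0L)
        return(matrix(integer(), 0L, 2L,
                      dimnames = list(NULL, c("row", "col"))))
    swap <- nr > nc
    if (swap) score <- t(score)
    nr <- nrow(score); nc <- ncol(score)
    best <- NULL; bestSum <- -Inf
    if (nc <= 8L) {
        perms <- permuteAll(seq_len(nc))
        for (p in perms) {
            cols <- p[seq_len(nr)]
            s <- sum(score[cbind(seq_len(nr), cols)])
            if (s > bestSum) { bestSum <- s; best <- cols }
        }
        pairs <- cbind(seq_len(nr), best)
    } else {
        usedC <- logical(nc); pairs <- matrix(0L, nr, 2L)
        ord <- order(-apply(score, 1L, max))
        for (i in ord) {
            j <- which.max(ifelse(usedC, -Inf, score[i, ]))
            usedC[j] <- TRUE
            pairs[i, ] <- c(i, j)
        }
    }
    if (swap) pairs <- pairs[, 2:1, drop = FALSE]
    colnames(pairs) <- c("row", "col")
    pairs[order(pairs[, 1L]), , drop = FALSE]
}

permuteAll <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        out <- c(out, lapply(permuteAll(v[-i]), function(p) c(v[i], p)))
    out
}

#' Training parameters for de novo deconvolution
#'
#' Bundles all tunable parameters of the seed-training and
#' rank-scheduling procedure. Defaults are the method's standard
#' protocol values; \code{R = 10000} resampling repetitions is the standard
#' default and is intended for cluster-scale runs -- for synthetic
#' data \code{R >= 100} is ample (see the vignette).
#'
#' @param R number of resampling repetitions per rank.
#' @param nInits random initializations of the short multiplicative
#'   phase per repetition.
#' @param multSteps multiplicative-update steps per initialization.
#' @param resampleFraction fraction of samples drawn (without
#'   replacement) per repetition; 0.8 is the standard "fivefold
#'   resampling".
#' @param topGenesConsensus genes per factor admitted to the
#'   consensus matrix.
#' @param seedHigh,seedLow loading values of the seed matrix for a
#'   gene's own cluster and the remaining columns.
#' @param topGenesFactor genes per factor used for scoring and
#'   linkage.
#' @param tol relative-objective convergence tolerance of the ALS
#'   phase.
#' @param maxIter ALS iteration cap.
#' @param kMin first trial rank.
#' @param kMax hard cap on the trial rank.
#' @param seed master RNG seed; per-rank and per-repetition streams
#'   are derived from it deterministically.
#' @return A named list of validated parameters.
#' @export
#' @examples
#' p <- nmfParams(R = 100, seed = 1)
#' p$resampleFraction
nmfParams <- function(R = 10000L, nInits = 20L, multSteps = 10L,
                      resampleFraction = 0.8, topGenesConsensus = 50L,
                      seedHigh = 1, seedLow = 0.01,
                      topGenesFactor = 250L, tol = 1e-6,
                      maxIter = 500L, kMin = 2L, kMax = 30L,
                      seed = 1L) {
    stopifnot(R >= 1L, nInits >= 1L, multSteps >= 1L,
              resampleFraction > 0, resampleFraction <= 1,
              topGenesConsensus >= 1L, seedLow < seedHigh,
              seedLow > 0, tol > 0, maxIter >= 1L,
              kMin >= 1L, kMax >= kMin)
    list(R = as.integer(R), nInits = as.integer(nInits),
         multSteps = as.integer(multSteps),
         resampleFraction = resampleFraction,
         topGenesConsensus = as.integer(topGenesConsensus),
         seedHigh = seedHigh, seedLow = seedLow,
         topGenesFactor = as.integer(topGenesFactor),
         tol = tol, maxIter = as.integer(maxIter),
         kMin = as.integer(kMin), kMax = as.integer(kMax),
         seed = as.integer(seed))
}
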