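#' Exclusive-weight scores of all features for all factors
#'
#' For factor i the exclusive weight of a feature is its loading in
#' column i minus its largest loading in any other column. This is the
#' ranking statistic for top genes, factor similarity and marker
#' selection. With a single column the loadings themselves are the
#' scores (degenerate case).
#'
#' Factorization and projection leave each weight column with an
#' arbitrary relative scale (the usual NMF scale indeterminacy; a
#' near-degenerate factor with a tiny sample-weight row acquires an
#' enormous gene-weight column), so by default each column is scaled
#' to unit Euclidean length before differencing, making the ranking
#' invariant to per-factor rescaling. Set \code{normalize = FALSE}
#' for raw loading differences.
#'
#' @param W non-negative features x factors matrix.
#' @param normalize scale columns to unit L2 norm before
#'   differencing (default).
#' @return A matrix of the same shape holding the exclusive-weight
#'   scores.
#' @export
exclusiveScores <- function(W, normalize = TRUE) {
    stopifnot(is.matrix(W))
    k <- ncol(W)
    if (normalize && k > 1L) {
        nrm <- sqrt(colSums(W^2))
        nrm[nrm == 0] <- 1
        W <- sweep(W, 2L, nrm, "/")
    }
    if (k == 1L) return(W)
    n <- nrow(W)
    am <- max.col(W, ties.method = "first")
    i1 <- cbind(seq_len(n), am)
    m1 <- W[i1]
    W2 <- W
    W2[i1] <- -Inf
    m2 <- W2[cbind(seq_len(n), max.col(W2, ties.method = "first"))]
    S <- W
    for (j in seq_len(k)) {
        other <- ifelse(am == j, m2, m1)
        S[, j] <- W[, j] - other
    }
    S
}

#' Rank features by exclusive weight for one factor
#'
#' @param W features x factors matrix.
#' @param factorIndex column to rank for.
#' @param normalize see [exclusiveScores()].
#' @return Integer vector of row indices sorted by decreasing
#'   exclusive weight (ties broken by input row order), with the
#'   score vector (input order) as attribute \code{"score"}.
#' @export
rankExclusiveWeight <- function(W, factorIndex, normalize = TRUE) {
    s <- exclusiveScores(W, normalize = normalize)[, factorIndex]
    ord <- order(-s, seq_along(s))
    attr(ord, "score") <- s
    ord
}

#' Top-n features of one factor
#'
#' First \code{n} entries of the exclusive-weight ranking, returned as
#' feature names when \code{W} has row names, indices otherwise.
#'
#' @param W features x factors matrix (typically a projected gene
#'   weight matrix).
#' @param factorIndex column of interest.
#' @param n list length (250 by convention).
#' @return Character (or integer) vector of length \code{min(n, nrow(W))}.
#' @export
topFeatures <- function(W, factorIndex, n = 250L) {
    ord <- rankExclusiveWeight(W, factorIndex)
    ord <- ord[seq_len(min(n, length(ord)))]
    if (!is.null(rownames(W))) rownames(W)[ord] else ord
}

#' Subsample columns of the training matrix
#'
#' Draws \code{ceiling(fraction * ncol(A))} distinct columns without
#' replacement (the standard "fivefold resampling" draws about 80% of
#' the samples). Uses the current RNG state; columns are returned in
#' their original order.
#'
#' @param A matrix to resample.
#' @param fraction fraction of columns to keep, in (0, 1].
#' @param minColumns minimum admissible number of sampled columns
#'   (e.g. the trial rank).
#' @return The column-subsampled matrix.
#' @export
subsampleColumns <- function(A, fraction, minColumns = 1L) {
    stopifnot(is.matrix(A), fraction > 0, fraction <= 1)
    m <- ncol(A)
    n <- ceiling(fraction * m)
    if (n < minColumns)
        stop(sprintf("resampling %d of %d columns is below the required %d",
                     n, m, minColumns))
    A[, sort(sample.int(m, n)), drop = FALSE]
}

#' Multiplicative-update NMF (short phase)
#'
#' Lee-Seung multiplicative updates for the Frobenius objective, run
#' for a fixed small number of steps from a given initialization. The
#' per-step objective trace is returned; it is non-increasing.
#'
#' @param A non-negative matrix.
#' @param W0,H0 non-negative initial factors.
#' @param steps number of full update steps.
#' @return list with \code{W}, \code{H} and \code{objective} (length
#'   \code{steps + 1}, the Frobenius residual before and after each
#'   step).
#' @export
multiplicativeNMF <- function(A, W0, H0, steps = 10L) {
    stopifnot(nrow(W0) == nrow(A), ncol(H0) == ncol(A),
              ncol(W0) == nrow(H0))
    .cpp_mu_nmf(A, W0, H0, as.integer(steps))
}

#' Alternating least squares NMF (refinement phase)
#'
#' Alternating unconstrained least squares with negatives projected
#' to zero, iterated until the relative objective change falls below
#' \code{tol} or \code{maxIter} is reached. The best (W, H) pair seen
#' (including the initial one) is returned, so the result never has a
#' larger residual than its initialization.
#'
#' @inheritParams multiplicativeNMF
#' @param tol relative objective-change convergence tolerance.
#' @param maxIter iteration cap.
#' @return list with \code{W}, \code{H}, \code{objective} and
#'   \code{iterations}.
#' @export
alsNMF <- function(A, W0, H0, tol = 1e-6, maxIter = 500L) {
    stopifnot(nrow(W0) == nrow(A), ncol(H0) == ncol(A),
              ncol(W0) == nrow(H0))
    .cpp_als_nmf(A, W0, H0, tol, as.integer(maxIter))
}

#' Two-phase NMF of one resampled partition
#'
#' Runs \code{nInits} randomly initialized instances of
#' multiplicative-update NMF for \code{multSteps} steps each, selects
#' the pair with the smallest Frobenius residual, and refines it to
#' convergence with the alternating least-squares solver.
#'
#' @param A non-negative matrix (a resampled training partition).
#' @param k trial rank; must be below both dimensions of \code{A}.
#' @param params a [nmfParams()] list.
#' @param returnCandidates if \code{TRUE}, attach the residuals (and
#'   factors) of all multiplicative candidates for inspection.
#' @return list with refined \code{W}, \code{H}, \code{objective},
#'   \code{muObjective} (residual of the selected candidate) and
#'   \code{muTrace} (its per-step objective trace).
#' @export
innerNMF <- function(A, k, params = nmfParams(), returnCandidates = FALSE) {
    stopifnot(is.matrix(A), k >= 1L)
    if (k >= min(dim(A)))
        stop("trial rank must be below both matrix dimensions")
    n <- nrow(A); m <- ncol(A)
    best <- NULL; bestObj <- Inf
    cand <- if (returnCandidates) vector("list", params$nInits)
    candObj <- numeric(params$nInits)
    for (i in seq_len(params$nInits)) {
        W0 <- matrix(runif(n * k), n, k)
        H0 <- matrix(runif(k * m), k, m)
        r <- .cpp_mu_nmf(A, W0, H0, params$multSteps)
        o <- r$objective[length(r$objective)]
        candObj[i] <- o
        if (returnCandidates) cand[[i]] <- r
        if (is.finite(o) && o < bestObj) { bestObj <- o; best <- r }
    }
    if (is.null(best))
        stop("all multiplicative candidates diverged (non-finite residuals)")
    ref <- .cpp_als_nmf(A, best$W, best$H, params$tol, params$maxIter)
    out <- list(W = ref$W, H = ref$H, objective = ref$objective,
                muObjective = bestObj, muTrace = best$objective,
                candidateObjectives = candObj)
    if (returnCandidates) out$candidates <- cand
    out
}

#' Accumulate a top-gene consensus matrix
#'
#' Records, for every repetition and factor, the pairwise
#' co-occurrence of the factor's top genes: for each top-gene set the
#' count of every gene pair in the set is incremented, and each
#' member's diagonal entry is incremented. A gene appearing in the top
#' set of two factors of one repetition has its diagonal incremented
#' twice. Genes enter the consensus index on first appearance.
#'
#' @param C an existing consensus (list with \code{genes} and
#'   \code{counts}) or \code{NULL} to start one.
#' @param topSets list of character vectors (top-gene sets).
#' @return list with \code{genes} (character) and \code{counts}
#'   (symmetric integer matrix over those genes).
#' @export
updateConsensus <- function(C = NULL, topSets = list()) {
    newGenes <- unique(unlist(topSets, use.names = FALSE))
    if (is.null(C)) C <- list(genes = character(),
                              counts = matrix(0L, 0L, 0L))
    add <- setdiff(newGenes, C$genes)
    if (length(add)) {
        genes <- c(C$genes, add)
        counts <- matrix(0L, length(genes), length(genes),
                         dimnames = list(genes, genes))
        if (length(C$genes))
            counts[C$genes, C$genes] <- C$counts
        C <- list(genes = genes, counts = counts)
    }
    for (s in topSets) {
        idx <- match(s, C$genes)
        C$counts[idx, idx] <- C$counts[idx, idx] + 1L
    }
    C
}

#' Build the seed matrix from consensus clusters
#'
#' Converts consensus counts to the dissimilarity
#' \eqn{1 - c_{ij} / \max(c_{ii}, c_{jj})}, clusters genes by
#' average-linkage hierarchical clustering cut at \code{k} clusters,
#' and assembles the seed matrix: each gene loads \code{seedHigh} in
#' its own cluster's column and \code{seedLow} elsewhere.
#'
#' @param C consensus list from [updateConsensus()].
#' @param k number of clusters (the trial rank).
#' @param seedHigh,seedLow the two loading values (standard values 1
#'   and 0.01).
#' @return Seed matrix (consensus genes x k) with gene row names.
#' @export
clusterConsensusToSeed <- function(C, k, seedHigh = 1, seedLow = 0.01) {
    g <- length(C$genes)
    if (g < k)
        stop(sprintf("consensus holds %d genes, fewer than k = %d", g, k))
    if (k == 1L) {
        cl <- rep(1L, g)
    } else {
        dmax <- pmax(matrix(diag(C$counts), g, g),
                     matrix(diag(C$counts), g, g, byrow = TRUE))
        D <- 1 - C$counts / dmax
        diag(D) <- 0
        cl <- cutree(hclust(as.dist(D), method = "average"), k = k)
    }
    W <- matrix(seedLow, g, k, dimnames = list(C$genes, NULL))
    W[cbind(seq_len(g), cl)] <- seedHigh
    W
}

#' Train the gene-weight seed for one trial rank
#'
#' Performs \code{params$R} repetitions of column resampling followed
#' by the two-phase NMF, records each factor's top consensus genes,
#' accumulates the consensus matrix, and clusters it into the seed
#' matrix. Per-repetition RNG streams are derived deterministically
#' from \code{seed}.
#'
#' @param Aprime filtered training matrix (features x samples).
#' @param k trial rank.
#' @param params a [nmfParams()] list.
#' @param seed integer seed for this rank's repetition streams.
#' @return list with \code{seed} (the seed matrix) and
#'   \code{consensus}.
#' @export
trainSeed <- function(Aprime, k, params = nmfParams(), seed = params$seed) {
    stopifnot(is.matrix(Aprime))
    if (ceiling(params$resampleFraction * ncol(Aprime)) < k)
        stop("resampled partitions would hold fewer samples than the rank")
    if (is.null(rownames(Aprime)))
        rownames(Aprime) <- paste0("f", seq_len(nrow(Aprime)))
    repSeeds <- deriveSeeds(seed, params$R)
    nTop <- min(params$topGenesConsensus, nrow(Aprime))
    sets <- vector("list", params$R * k)
    si <- 0L
    for (r in seq_len(params$R)) {
        res <- withSeed(repSeeds[r], {
            Add <- subsampleColumns(Aprime, params$resampleFraction,
                                    minColumns = k)
            innerNMF(Add, k, params)
        })
        S <- exclusiveScores(res$W)
        for (j in seq_len(k)) {
            ord <- order(-S[, j], seq_len(nrow(S)))
            si <- si + 1L
            sets[[si]] <- rownames(Aprime)[ord[seq_len(nTop)]]
        }
    }
    consensus <- updateConsensus(NULL, sets)
    seedM <- clusterConsensusToSeed(consensus, k,
                                    params$seedHigh, params$seedLow)
    list(seed = seedM, consensus = consensus)
}

#' Final seeded NMF at one trial rank
#'
#' Expands the seed matrix to the full filtered feature space
#' (features outside the consensus start at \code{seedLow} in every
#' column, keeping them learnable without biasing any factor),
#' computes the NNLS-optimal H for that initialization, and runs the
#' alternating least-squares NMF to convergence.
#'
#' @param Aprime filtered training matrix.
#' @param Wseed seed matrix from [trainSeed()]; its row names must be
#'   a subset of \code{rownames(Aprime)}.
#' @param params a [nmfParams()] list.
#' @return list with \code{W} (features x k), \code{H} (k x samples)
#'   and \code{objective}; a \code{"zeroColumns"} attribute on
#'   \code{W} flags degenerate all-zero factors (they are retained so
#'   factor indices stay stable).
#' @export
finalSeededNMF <- function(Aprime, Wseed, params = nmfParams()) {
    stopifnot(is.matrix(Aprime), is.matrix(Wseed))
    if (is.null(rownames(Aprime)))
        rownames(Aprime) <- paste0("f", seq_len(nrow(Aprime)))
    if (!all(rownames(Wseed) %in% rownames(Aprime)))
        stop("seed matrix contains features absent from the training matrix")
    k <- ncol(Wseed)
    W0 <- matrix(params$seedLow, nrow(Aprime), k,
                 dimnames = list(rownames(Aprime), NULL))
    W0[rownames(Wseed), ] <- Wseed
    H0 <- .cpp_nnls_cols(W0, Aprime)
    res <- .cpp_als_nmf(Aprime, W0, H0, params$tol, params$maxIter)
    if (anyNA(res$W) || anyNA(res$H) || !is.finite(res$objective))
        stop("final seeded NMF diverged (non-finite result)")
    W <- res$W
    dimnames(W) <- list(rownames(Aprime), NULL)
    H <- res$H
    colnames(H) <- colnames(Aprime)
    zero <- which(colSums(W) == 0)
    if (length(zero)) attr(W, "zeroColumns") <- zero
    list(W = W, H = H, objective = res$objective)
}
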