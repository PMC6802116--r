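#' Estimate compartment weights for new samples
#'
#' Projects new bulk measurements onto saved gene weights: restricts
#' both to their shared feature set and solves one NNLS per sample,
#' so weights can be estimated for even a single sample without
#' re-running de novo deconvolution. Unmatched reference features are
#' dropped, not imputed.
#'
#' @param B new features x samples matrix (a vector is treated as one
#'   sample), data.frame or SummarizedExperiment.
#' @param W reference gene weights: a features x compartments matrix
#'   or a \linkS4class{CompartmentSet} /
#'   \linkS4class{DeconvResult}.
#' @return Non-negative compartments x samples weight matrix with a
#'   \code{"nGenesUsed"} attribute. A warning is raised when fewer
#'   than half of the reference features are matched.
#' @export
#' @examples
#' W <- matrix(c(4, 0, 0, 3), 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' B <- W %*% matrix(c(0.3, 0.7), 2, 1, dimnames = list(NULL, "s1"))
#' rownames(B) <- rownames(W)
#' estimateWeights(B, W)
estimateWeights <- function(B, W) {
    if (methods::is(W, "DeconvResult")) W <- geneWeights(W)
    if (methods::is(W, "CompartmentSet")) W <- geneWeights(W)
    stopifnot(is.matrix(W))
    if (is.null(rownames(W))) stop("reference gene weights need row names")
    if (is.vector(B)) {
        B <- matrix(B, ncol = 1L,
                    dimnames = list(names(B), "sample1"))
    }
    B <- asInputMatrix(B, "query matrix")
    if (is.null(rownames(B))) stop("query matrix needs feature row names")
    shared <- intersect(rownames(W), rownames(B))
    if (!length(shared))
        stop("no shared features between the query and the gene weights")
    if (length(shared) < 0.5 * nrow(W))
        warning(sprintf(
            "only %d of %d reference features matched (< 50%%); weights may be unreliable",
            length(shared), nrow(W)))
    # crude scale check: the query should live on the same scale as
    # the data the weights were trained on (no re-normalization is
    # applied here)
    mB <- median(B[B > 0]); mW <- median(W[W > 0])
    if (is.finite(mB) && is.finite(mW) && mW > 0 &&
        (mB / mW > 10 || mW / mB > 10))
        warning(sprintf(
            "query values (median %.3g) and gene weights (median %.3g) differ by more than 10-fold; check that the query is on the training scale",
            mB, mW))
    H <- .cpp_nnls_cols(W[shared, , drop = FALSE],
                        B[shared, , drop = FALSE])
    dimnames(H) <- list(colnames(W), colnames(B))
    attr(H, "nGenesUsed") <- length(shared)
    H
}

#' Normalize compartment weights to sum one
#'
#' Divides the weights of a declared compartment subset by their sum,
#' per sample, producing a probability vector over that subset (e.g.
#' the seven pancreatic compartments of a typical pancreatic-cancer analysis).
#' Samples whose subset weights are all zero stay zero and are
#' flagged.
#'
#' @param raw non-negative weight vector (one sample) or
#'   compartments x samples matrix.
#' @param subset compartment names or indices to normalize over;
#'   all by default.
#' @return Normalized weights of the subset (same shape as the subset
#'   of \code{raw}), with attribute \code{"zeroSamples"} listing
#'   flagged samples, if any.
#' @export
#' @examples
#' normalizeWeights(c(a = 2, b = 1, c = 1))
normalizeWeights <- function(raw, subset = NULL) {
    vec <- is.null(dim(raw))
    m <- if (vec) matrix(raw, ncol = 1L,
                         dimnames = list(names(raw), NULL)) else raw
    if (any(m < 0)) stop("weights must be non-negative")
    if (is.null(subset)) subset <- seq_len(nrow(m))
    sub <- m[subset, , drop = FALSE]
    if (!nrow(sub)) stop("empty compartment subset")
    s <- colSums(sub)
    zero <- which(s == 0)
    s[zero] <- 1                      # keep zeros, avoid 0/0
    out <- sweep(sub, 2L, s, "/")
    if (length(zero))
        attr(out, "zeroSamples") <- if (!is.null(colnames(m)))
            colnames(m)[zero] else zero
    if (vec) {
        zs <- attr(out, "zeroSamples")
        out <- setNames(drop(out), rownames(sub))
        attr(out, "zeroSamples") <- zs
    }
    out
}

#' Basal/classical metrics and subtype call
#'
#' Computes the basal-to-classical weight ratio (B./C.) and
#' difference per sample and calls the subtype: samples with
#' B./C. >= 1 are Basal-like, samples with B./C. < 1 Classical
#' (boundary inclusive). A zero classical weight with positive basal
#' weight yields an infinite ratio (Basal-like, flagged); a sample
#' with both weights zero gets an NA call and is flagged.
#'
#' @param weights compartments x samples matrix (or named vector for
#'   one sample), e.g. from [estimateWeights()].
#' @param basal,classical row names (or indices) of the basal and
#'   classical tumor compartments.
#' @return data.frame with columns \code{sample}, \code{basal},
#'   \code{classical}, \code{ratio}, \code{difference},
#'   \code{subtype} and \code{flagged}.
#' @export
basalClassicalCall <- function(weights, basal, classical) {
    if (is.null(dim(weights)))
        weights <- matrix(weights, ncol = 1L,
                          dimnames = list(names(weights), "sample1"))
    rows <- rownames(weights)
    idx <- function(x) {
        if (is.character(x)) {
            if (is.null(rows) || !(x %in% rows))
                stop("compartment '", x, "' not present in the weights")
            match(x, rows)
        } else {
            if (x > nrow(weights)) stop("compartment index out of range")
            x
        }
    }
    b <- weights[idx(basal), ]
    cl <- weights[idx(classical), ]
    ratio <- ifelse(cl > 0, b / cl, ifelse(b > 0, Inf, NaN))
    subtype <- ifelse(is.nan(ratio), NA_character_,
                      ifelse(ratio >= 1, "Basal-like", "Classical"))
    data.frame(sample = colnames(weights) %||%
                   paste0("s", seq_along(b)),
               basal = unname(b), classical = unname(cl),
               ratio = unname(ratio), difference = unname(b - cl),
               subtype = unname(subtype),
               flagged = unname(!is.finite(ratio)),
               stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Balanced cross-validation folds
#'
#' Randomly partitions \code{n} samples into \code{k} folds of as
#' equal size as possible; every sample is held out exactly once.
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed RNG seed for the partition.
#' @return Integer vector of fold assignments in \code{1..k}.
#' @export
cvFolds <- function(n, k = 10L, seed = 1L) {
    if (n < k) stop("need at least as many samples as folds")
    withSeed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' Ten-fold cross-validation of compartment weights
#'
#' Partitions the samples into folds; for each fold, runs de novo
#' deconvolution on the remaining samples, projects the held-out
#' samples onto the fold's final gene weights, and matches the
#' fold's compartments to the reference (full-data) compartments by
#' top-250 gene overlap with maximum-sum assignment. Reports, per
#' reference compartment, the Pearson correlation between the
#' cross-validated weight estimates and the reference weights.
#'
#' @param A full non-negative features x samples matrix.
#' @param params [nmfParams()] list used for every de novo run.
#' @param folds number of folds (10 by default; requires
#'   \code{ncol(A) >= folds}).
#' @param reference optional precomputed \linkS4class{DeconvResult}
#'   of the full data (computed if missing).
#' @param minSimilarity minimum top-gene overlap fraction for a
#'   fold-to-reference compartment match (the 0.1 association
#'   threshold of the factor linkage); pairs below it are treated as
#'   "not recovered in this fold" rather than matched.
#' @param ... further arguments passed to [deconvolve()] (e.g.
#'   \code{nKeep}).
#' @return list with \code{correlations} (data.frame: compartment,
#'   r, nSamples), \code{estimates} (compartments x samples matrix of
#'   cross-validated weights, NA where a fold did not recover the
#'   compartment), \code{folds} (the partition) and
#'   \code{reference}.
#' @export
crossValidate <- function(A, params = nmfParams(), folds = 10L,
                          reference = NULL, minSimilarity = 0.1, ...) {
    A <- asInputMatrix(A, "input matrix")
    if (ncol(A) < folds)
        stop("need at least ", folds, " samples for ", folds, "-fold CV")
    if (is.null(colnames(A)))
        colnames(A) <- paste0("s", seq_len(ncol(A)))
    if (is.null(reference))
        reference <- deconvolve(A, params = params, ...)
    refSet <- reference@compartments
    refIds <- refSet@compartments$factor_id
    refTop <- reference@tree@topGenes[refIds]
    fold <- cvFolds(ncol(A), folds, seed = params$seed)
    foldSeeds <- deriveSeeds(params$seed + 1L, folds)
    est <- matrix(NA_real_, length(refIds), ncol(A),
                  dimnames = list(refSet@compartments$name, colnames(A)))
    for (i in seq_len(folds)) {
        held <- which(fold == i)
        pf <- params; pf$seed <- foldSeeds[i]
        resF <- deconvolve(A[, -held, drop = FALSE], params = pf, ...)
        csF <- resF@compartments
        if (!nrow(csF@compartments)) next
        h <- estimateWeights(A[, held, drop = FALSE], geneWeights(csF))
        fIds <- csF@compartments$factor_id
        fTop <- resF@tree@topGenes[fIds]
        ov <- outer(seq_along(fIds), seq_along(refIds),
                    Vectorize(function(a, b)
                        length(intersect(fTop[[a]], refTop[[b]]))))
        pairs <- assignMatch(ov)
        for (p in seq_len(nrow(pairs))) {
            sim <- ov[pairs[p, "row"], pairs[p, "col"]] /
                   length(refTop[[pairs[p, "col"]]])
            if (sim > minSimilarity)
                est[pairs[p, "col"], held] <- h[pairs[p, "row"], ]
        }
    }
    refH <- refSet@sampleWeights
    corr <- vapply(seq_along(refIds), function(j) {
        ok <- !is.na(est[j, ])
        if (sum(ok) < 3L) return(NA_real_)
        suppressWarnings(cor(est[j, ok], refH[j, ok]))
    }, numeric(1))
    list(correlations = data.frame(
             compartment = refSet@compartments$name,
             r = corr,
             nSamples = rowSums(!is.na(est)),
             stringsAsFactors = FALSE),
         estimates = est, folds = fold, reference = reference)
}
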