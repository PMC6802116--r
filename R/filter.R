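#' Pre-filter expression features for training
#'
#' Two-step reduction used to build the training matrix A' from a
#' genes x samples expression matrix A: (1) keep genes whose mean
#' across samples exceeds the third quartile (type-7) of all per-gene
#' means ("highly expressed"); (2) of those, keep the \code{nKeep}
#' genes with the largest per-gene standard deviation ("most
#' variable"). Original row order is preserved among survivors and
#' values are passed through untransformed.
#'
#' @param A non-negative numeric matrix (features x samples), a
#'   data.frame, or a SummarizedExperiment.
#' @param nKeep number of variable features to retain (5000 by
#'   convention). If fewer survive the expression filter, all
#'   survivors are returned with a warning.
#' @param logTransform if \code{TRUE}, means and standard deviations
#'   are computed on \code{log2(x + 1)}; returned values stay on the
#'   original scale.
#' @return The filtered sub-matrix, with a \code{"provenance"}
#'   attribute recording the filter and its parameters.
#' @export
#' @examples
#' A <- matrix(rpois(200, 10), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' Af <- filterExpressionFeatures(A, nKeep = 3)
#' nrow(Af)
filterExpressionFeatures <- function(A, nKeep = 5000L,
                                     logTransform = FALSE) {
    A <- asInputMatrix(A, "expression matrix")
    stopifnot(nKeep >= 1L)
    # a matrix already produced by this filter with the same
    # parameters passes through unchanged (idempotence)
    prov <- attr(A, "provenance")
    if (!is.null(prov) && identical(prov$filter, "expression") &&
        identical(prov$nKeep, as.integer(nKeep)) &&
        identical(prov$logTransform, logTransform))
        return(A)
    X <- if (logTransform) log2(A + 1) else A
    mu <- rowMeans(X)
    q3 <- unname(quantile(mu, 0.75, type = 7L))
    surv <- which(mu > q3)
    if (!length(surv))
        stop("no features pass the expression (mean > Q3) filter")
    s <- apply(X[surv, , drop = FALSE], 1L, sd)
    if (all(s == 0))
        stop("no variable features: all surviving features are constant")
    if (length(surv) <= nKeep) {
        if (length(surv) < nKeep)
            warning(sprintf(
                "only %d features survive the expression filter (< nKeep = %d); keeping all",
                length(surv), nKeep))
        keep <- surv
    } else {
        ord <- order(-s, seq_along(s))   # SD desc, ties by row order
        keep <- sort(surv[ord[seq_len(nKeep)]])
    }
    out <- A[keep, , drop = FALSE]
    attr(out, "provenance") <- list(filter = "expression",
                                    nKeep = as.integer(nKeep),
                                    q3 = q3,
                                    logTransform = logTransform)
    out
}

#' Pre-filter ATAC-seq loci for training
#'
#' Keeps loci with per-locus mean count above the grand mean of all
#' per-locus means AND per-locus standard deviation above the mean of
#' all per-locus standard deviations, then (if more than \code{nKeep}
#' survive) reduces to the \code{nKeep} loci with the largest rank-sum
#' of mean rank and SD rank, so that neither criterion dominates.
#' Original row order is preserved.
#'
#' @param A non-negative locus x sample count matrix (or data.frame /
#'   SummarizedExperiment).
#' @param nKeep number of loci to retain (8000 by
#'   convention).
#' @return The filtered sub-matrix with a \code{"provenance"}
#'   attribute.
#' @export
filterAtacLoci <- function(A, nKeep = 8000L) {
    A <- asInputMatrix(A, "ATAC count matrix")
    stopifnot(nKeep >= 1L)
    prov <- attr(A, "provenance")
    if (!is.null(prov) && identical(prov$filter, "atac") &&
        identical(prov$nKeep, as.integer(nKeep)))
        return(A)
    mu <- rowMeans(A)
    s <- apply(A, 1L, sd)
    surv <- which(mu > mean(mu) & s > mean(s))
    if (!length(surv))
        stop("no loci pass the mean/SD filter (all loci too uniform)")
    if (length(surv) > nKeep) {
        rs <- rank(mu[surv], ties.method = "first") +
              rank(s[surv], ties.method = "first")
        ord <- order(-rs, seq_along(rs))
        surv <- sort(surv[ord[seq_len(nKeep)]])
    }
    out <- A[surv, , drop = FALSE]
    attr(out, "provenance") <- list(filter = "atac",
                                    nKeep = as.integer(nKeep),
                                    grandMean = mean(mu),
                                    meanSD = mean(s))
    out
}
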