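#' Non-negative least squares
#'
#' Solves \eqn{\min_x \|Mx - b\|_2} subject to \eqn{x \ge 0} by the
#' Lawson-Hanson active-set algorithm (global optimum of the convex
#' problem).
#'
#' @param M design matrix (rows = observations, columns = unknowns).
#' @param b response vector of length \code{nrow(M)}.
#' @return Non-negative solution vector of length \code{ncol(M)}.
#' @export
#' @examples
#' nnlsSolve(diag(2), c(3, 7))           # c(3, 7)
#' nnlsSolve(cbind(c(1, 1)), c(0, 2))    # 1
nnlsSolve <- function(M, b) {
    if (!is.matrix(M)) M <- as.matrix(M)
    b <- as.numeric(b)
    if (nrow(M) != length(b))
        stop("dimension mismatch: nrow(M) != length(b)")
    if (ncol(M) < 1L) stop("M must have at least one column")
    if (anyNA(M) || anyNA(b)) stop("NaN/NA in NNLS input")
    drop(.cpp_nnls(M, b))
}

#' Project compartment weights (per-sample NNLS)
#'
#' Given the gene weights W' of the final seeded NMF and the filtered
#' training matrix A', solves one NNLS per sample column; the H' from
#' the NMF is discarded in favor of this projection, which defines the
#' final per-run compartment weights \eqn{\tilde H}.
#'
#' @param Wprime features x factors weight matrix (rows aligned with
#'   \code{Aprime}).
#' @param Aprime filtered features x samples matrix.
#' @return \eqn{\tilde H}, a factors x samples non-negative matrix.
#' @export
projectCompartmentWeights <- function(Wprime, Aprime) {
    stopifnot(is.matrix(Wprime), is.matrix(Aprime))
    if (nrow(Wprime) != nrow(Aprime))
        stop("feature misalignment: W' and A' row counts differ")
    if (!is.null(rownames(Wprime)) && !is.null(rownames(Aprime)) &&
        !identical(rownames(Wprime), rownames(Aprime)))
        stop("feature misalignment: W' and A' row names differ")
    if (anyNA(Wprime) || anyNA(Aprime)) stop("NaN/NA in projection input")
    H <- .cpp_nnls_cols(Wprime, Aprime)
    dimnames(H) <- list(colnames(Wprime), colnames(Aprime))
    H
}

#' Project gene weights (per-gene NNLS on the full matrix)
#'
#' Given the projected compartment weights \eqn{\tilde H} and the FULL
#' input matrix A (all features, not only the filtered ones), solves
#' one NNLS per feature row, so every gene obtains a weight in every
#' factor. These genome-wide weights make later single-sample
#' projection possible.
#'
#' @param Htilde factors x samples matrix (columns aligned with
#'   \code{A}).
#' @param A full features x samples matrix.
#' @return \eqn{\tilde W}, a features x factors non-negative matrix.
#' @export
projectGeneWeights <- function(Htilde, A) {
    stopifnot(is.matrix(Htilde), is.matrix(A))
    if (ncol(Htilde) != ncol(A))
        stop("sample misalignment: H-tilde and A column counts differ")
    if (!is.null(colnames(Htilde)) && !is.null(colnames(A)) &&
        !identical(colnames(Htilde), colnames(A)))
        stop("sample misalignment: H-tilde and A column names differ")
    if (anyNA(Htilde) || anyNA(A)) stop("NaN/NA in projection input")
    W <- t(.cpp_nnls_cols(t(Htilde), t(A)))
    dimnames(W) <- list(rownames(A), rownames(Htilde))
    W
}
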