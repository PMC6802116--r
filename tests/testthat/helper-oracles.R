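# Independent oracles used across tests. These deliberately avoid the
# package's own solver paths.

# Exhaustive active-set NNLS oracle: solve the unconstrained least
# squares on every subset of columns, clip negatives to zero, and keep
# the feasible candidate with the smallest residual.
bruteNNLS <- function(M, b) {
    p <- ncol(M)
    best <- rep(0, p)
    bestRes <- sum(b^2)
    for (mask in seq_len(2^p) - 1L) {
        sel <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
        if (!length(sel)) next
        z <- tryCatch(qr.solve(M[, sel, drop = FALSE], b),
                      error = function(e) NULL)
        if (is.null(z) || any(z < 0)) next
        x <- rep(0, p)
        x[sel] <- z
        res <- sum((M %*% x - b)^2)
        if (res < bestRes) { bestRes <- res; best <- x }
    }
    best
}

# Brute-force exclusive-weight ranking for one factor.
bruteExclusiveRank <- function(W, j, normalize = TRUE) {
    if (normalize && ncol(W) > 1L) {
        for (c in seq_len(ncol(W))) {
            n <- sqrt(sum(W[, c]^2))
            if (n > 0) W[, c] <- W[, c] / n
        }
    }
    s <- vapply(seq_len(nrow(W)), function(g) {
        if (ncol(W) == 1L) W[g, 1L]
        else W[g, j] - max(W[g, -j])
    }, numeric(1))
    order(-s, seq_len(nrow(W)))
}
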