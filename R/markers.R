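#' Select marker genes at the geometric knee
#'
#' Marker genes of a compartment are the top genes whose positive
#' exclusive-weight scores are exponentially greater than the rest:
#' the positive scores are normalized to \code{[0, 1]} (divided by
#' their maximum) and plotted against rank position normalized to
#' \code{[0, 1]}; the knee is the ranked position with the maximum
#' perpendicular distance to the chord joining the first and last
#' points of the decreasing curve, and markers are all genes strictly
#' above it. Two degenerate curves are handled explicitly: when all
#' positive scores tie, every one is a marker (no gene is less
#' exclusive than another); when the curve is numerically straight
#' but sloped the knee is undefined and the minimal prefix -- the
#' single top gene -- is returned.
#'
#' @param W final gene-weight matrix (features x compartments); at
#'   least two columns are required for exclusive-weight scores.
#' @param compartmentIndex column to select markers for.
#' @return data.frame with columns \code{feature}, \code{score}
#'   (exclusive weight) and \code{normScore}; zero rows (with a
#'   warning) if no gene has a positive score.
#' @export
selectMarkers <- function(W, compartmentIndex) {
    stopifnot(is.matrix(W))
    if (ncol(W) < 2L)
        stop("marker selection needs at least two compartments")
    if (is.null(rownames(W)))
        rownames(W) <- paste0("f", seq_len(nrow(W)))
    s <- exclusiveScores(W)[, compartmentIndex]
    pos <- which(s > 0)
    if (!length(pos)) {
        warning("no gene has a positive exclusive weight; empty marker list")
        return(data.frame(feature = character(), score = numeric(),
                          normScore = numeric(), stringsAsFactors = FALSE))
    }
    ord <- pos[order(-s[pos], seq_along(pos))]
    y <- s[ord] / max(s[ord])
    n <- length(ord)
    if (n == 1L) {
        nMark <- 1L
    } else if (diff(range(y)) < 1e-12) {
        nMark <- n     # all positive scores tie: every one is a marker
    } else {
        x <- (seq_len(n) - 1) / (n - 1)
        # perpendicular distance to the chord (x1,y1)-(xn,yn)
        dx <- x[n] - x[1L]; dy <- y[n] - y[1L]
        d <- abs(dy * x - dx * y + dx * y[1L] - dy * x[1L]) /
             sqrt(dx^2 + dy^2)
        if (max(d) < 1e-12) nMark <- 1L      # straight curve: minimal prefix
        else nMark <- max(1L, which.max(d) - 1L)
    }
    idx <- ord[seq_len(nMark)]
    data.frame(feature = rownames(W)[idx], score = s[idx],
               normScore = s[idx] / max(s[ord]),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Ranked-list gene-set enrichment by the Kolmogorov-Smirnov statistic
#'
#' For each gene set, compares the rank positions of set members
#' against non-members with the two-sample Kolmogorov-Smirnov test
#' (asymptotic p-values) and corrects across sets with
#' Benjamini-Hochberg.
#'
#' @param ranking ordered character vector of features (best first),
#'   e.g. a compartment's exclusive-weight ranking.
#' @param geneSets named list of character vectors; sets with no
#'   member in the ranking are skipped with a warning.
#' @param alternative KS alternative, \code{"two.sided"} by default.
#' @param nPermutations if positive, p-values come from permuting
#'   set membership over the ranking (recommended for very small
#'   sets, where the asymptotic approximation is poor); 0 uses the
#'   asymptotic p-value.
#' @return data.frame with columns \code{set}, \code{size},
#'   \code{overlap}, \code{D}, \code{p} and \code{q} (BH-adjusted).
#' @export
ksEnrichment <- function(ranking, geneSets,
                         alternative = c("two.sided", "less", "greater"),
                         nPermutations = 0L) {
    alternative <- match.arg(alternative)
    stopifnot(is.character(ranking), !anyDuplicated(ranking),
              length(geneSets) > 0L)
    if (is.null(names(geneSets)))
        names(geneSets) <- paste0("set", seq_along(geneSets))
    rows <- lapply(names(geneSets), function(nm) {
        pos <- which(ranking %in% geneSets[[nm]])
        if (!length(pos)) {
            warning("gene set '", nm, "' has no member in the ranking; skipped")
            return(NULL)
        }
        if (length(pos) == length(ranking)) {
            warning("gene set '", nm,
                    "' covers the whole ranking; skipped")
            return(NULL)
        }
        neg <- setdiff(seq_along(ranking), pos)
        ks <- suppressWarnings(ks.test(pos, neg,
                                       alternative = alternative,
                                       exact = FALSE))
        p <- ks$p.value
        if (nPermutations > 0L) {
            n <- length(ranking); k <- length(pos)
            Dperm <- replicate(nPermutations, {
                pp <- sample.int(n, k)
                suppressWarnings(ks.test(pp, setdiff(seq_len(n), pp),
                    alternative = alternative,
                    exact = FALSE)$statistic)
            })
            p <- (1 + sum(Dperm >= ks$statistic)) / (nPermutations + 1)
        }
        data.frame(set = nm, size = length(geneSets[[nm]]),
                   overlap = length(pos),
                   D = unname(ks$statistic), p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(set = character(), size = integer(),
                          overlap = integer(), D = numeric(),
                          p = numeric(), q = numeric(),
                          stringsAsFactors = FALSE))
    out$q <- p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}
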