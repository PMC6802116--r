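#' Simulate a convex bulk mixture with ground truth
#'
#' Generates a features x samples matrix A = W H + noise emulating the
#' compartment structure the deconvolution assumes: each compartment
#' owns a disjoint block of marker features with high weight
#' (\code{highWeight}) against a low background (\code{lowWeight}),
#' per-sample mixing proportions are Dirichlet(\code{alpha}) columns
#' scaled by a lognormal library size, and noise is either Gaussian
#' with standard deviation expressed as a fraction of the mean signal
#' (clipped at zero) or Poisson resampling of the signal.
#'
#' @param nFeatures,nSamples matrix dimensions.
#' @param kTrue number of compartments.
#' @param markersPerComp markers per compartment
#'   (\code{kTrue * markersPerComp <= nFeatures}).
#' @param alpha Dirichlet concentration (1 = uniform simplex).
#' @param noiseSd Gaussian noise SD as a fraction of the mean signal
#'   (ignored for Poisson noise).
#' @param noiseModel \code{"gaussian"} or \code{"poisson"}.
#' @param highWeight,lowWeight marker and background loadings of the
#'   true W (10 and 0.1 by default).
#' @param libSizeSd lognormal sigma of the per-sample library-size
#'   factor.
#' @param seed RNG seed; the same seed reproduces the same mixture.
#' @return list with \code{A} (the noisy mixture, with feature and
#'   sample names) and \code{truth} (a
#'   \linkS4class{SyntheticTruth}).
#' @export
#' @examples
#' sim <- simulateMixture(nFeatures = 100, nSamples = 12, kTrue = 3,
#'                        markersPerComp = 10, seed = 7)
#' dim(sim$A)
simulateMixture <- function(nFeatures = 2000L, nSamples = 60L,
                            kTrue = 5L, markersPerComp = 100L,
                            alpha = 1, noiseSd = 0.05,
                            noiseModel = c("gaussian", "poisson"),
                            highWeight = 10, lowWeight = 0.1,
                            libSizeSd = 0.15, seed = 1L) {
    noiseModel <- match.arg(noiseModel)
    if (kTrue * markersPerComp > nFeatures)
        stop("marker blocks do not fit: kTrue * markersPerComp > nFeatures")
    withSeed(seed, {
        features <- sprintf("g%05d", seq_len(nFeatures))
        samples <- sprintf("s%03d", seq_len(nSamples))
        comps <- paste0("comp", seq_len(kTrue))
        W <- matrix(lowWeight, nFeatures, kTrue,
                    dimnames = list(features, comps))
        blocks <- lapply(seq_len(kTrue), function(i)
            features[((i - 1L) * markersPerComp + 1L):(i * markersPerComp)])
        names(blocks) <- comps
        for (i in seq_len(kTrue)) W[blocks[[i]], i] <- highWeight
        G <- matrix(rgamma(kTrue * nSamples, shape = alpha, rate = 1),
                    kTrue, nSamples)
        H <- sweep(G, 2L, colSums(G), "/")
        lib <- exp(rnorm(nSamples, 0, libSizeSd))
        H <- sweep(H, 2L, lib, "*")
        dimnames(H) <- list(comps, samples)
        A0 <- W %*% H
        A <- switch(noiseModel,
            gaussian = pmax(A0 + matrix(
                rnorm(length(A0), 0, noiseSd * mean(A0)),
                nrow(A0), ncol(A0)), 0),
            poisson = matrix(rpois(length(A0), lambda = A0),
                             nrow(A0), ncol(A0)))
        dimnames(A) <- dimnames(A0)
        truth <- methods::new("SyntheticTruth", geneWeights = W,
                              sampleWeights = H, markerBlocks = blocks,
                              noise = list(model = noiseModel,
                                           sdFraction = noiseSd),
                              seed = as.integer(seed))
        list(A = A, truth = truth)
    })
}

#' Evaluate parameter recovery against synthetic truth
#'
#' Matches recovered compartments to the ground truth by maximum-sum
#' assignment on Pearson correlations of the sample-weight rows, and
#' reports per-compartment correlation together with marker-gene
#' precision and recall against the true marker blocks.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param result a \linkS4class{CompartmentSet} or
#'   \linkS4class{DeconvResult}.
#' @param labels compartment labels entering the evaluation
#'   (\code{"major"} by default).
#' @return list with \code{nMajor} (majors in the result),
#'   \code{matchedR} (named by truth compartment; NA if unmatched),
#'   \code{markerPrecision}, \code{markerRecall} (same naming) and
#'   \code{assignment} (recovered index, truth index pairs).
#' @export
evaluateRecovery <- function(truth, result, labels = "major") {
    cs <- if (methods::is(result, "DeconvResult"))
        result@compartments else result
    stopifnot(methods::is(cs, "CompartmentSet"),
              methods::is(truth, "SyntheticTruth"))
    cc <- cs@compartments
    nMajor <- sum(cc$label == "major")
    keep <- which(cc$label %in% labels)
    Ht <- truth@sampleWeights
    kT <- nrow(Ht)
    matchedR <- setNames(rep(NA_real_, kT), rownames(Ht))
    prec <- rec <- matchedR
    if (!length(keep))
        return(list(nMajor = nMajor, matchedR = matchedR,
                    markerPrecision = prec, markerRecall = rec,
                    assignment = NULL))
    Hr <- cs@sampleWeights[keep, , drop = FALSE]
    common <- intersect(colnames(Hr) %||% colnames(Ht), colnames(Ht))
    if (is.null(colnames(Hr)) || !length(common)) {
        stopifnot(ncol(Hr) == ncol(Ht))
        ci <- seq_len(ncol(Ht)); cj <- ci
    } else {
        ci <- match(common, colnames(Hr)); cj <- match(common, colnames(Ht))
    }
    R <- matrix(0, nrow(Hr), kT)
    for (a in seq_len(nrow(Hr))) for (b in seq_len(kT)) {
        r <- suppressWarnings(cor(Hr[a, ci], Ht[b, cj]))
        R[a, b] <- if (is.na(r)) 0 else r
    }
    pairs <- assignMatch(R)
    Wr <- cs@geneWeights[, keep, drop = FALSE]
    canMark <- ncol(Wr) >= 2L
    for (p in seq_len(nrow(pairs))) {
        a <- pairs[p, "row"]; b <- pairs[p, "col"]
        matchedR[b] <- R[a, b]
        if (canMark) {
            mk <- suppressWarnings(selectMarkers(Wr, a)$feature)
            blk <- truth@markerBlocks[[b]]
            if (length(mk)) {
                prec[b] <- length(intersect(mk, blk)) / length(mk)
                rec[b] <- length(intersect(mk, blk)) / length(blk)
            }
        }
    }
    list(nMajor = nMajor, matchedR = matchedR,
         markerPrecision = prec, markerRecall = rec,
         assignment = pairs)
}
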