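#' Accessors for deconvolution objects
#'
#' \code{geneWeights} returns the features-by-compartments (or
#' features-by-factors) weight matrix; \code{sampleWeights} the
#' compartments-by-samples matrix; \code{compartments} the compartment
#' table; \code{factorTree} the tree of linked factors;
#' \code{factorScores} the per-factor similarity scores;
#' \code{markerGenes} the per-compartment marker lists.
#'
#' @param x an object of class \linkS4class{NMFRun},
#'   \linkS4class{FactorTree}, \linkS4class{CompartmentSet},
#'   \linkS4class{SyntheticTruth} or \linkS4class{DeconvResult}.
#' @return The requested component (a matrix, data.frame, list or S4
#'   object, depending on the accessor).
#' @name accessors
#' @aliases geneWeights sampleWeights compartments factorTree
#'   factorScores markerGenes
#' @examples
#' sim <- simulateMixture(nFeatures = 60, nSamples = 8, kTrue = 2,
#'                        markersPerComp = 10, seed = 1)
#' dim(geneWeights(sim$truth))
NULL

#' @rdname accessors
#' @export
setGeneric("geneWeights", function(x) standardGeneric("geneWeights"))

#' @rdname accessors
#' @export
setGeneric("sampleWeights", function(x) standardGeneric("sampleWeights"))

#' @rdname accessors
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' @rdname accessors
#' @export
setGeneric("factorTree", function(x) standardGeneric("factorTree"))

#' @rdname accessors
#' @export
setGeneric("factorScores", function(x) standardGeneric("factorScores"))

#' @rdname accessors
#' @export
setGeneric("markerGenes", function(x) standardGeneric("markerGenes"))

#' @rdname accessors
#' @export
setMethod("geneWeights", "NMFRun", function(x) x@geneWeights)

#' @rdname accessors
#' @export
setMethod("sampleWeights", "NMFRun", function(x) x@sampleWeights)

#' @rdname accessors
#' @export
setMethod("geneWeights", "CompartmentSet", function(x) x@geneWeights)

#' @rdname accessors
#' @export
setMethod("sampleWeights", "CompartmentSet", function(x) x@sampleWeights)

#' @rdname accessors
#' @export
setMethod("compartments", "CompartmentSet", function(x) x@compartments)

#' @rdname accessors
#' @export
setMethod("markerGenes", "CompartmentSet", function(x) x@markers)

#' @rdname accessors
#' @export
setMethod("geneWeights", "SyntheticTruth", function(x) x@geneWeights)

#' @rdname accessors
#' @export
setMethod("sampleWeights", "SyntheticTruth", function(x) x@sampleWeights)

#' @rdname accessors
#' @export
setMethod("factorScores", "FactorTree", function(x) {
    s <- x@factors$score
    names(s) <- x@factors$factor_id
    s
})

#' @rdname accessors
#' @export
setMethod("geneWeights", "DeconvResult",
          function(x) x@compartments@geneWeights)

#' @rdname accessors
#' @export
setMethod("sampleWeights", "DeconvResult",
          function(x) x@compartments@sampleWeights)

#' @rdname accessors
#' @export
setMethod("compartments", "DeconvResult",
          function(x) x@compartments@compartments)

#' @rdname accessors
#' @export
setMethod("factorTree", "DeconvResult", function(x) x@tree)

#' @rdname accessors
#' @export
setMethod("factorScores", "DeconvResult",
          function(x) factorScores(x@tree))

#' @rdname accessors
#' @export
setMethod("markerGenes", "DeconvResult",
          function(x) x@compartments@markers)
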