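#' @import methods
NULL

#' Per-rank factorization result
#'
#' Holds the definitive output of one de novo run at a trial rank
#' \eqn{\tilde K}: the NNLS-projected gene weights \eqn{\tilde W}
#' (all N input features by \eqn{\tilde K} factors) and compartment
#' weights \eqn{\tilde H} (\eqn{\tilde K} factors by M samples),
#' together with stable factor identifiers of the form
#' \code{"<K>.<j>"}.
#'
#' @slot kTilde integer(1), the trial rank of this run.
#' @slot factorIds character vector of unique factor identifiers.
#' @slot geneWeights non-negative matrix, features x factors
#'   (\eqn{\tilde W}).
#' @slot sampleWeights non-negative matrix, factors x samples
#'   (\eqn{\tilde H}).
#' @slot objective numeric(1), Frobenius residual of the seeded NMF on
#'   the filtered training matrix.
#'
#' @exportClass NMFRun
setClass("NMFRun",
    representation(
        kTilde = "integer",
        factorIds = "character",
        geneWeights = "matrix",
        sampleWeights = "matrix",
        objective = "numeric"
    )
)

setValidity("NMFRun", function(object) {
    msg <- character()
    k <- object@kTilde
    if (length(k) != 1L || k < 1L)
        msg <- c(msg, "kTilde must be a single positive integer")
    if (anyDuplicated(object@factorIds))
        msg <- c(msg, "factorIds must be unique")
    if (length(object@factorIds) != k)
        msg <- c(msg, "length(factorIds) must equal kTilde")
    if (ncol(object@geneWeights) != k)
        msg <- c(msg, "geneWeights must have kTilde columns")
    if (nrow(object@sampleWeights) != k)
        msg <- c(msg, "sampleWeights must have kTilde rows")
    if (any(object@geneWeights < 0) || any(object@sampleWeights < 0))
        msg <- c(msg, "weights must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Factor tree across runs of increasing rank
#'
#' Collects the factors of all executed runs, their similarity scores
#' to the best-matching factor at rank \eqn{\tilde K - 1}, and the
#' parent-child linkages that form the factor forest used for
#' compartment identification.
#'
#' @slot runs named list of \linkS4class{NMFRun}, names are the ranks.
#' @slot factors data.frame with columns \code{factor_id}, \code{k},
#'   \code{index}, \code{score}, \code{parent_id},
#'   \code{newly_emerged}.
#' @slot topGenes named list (by factor_id) of the top-250
#'   exclusive-weight gene lists.
#' @slot consideredK integer vector of ranks admitted to compartment
#'   identification.
#' @slot medianScores named numeric, median factor score per executed
#'   rank.
#' @slot params list, the training parameters used.
#'
#' @exportClass FactorTree
setClass("FactorTree",
    representation(
        runs = "list",
        factors = "data.frame",
        topGenes = "list",
        consideredK = "integer",
        medianScores = "numeric",
        params = "list"
    ),
    prototype(
        runs = list(),
        factors = data.frame(),
        topGenes = list(),
        consideredK = integer(),
        medianScores = numeric(),
        params = list()
    )
)

setValidity("FactorTree", function(object) {
    msg <- character()
    f <- object@factors
    need <- c("factor_id", "k", "score", "parent_id", "newly_emerged")
    if (nrow(f)) {
        if (!all(need %in% names(f)))
            msg <- c(msg, paste("factors needs columns:",
                                paste(need, collapse = ", ")))
        else {
            if (anyDuplicated(f$factor_id))
                msg <- c(msg, "factor ids must be unique")
            linked <- !is.na(f$parent_id)
            if (any(linked)) {
                pk <- f$k[match(f$parent_id[linked], f$factor_id)]
                if (any(!is.na(pk) & pk != f$k[linked] - 1L))
                    msg <- c(msg, "links must join adjacent ranks")
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' Final compartment set
#'
#' The compartments selected from the factor tree, each carrying its
#' gene-weight column and sample-weight row extracted verbatim from
#' the run of origin, plus major/minor/unstable labels.
#'
#' @slot compartments data.frame with columns \code{factor_id},
#'   \code{label}, \code{k}, \code{score}, \code{name},
#'   \code{annotation}.
#' @slot geneWeights non-negative matrix, features x compartments
#'   (final W).
#' @slot sampleWeights non-negative matrix, compartments x samples
#'   (final H).
#' @slot markers named list of marker data.frames (one per
#'   compartment), possibly empty.
#'
#' @exportClass CompartmentSet
setClass("CompartmentSet",
    representation(
        compartments = "data.frame",
        geneWeights = "matrix",
        sampleWeights = "matrix",
        markers = "list"
    ),
    prototype(markers = list())
)

setValidity("CompartmentSet", function(object) {
    msg <- character()
    K <- nrow(object@compartments)
    if (ncol(object@geneWeights) != K)
        msg <- c(msg, "geneWeights must have one column per compartment")
    if (nrow(object@sampleWeights) != K)
        msg <- c(msg, "sampleWeights must have one row per compartment")
    if (K && any(object@geneWeights < 0, object@sampleWeights < 0))
        msg <- c(msg, "weights must be non-negative")
    if (K && !all(object@compartments$label %in%
                  c("major", "minor", "unstable")))
        msg <- c(msg, "labels must be major, minor or unstable")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic mixture
#'
#' @slot geneWeights true W (features x compartments) with disjoint
#'   marker blocks.
#' @slot sampleWeights true H (compartments x samples), Dirichlet
#'   columns scaled by library size.
#' @slot markerBlocks named list of true marker-gene sets per
#'   compartment.
#' @slot noise list recording the noise model and its magnitude.
#' @slot seed integer(1), the generator seed.
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    representation(
        geneWeights = "matrix",
        sampleWeights = "matrix",
        markerBlocks = "list",
        noise = "list",
        seed = "integer"
    )
)

#' Full de novo deconvolution result
#'
#' @slot tree the \linkS4class{FactorTree} over all executed ranks.
#' @slot compartments the selected \linkS4class{CompartmentSet}.
#' @slot filteredFeatures character, features retained by the
#'   pre-filter (rows of the training matrix A').
#' @slot datatype "expression" or "atac".
#' @slot params list of resolved training parameters.
#'
#' @exportClass DeconvResult
setClass("DeconvResult",
    representation(
        tree = "FactorTree",
        compartments = "CompartmentSet",
        filteredFeatures = "character",
        datatype = "character",
        params = "list"
    )
)

setMethod("show", "NMFRun", function(object) {
    cat(sprintf("NMFRun (K~ = %d): %d features x %d samples\n",
                object@kTilde, nrow(object@geneWeights),
                ncol(object@sampleWeights)))
    cat("  factors:", paste(object@factorIds, collapse = ", "), "\n")
    cat(sprintf("  seeded-NMF residual: %.4g\n", object@objective))
})

setMethod("show", "FactorTree", function(object) {
    ks <- sort(as.integer(names(object@runs)))
    cat(sprintf("FactorTree: %d runs (K~ = %s), %d factors\n",
                length(ks), if (length(ks))
                    paste(range(ks), collapse = "..") else "-",
                nrow(object@factors)))
    if (length(object@consideredK))
        cat("  considered K~:",
            paste(range(object@consideredK), collapse = ".."), "\n")
    if (length(object@medianScores)) {
        cat("  median scores:\n")
        print(round(object@medianScores, 3))
    }
})

setMethod("show", "CompartmentSet", function(object) {
    cc <- object@compartments
    cat(sprintf("CompartmentSet: %d compartment(s)\n", nrow(cc)))
    if (nrow(cc))
        print(cc[, c("name", "label", "k", "score")], row.names = FALSE)
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(
        "SyntheticTruth: %d features, %d samples, %d compartments (%s noise)\n",
        nrow(object@geneWeights), ncol(object@sampleWeights),
        ncol(object@geneWeights), object@noise$model))
})

setMethod("show", "DeconvResult", function(object) {
    cat(sprintf("DeconvResult (%s data)\n", object@datatype))
    show(object@tree)
    show(object@compartments)
})
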