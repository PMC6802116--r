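#' Run one de novo deconvolution rank
#'
#' Executes the full per-rank stage: seed training on the filtered
#' matrix, final seeded NMF, NNLS projection of compartment weights
#' against A' and of gene weights against the full A. Factor ids are
#' \code{"<k>.<j>"}.
#'
#' @param A full non-negative features x samples matrix.
#' @param Aprime filtered training matrix (rows a subset of
#'   \code{A}'s).
#' @param k trial rank.
#' @param params [nmfParams()] list.
#' @param seed integer seed for this rank.
#' @return An \linkS4class{NMFRun}.
#' @export
runRank <- function(A, Aprime, k, params = nmfParams(),
                    seed = params$seed) {
    ts <- trainSeed(Aprime, k, params, seed = seed)
    fit <- finalSeededNMF(Aprime, ts$seed, params)
    Htilde <- projectCompartmentWeights(fit$W, Aprime)
    Wtilde <- projectGeneWeights(Htilde, A)
    ids <- paste0(k, ".", seq_len(k))
    rownames(Htilde) <- ids
    colnames(Wtilde) <- ids
    methods::new("NMFRun", kTilde = as.integer(k), factorIds = ids,
                 geneWeights = Wtilde, sampleWeights = Htilde,
                 objective = fit$objective)
}

#' De novo compartment deconvolution
#'
#' The full pipeline: pre-filter the input (expression or ATAC rules),
#' then for each scheduled trial rank train the consensus seed, run
#' the final seeded NMF and re-project weights by NNLS; link factors
#' across adjacent ranks into the factor tree; stop the rank schedule
#' by the median-score rules; select compartments from high-score
#' branch blocks, relabel duplicated majors as minor, assemble the
#' final W and H, and select marker genes.
#'
#' The factors of the first executed rank (2) have no previous rank
#' to score against, so a rank-1 pseudo-run is computed solely to
#' provide their scores; it is never considered for selection.
#'
#' @param A non-negative features x samples matrix, data.frame or
#'   SummarizedExperiment.
#' @param params [nmfParams()] list (rank range, repetitions, seeds).
#' @param datatype \code{"expression"} (mean > Q3 then top-variable
#'   filter, 5000 features) or \code{"atac"} (mean/SD filter, 8000
#'   loci).
#' @param nKeep override of the filter's feature count.
#' @param includeUnstable include unstable compartments in the final
#'   weight matrices.
#' @param computeMarkers select marker genes per compartment (needs
#'   at least two compartments).
#' @param checkpointDir directory for per-rank checkpoints; a killed
#'   run restarted with the same directory, data and parameters
#'   resumes at the first incomplete rank and yields identical
#'   output.
#' @param verbose print per-rank progress.
#' @return A \linkS4class{DeconvResult}.
#' @export
deconvolve <- function(A, params = nmfParams(),
                       datatype = c("expression", "atac"),
                       nKeep = NULL, includeUnstable = FALSE,
                       computeMarkers = TRUE, checkpointDir = NULL,
                       verbose = FALSE) {
    datatype <- match.arg(datatype)
    A <- asInputMatrix(A, "input matrix")
    if (ncol(A) < 2L) stop("de novo deconvolution needs at least 2 samples")
    if (is.null(rownames(A))) rownames(A) <- paste0("g", seq_len(nrow(A)))
    if (is.null(colnames(A))) colnames(A) <- paste0("s", seq_len(ncol(A)))
    if (is.null(nKeep))
        nKeep <- if (datatype == "atac") 8000L else 5000L
    Aprime <- if (datatype == "atac") filterAtacLoci(A, nKeep)
              else filterExpressionFeatures(A, nKeep)
    kSeeds <- deriveSeeds(params$seed, params$kMax)
    ckpt <- if (!is.null(checkpointDir))
        openCheckpoint(checkpointDir, params, datatype, nKeep,
                       dim(A)) else NULL
    tree <- newFactorTree(params = params)
    doRank <- function(k) {
        run <- NULL
        if (!is.null(ckpt)) run <- loadRankCheckpoint(ckpt, k)
        if (is.null(run)) {
            run <- tryCatch(
                runRank(A, Aprime, k, params, seed = kSeeds[k]),
                error = function(e) stop(
                    "stage 'runRank' failed at rank ", k, ": ",
                    conditionMessage(e), call. = FALSE))
            if (!is.null(ckpt)) saveRankCheckpoint(ckpt, run)
        }
        run
    }
    tree <- addRun(tree, doRank(1L), nTop = params$topGenesFactor)
    step <- function(k) {
        tree <<- addRun(tree, doRank(k), nTop = params$topGenesFactor)
        tree <<- linkRuns(tree, k)
        m <- median(tree@factors$score[tree@factors$k == k])
        tree@medianScores[as.character(k)] <<- m
        if (verbose)
            message(sprintf("rank %d: median factor score %.3f", k, m))
        m
    }
    sched <- scheduleK(step, kMin = max(2L, params$kMin),
                       kMax = params$kMax)
    if (is.na(sched$consideredStart))
        stop("no run ever reached a median factor score > 0.5; ",
             "the data may lack reproducible structure ",
             "(executed ranks: ",
             paste(sched$executed, collapse = ", "), ")")
    tree@consideredK <- sched$consideredK
    sel <- identifyCompartments(tree)
    sel <- labelMinor(sel, tree)
    wanted <- c("major", "minor", if (includeUnstable) "unstable")
    if (nrow(sel) && !any(sel$label %in% wanted))
        warning("only unstable compartments were identified; ",
                "final weight matrices are empty ",
                "(set includeUnstable = TRUE to keep them)")
    if (nrow(sel) && any(sel$label %in% wanted)) {
        cs <- assembleCompartments(sel, tree,
                                   includeUnstable = includeUnstable)
        if (computeMarkers && ncol(cs@geneWeights) >= 2L) {
            mk <- lapply(seq_len(ncol(cs@geneWeights)), function(j)
                suppressWarnings(selectMarkers(cs@geneWeights, j)))
            names(mk) <- cs@compartments$name
            cs@markers <- mk
        }
    } else {
        cs <- methods::new("CompartmentSet",
                           compartments = data.frame(
                               factor_id = character(),
                               label = character(), k = integer(),
                               score = numeric(), name = character(),
                               annotation = character(),
                               stringsAsFactors = FALSE),
                           geneWeights = matrix(0, nrow(A), 0L,
                               dimnames = list(rownames(A), NULL)),
                           sampleWeights = matrix(0, 0L, ncol(A),
                               dimnames = list(NULL, colnames(A))),
                           markers = list())
    }
    methods::new("DeconvResult", tree = tree, compartments = cs,
                 filteredFeatures = rownames(Aprime),
                 datatype = datatype, params = params)
}

# --- checkpointing -------------------------------------------------

openCheckpoint <- function(dir, params, datatype, nKeep, dims) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifestPath <- file.path(dir, "manifest.json")
    key <- list(params = params, datatype = datatype,
                nKeep = as.integer(nKeep), nFeatures = dims[1L],
                nSamples = dims[2L])
    if (file.exists(manifestPath)) {
        old <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
        oldKey <- old$key
        newKey <- jsonlite::fromJSON(jsonlite::toJSON(key, auto_unbox = TRUE,
                                                      digits = NA))
        if (!isTRUE(all.equal(oldKey, newKey)))
            stop("checkpoint directory was written with different ",
                 "data or parameters; refusing to resume")
    } else {
        jsonlite::write_json(list(key = key), manifestPath,
                             auto_unbox = TRUE, digits = NA)
    }
    list(dir = dir)
}

rankFiles <- function(ckpt, k) {
    list(W = file.path(ckpt$dir, sprintf("run_K%d_W.tsv", k)),
         H = file.path(ckpt$dir, sprintf("run_K%d_H.tsv", k)),
         meta = file.path(ckpt$dir, sprintf("run_K%d_meta.json", k)))
}

saveRankCheckpoint <- function(ckpt, run) {
    f <- rankFiles(ckpt, run@kTilde)
    writeMatrix(run@geneWeights, f$W)            # %.17g: exact round-trip
    writeMatrix(run@sampleWeights, f$H)
    jsonlite::write_json(list(kTilde = run@kTilde,
                              factorIds = run@factorIds,
                              objective = run@objective),
                         f$meta, auto_unbox = TRUE, digits = NA)
    invisible(NULL)
}

loadRankCheckpoint <- function(ckpt, k) {
    f <- rankFiles(ckpt, k)
    if (!all(file.exists(f$W, f$H, f$meta))) return(NULL)
    meta <- jsonlite::read_json(f$meta, simplifyVector = TRUE)
    W <- readMatrix(f$W, format = "tsv")
    H <- readMatrix(f$H, format = "tsv")
    rownames(H) <- meta$factorIds
    colnames(W) <- meta$factorIds
    methods::new("NMFRun", kTilde = as.integer(meta$kTilde),
                 factorIds = as.character(meta$factorIds),
                 geneWeights = W, sampleWeights = H,
                 objective = as.numeric(meta$objective))
}

#' Write deconvolution outputs
#'
#' Writes \code{compartments.tsv} (factor id, label, rank of origin,
#' score, name), \code{W.tsv} and \code{H.tsv} with compartment
#' names as headers, \code{markers.gmt} (one set per compartment,
#' when markers were computed), \code{tree.json} (factors, scores,
#' links) and \code{tree.dot}.
#'
#' @param result a \linkS4class{DeconvResult}.
#' @param dir output directory (created if missing).
#' @return Invisibly, \code{dir}.
#' @export
writeDeconvolution <- function(result, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    cs <- result@compartments
    write.table(cs@compartments,
                file.path(dir, "compartments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (ncol(cs@geneWeights)) {
        writeMatrix(cs@geneWeights, file.path(dir, "W.tsv"))
        writeMatrix(cs@sampleWeights, file.path(dir, "H.tsv"))
    }
    if (length(cs@markers)) {
        writeGmt(lapply(cs@markers, `[[`, "feature"),
                 file.path(dir, "markers.gmt"))
        mk <- do.call(rbind, lapply(names(cs@markers), function(nm) {
            d <- cs@markers[[nm]]
            if (!nrow(d)) return(NULL)
            cbind(compartment = nm, d)
        }))
        write.table(mk, file.path(dir, "markers.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    tr <- result@tree
    jsonlite::write_json(
        list(factors = tr@factors,
             consideredK = tr@consideredK,
             medianScores = as.list(tr@medianScores)),
        file.path(dir, "tree.json"), auto_unbox = TRUE, digits = NA,
        dataframe = "rows", na = "null")
    exportTreeDot(tr, file.path(dir, "tree.dot"))
    invisible(dir)
}
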