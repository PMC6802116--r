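#' Construct a factor tree
#'
#' Usually built incrementally by [addRun()] and [linkRuns()] inside
#' [deconvolve()], but may also be assembled directly (e.g. for
#' fixtures or imported results) from a factor table and top-gene
#' lists.
#'
#' @param factors data.frame with columns \code{factor_id}, \code{k},
#'   \code{index}, \code{score}, \code{parent_id},
#'   \code{newly_emerged}.
#' @param topGenes named list (by factor_id) of top-gene character
#'   vectors.
#' @param runs named list of \linkS4class{NMFRun} objects (names =
#'   ranks); may be empty when only selection logic is needed.
#' @param consideredK integer vector of ranks admitted to compartment
#'   identification.
#' @param medianScores named numeric of median scores per rank.
#' @param params list of training parameters.
#' @return A \linkS4class{FactorTree}.
#' @export
newFactorTree <- function(factors = emptyFactorTable(),
                          topGenes = list(), runs = list(),
                          consideredK = integer(),
                          medianScores = numeric(), params = list()) {
    methods::new("FactorTree", runs = runs, factors = factors,
                 topGenes = topGenes,
                 consideredK = as.integer(consideredK),
                 medianScores = medianScores, params = params)
}

emptyFactorTable <- function() {
    data.frame(factor_id = character(), k = integer(),
               index = integer(), score = numeric(),
               parent_id = character(), newly_emerged = logical(),
               stringsAsFactors = FALSE)
}

#' Add a per-rank run to a factor tree
#'
#' Registers the run, creates unscored factor entries (one per
#' column) and stores each factor's top-gene list computed from the
#' projected gene weights.
#'
#' @param tree a \linkS4class{FactorTree}.
#' @param run an \linkS4class{NMFRun}.
#' @param nTop length of the stored top-gene lists (250 by default).
#' @return The updated tree.
#' @export
addRun <- function(tree, run, nTop = 250L) {
    stopifnot(methods::is(tree, "FactorTree"), methods::is(run, "NMFRun"))
    k <- run@kTilde
    if (as.character(k) %in% names(tree@runs))
        stop("run at rank ", k, " already present")
    tree@runs[[as.character(k)]] <- run
    add <- data.frame(factor_id = run@factorIds, k = k,
                      index = seq_len(k), score = NA_real_,
                      parent_id = NA_character_,
                      newly_emerged = NA, stringsAsFactors = FALSE)
    tree@factors <- rbind(tree@factors, add)
    for (j in seq_len(k))
        tree@topGenes[[run@factorIds[j]]] <-
            topFeatures(run@geneWeights, j, nTop)
    tree
}

#' Similarity of two factors
#'
#' Fraction of shared genes between two equally long top-gene lists
#' (overlap count divided by the list length, i.e. the overlapping
#' percentage of the top 250 genes converted to a decimal).
#'
#' @param a,b character vectors (top-gene lists) of equal length.
#' @return A value in \code{[0, 1]}.
#' @export
factorSimilarity <- function(a, b) {
    stopifnot(length(a) == length(b), length(a) > 0L)
    length(intersect(a, b)) / length(a)
}

#' Score and link the factors of one rank against the previous rank
#'
#' Each factor at rank \code{k} is compared against all factors at
#' \code{k - 1}. If the best-matching parent's similarity exceeds
#' \code{linkThreshold} (0.1), a link is established and the
#' similarity becomes the factor's score; otherwise the factor is
#' marked newly emerged, with its maximum similarity retained as its
#' score so that runs dominated by unstable factors still lower the
#' rank schedule's median. Ties in the best parent go to the lower
#' parent index, deterministically. A parent left without children
#' simply terminates its branch.
#'
#' @param tree a \linkS4class{FactorTree} with runs at \code{k} and
#'   \code{k - 1}.
#' @param k the rank to link.
#' @param linkThreshold minimum similarity for a link.
#' @return The updated tree.
#' @export
linkRuns <- function(tree, k, linkThreshold = 0.1) {
    idCur <- tree@factors$factor_id[tree@factors$k == k]
    idPrev <- tree@factors$factor_id[tree@factors$k == k - 1L]
    if (!length(idCur) || !length(idPrev))
        stop("runs at ranks ", k, " and ", k - 1L, " must both be present")
    for (fid in idCur) {
        sims <- vapply(idPrev, function(p)
            factorSimilarity(tree@topGenes[[fid]], tree@topGenes[[p]]),
            numeric(1))
        best <- which.max(sims)    # first max: lower index wins ties
        row <- which(tree@factors$factor_id == fid)
        tree@factors$score[row] <- sims[best]
        if (sims[best] > linkThreshold) {
            tree@factors$parent_id[row] <- idPrev[best]
            tree@factors$newly_emerged[row] <- FALSE
        } else {
            tree@factors$parent_id[row] <- NA_character_
            tree@factors$newly_emerged[row] <- TRUE
        }
    }
    tree
}

#' Rank schedule controller
#'
#' Drives the trial rank \eqn{\tilde K} upward from \code{kMin}
#' (default 2), calling \code{step(k)} (which must execute the run and
#' return that rank's median factor score). A run becomes
#' "considered" once its median score exceeds
#' \code{startThreshold}; iteration ends after \code{stopAfter}
#' consecutive runs with median score below \code{startThreshold}
#' ("below 0.5 for more than three consecutive runs" = 4 runs), or at
#' the hard cap \code{kMax} (with a warning).
#'
#' @param step function of one argument (the rank) returning that
#'   run's median factor score.
#' @param kMin,kMax first and maximal trial rank.
#' @param startThreshold the 0.5 median-score threshold.
#' @param stopAfter number of consecutive sub-threshold runs that
#'   stops the schedule.
#' @return list with \code{executed} (ranks run), \code{medians}
#'   (named numeric), \code{consideredStart} (first considered rank,
#'   or \code{NA} if none), \code{consideredK} (integer vector) and
#'   \code{stopped} ("lowscore" or "cap").
#' @export
#' @examples
#' med <- c(`2` = 0.8, `3` = 0.7, `4` = 0.4, `5` = 0.4, `6` = 0.4, `7` = 0.4)
#' scheduleK(function(k) med[[as.character(k)]], kMax = 10)
scheduleK <- function(step, kMin = 2L, kMax = 30L,
                      startThreshold = 0.5, stopAfter = 4L) {
    executed <- integer()
    medians <- numeric()
    consideredStart <- NA_integer_
    streak <- 0L
    stopped <- "cap"
    k <- as.integer(kMin)
    while (k <= kMax) {
        m <- step(k)
        executed <- c(executed, k)
        medians[as.character(k)] <- m
        if (is.na(consideredStart) && !is.na(m) && m > startThreshold)
            consideredStart <- k
        if (!is.na(m) && m < startThreshold) streak <- streak + 1L
        else streak <- 0L
        if (streak >= stopAfter) { stopped <- "lowscore"; break }
        k <- k + 1L
    }
    if (stopped == "cap")
        warning(sprintf(
            "rank schedule reached the hard cap kMax = %d before %d consecutive low-score runs",
            kMax, stopAfter))
    consideredK <- if (is.na(consideredStart)) integer()
                   else seq(consideredStart, max(executed))
    list(executed = executed, medians = medians,
         consideredStart = consideredStart,
         consideredK = as.integer(consideredK), stopped = stopped)
}

# Enumerate maximal root-to-leaf branches over the considered ranks.
# Links to parents outside the considered range are cut, making those
# factors branch roots. Branches are ordered by leaf rank then leaf
# index for determinism. Returns a list of factor_id vectors ordered
# root -> leaf.
treeBranches <- function(tree) {
    f <- tree@factors
    keep <- f$k %in% tree@consideredK
    f <- f[keep, , drop = FALSE]
    if (!nrow(f)) return(list())
    parent <- f$parent_id
    parent[!(parent %in% f$factor_id)] <- NA_character_
    isParent <- f$factor_id %in% parent
    leaves <- f[!isParent, , drop = FALSE]
    leaves <- leaves[order(leaves$k, leaves$index), , drop = FALSE]
    lapply(leaves$factor_id, function(leaf) {
        chain <- leaf
        cur <- leaf
        repeat {
            p <- parent[match(cur, f$factor_id)]
            if (is.na(p)) break
            chain <- c(p, chain)
            cur <- p
        }
        chain
    })
}

#' Export a factor tree as DOT
#'
#' Writes a Graphviz DOT description of the factor forest (nodes
#' labeled with factor id and score, edges between linked factors)
#' for visualization.
#'
#' @param tree a \linkS4class{FactorTree}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
exportTreeDot <- function(tree, path) {
    f <- tree@factors
    lines <- c("digraph factors {", "  rankdir=LR;")
    for (i in seq_len(nrow(f))) {
        lab <- sprintf("%s\\n%.2f", f$factor_id[i],
                       if (is.na(f$score[i])) 0 else f$score[i])
        lines <- c(lines, sprintf("  \"%s\" [label=\"%s\"];",
                                  f$factor_id[i], lab))
    }
    linked <- which(!is.na(f$parent_id))
    for (i in linked)
        lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                                  f$parent_id[i], f$factor_id[i]))
    lines <- c(lines, "}")
    writeLines(lines, path)
    invisible(path)
}
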