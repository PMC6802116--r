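#' Quartiles of all factor scores
#'
#' Median (Q2) and third quartile (Q3) over the scores of all factors
#' in the considered ranks (type-7 interpolation), the thresholds of
#' the compartment selection rules.
#'
#' @param tree a \linkS4class{FactorTree} with a non-empty considered
#'   range.
#' @return Named numeric \code{c(Q2 = ..., Q3 = ...)}.
#' @export
scoreQuartiles <- function(tree) {
    f <- tree@factors
    s <- f$score[f$k %in% tree@consideredK & !is.na(f$score)]
    if (!length(s)) stop("no factor scores in the considered ranks")
    c(Q2 = unname(quantile(s, 0.5, type = 7L)),
      Q3 = unname(quantile(s, 0.75, type = 7L)))
}

#' Identify compartments from the factor tree
#'
#' Applies the selection rules to every maximal root-to-leaf branch
#' of the linkage forest over the considered ranks: (a) branches with
#' two or fewer factors are discarded; within a branch, maximal
#' blocks of consecutively linked factors with score above Q2 are
#' located; (c) a block of three or more factors is a major
#' candidate, a block of one or two an unstable candidate; (d) the
#' candidate factor is the block's score maximum, which (b) must also
#' exceed Q3, else the block yields nothing; (e) if several blocks on
#' one branch qualify, the block with the most factors wins, ties
#' broken by the greater block-maximum score. A factor reachable from
#' several branches is selected at most once (first selection, in
#' branch order, wins).
#'
#' @param tree a \linkS4class{FactorTree}.
#' @param quartiles optional precomputed \code{c(Q2, Q3)}; computed
#'   from the tree by default.
#' @return data.frame with columns \code{factor_id}, \code{label}
#'   ("major" or "unstable"), \code{k}, \code{score},
#'   \code{block_length} and \code{branch}. Zero rows (with a
#'   warning) if nothing qualifies.
#' @export
identifyCompartments <- function(tree, quartiles = NULL) {
    if (is.null(quartiles)) quartiles <- scoreQuartiles(tree)
    q2 <- quartiles[["Q2"]]; q3 <- quartiles[["Q3"]]
    f <- tree@factors
    branches <- treeBranches(tree)
    sel <- data.frame(factor_id = character(), label = character(),
                      k = integer(), score = numeric(),
                      block_length = integer(), branch = integer(),
                      stringsAsFactors = FALSE)
    for (bi in seq_along(branches)) {
        br <- branches[[bi]]
        if (length(br) <= 2L) next                      # rule (a)
        sc <- f$score[match(br, f$factor_id)]
        high <- !is.na(sc) & sc > q2
        r <- rle(high)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        bestBlock <- NULL
        for (b in which(r$values)) {
            blk <- seq(starts[b], ends[b])
            cand <- blk[which.max(sc[blk])]             # rule (d)
            if (!(sc[cand] > q3)) next                  # rule (b)
            info <- list(cand = cand, len = length(blk),
                         max = sc[cand])
            if (is.null(bestBlock) ||
                info$len > bestBlock$len ||             # rule (e)
                (info$len == bestBlock$len && info$max > bestBlock$max))
                bestBlock <- info
        }
        if (is.null(bestBlock)) next
        fid <- br[bestBlock$cand]
        if (fid %in% sel$factor_id) next  # selected once, first wins
        label <- if (bestBlock$len >= 3L) "major" else "unstable"
        sel <- rbind(sel, data.frame(
            factor_id = fid, label = label,
            k = f$k[match(fid, f$factor_id)],
            score = sc[bestBlock$cand],
            block_length = bestBlock$len, branch = bi,
            stringsAsFactors = FALSE))
    }
    if (!nrow(sel))
        warning("no compartment satisfies the selection rules")
    sel
}

#' Relabel duplicated majors as minor
#'
#' If two major compartments lie on the same root-to-leaf branch and
#' share strictly more than \code{overlapThreshold} genes of their
#' top-250 lists, the one identified at the larger rank is relabeled
#' "minor".
#'
#' @param selected data.frame from [identifyCompartments()].
#' @param tree the originating \linkS4class{FactorTree} (provides the
#'   top-gene lists and branch structure).
#' @param overlapThreshold strict gene-overlap threshold (100).
#' @return The selection data.frame with updated labels.
#' @export
labelMinor <- function(selected, tree, overlapThreshold = 100L) {
    if (nrow(selected) < 2L) return(selected)
    branches <- treeBranches(tree)
    majors <- which(selected$label == "major")
    if (length(majors) < 2L) return(selected)
    for (a in majors) for (b in majors) {
        if (a >= b) next
        fa <- selected$factor_id[a]; fb <- selected$factor_id[b]
        if (selected$label[a] != "major" || selected$label[b] != "major")
            next
        sameBranch <- any(vapply(branches, function(br)
            all(c(fa, fb) %in% br), logical(1)))
        if (!sameBranch) next
        ov <- length(intersect(tree@topGenes[[fa]], tree@topGenes[[fb]]))
        if (ov > overlapThreshold) {
            larger <- if (selected$k[a] > selected$k[b]) a else b
            selected$label[larger] <- "minor"
        }
    }
    selected
}

#' Assemble the final compartment set
#'
#' Extracts each selected compartment's gene-weight column and
#' sample-weight row verbatim from the run of origin (compartments
#' may originate at different ranks) and names compartments
#' \code{"D<factor_id>"}, with \code{":<annotation>"} appended when an
#' annotation is supplied. Unstable compartments are excluded by
#' default.
#'
#' @param selected labeled selection data.frame (after
#'   [labelMinor()]).
#' @param tree the \linkS4class{FactorTree} holding the runs.
#' @param includeUnstable include unstable compartments in the final
#'   W / H.
#' @param annotations optional named character vector
#'   (factor_id -> annotation).
#' @return A \linkS4class{CompartmentSet}.
#' @export
assembleCompartments <- function(selected, tree,
                                 includeUnstable = FALSE,
                                 annotations = NULL) {
    keep <- selected$label %in%
        c("major", "minor", if (includeUnstable) "unstable")
    sel <- selected[keep, , drop = FALSE]
    if (!nrow(sel)) stop("empty compartment selection")
    ann <- vapply(sel$factor_id, function(id) {
        a <- if (!is.null(annotations)) annotations[id] else NA_character_
        if (is.na(a)) "" else a
    }, "")
    nm <- paste0("D", sel$factor_id,
                 ifelse(nzchar(ann), paste0(":", ann), ""))
    Wcols <- lapply(seq_len(nrow(sel)), function(i) {
        run <- tree@runs[[as.character(sel$k[i])]]
        if (is.null(run)) stop("run at rank ", sel$k[i], " missing")
        run@geneWeights[, match(sel$factor_id[i], run@factorIds)]
    })
    Hrows <- lapply(seq_len(nrow(sel)), function(i) {
        run <- tree@runs[[as.character(sel$k[i])]]
        run@sampleWeights[match(sel$factor_id[i], run@factorIds), ]
    })
    W <- do.call(cbind, Wcols)
    H <- do.call(rbind, Hrows)
    colnames(W) <- nm
    rownames(H) <- nm
    cc <- data.frame(factor_id = sel$factor_id, label = sel$label,
                     k = sel$k, score = sel$score, name = nm,
                     annotation = ann, stringsAsFactors = FALSE,
                     row.names = NULL)
    methods::new("CompartmentSet", compartments = cc,
                 geneWeights = W, sampleWeights = H, markers = list())
}
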