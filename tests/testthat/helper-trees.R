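# Hand-constructed factor-tree fixtures for the compartment-selection
# rule engine, each with a hand-traced expected outcome.

# Build a FactorTree from a compact description: `chains` is a list of
# numeric score vectors; `parents[[i]]` names the (chain, position)
# the first factor of chain i links to (NULL = chain starts a root).
# Factors are labeled "<k>.<index>" automatically.
mkTree <- function(chains, parents = vector("list", length(chains)),
                   kStart = 2L, topGenes = list()) {
    fid <- character(); k <- integer(); idx <- integer()
    score <- numeric(); parent <- character(); ne <- logical()
    chainIds <- vector("list", length(chains))
    perK <- integer()
    for (i in seq_along(chains)) {
        p <- parents[[i]]
        if (is.null(p)) { pk <- NA_integer_; pid <- NA_character_ }
        else { pid <- chainIds[[p[[1L]]]][p[[2L]]]
               pk <- k[match(pid, fid)] }
        k0 <- if (is.na(pk)) kStart + (i > 1L) * 0L else pk + 1L
        if (!is.null(attr(chains, "k0")) && !is.null(attr(chains, "k0")[[i]]))
            k0 <- attr(chains, "k0")[[i]]
        ids <- character(length(chains[[i]]))
        for (j in seq_along(chains[[i]])) {
            kk <- k0 + j - 1L
            perK[as.character(kk)] <-
                (if (is.na(perK[as.character(kk)])) 0L
                 else perK[as.character(kk)]) + 1L
            id <- paste0(kk, ".", perK[as.character(kk)])
            ids[j] <- id
            fid <- c(fid, id); k <- c(k, kk)
            idx <- c(idx, perK[as.character(kk)])
            score <- c(score, chains[[i]][j])
            if (j == 1L) {
                parent <- c(parent, pid)
                ne <- c(ne, is.na(pid))
            } else {
                parent <- c(parent, ids[j - 1L])
                ne <- c(ne, FALSE)
            }
        }
        chainIds[[i]] <- ids
    }
    f <- data.frame(factor_id = fid, k = as.integer(k),
                    index = as.integer(idx), score = score,
                    parent_id = parent, newly_emerged = ne,
                    stringsAsFactors = FALSE)
    tree <- newFactorTree(factors = f, topGenes = topGenes,
                          consideredK = seq(min(f$k), max(f$k)))
    attr(tree, "chainIds") <- chainIds
    tree
}

# Disjoint / overlapping synthetic top-250 gene lists.
geneList <- function(offset, n = 250L) sprintf("g%05d", offset + seq_len(n))

# The fixture suite: each entry has a tree, the quartiles to apply
# (NULL = compute from the tree), and the hand-traced selection
# (factor_id -> label) after minor labeling.
ruleFixtures <- function() {
    fx <- list()

    # 1. straight chain, one long high block: major at its score max
    t1 <- mkTree(list(c(0.9, 0.85, 0.8, 0.3)))
    fx$majorSimple <- list(tree = t1, q = c(Q2 = 0.5, Q3 = 0.7),
                           expect = c(`2.1` = "major"))

    # 2. rule (a): branches with <= 2 factors yield nothing
    t2 <- mkTree(list(c(0.9, 0.8)))
    fx$ruleATwoFactors <- list(tree = t2, q = c(Q2 = 0.5, Q3 = 0.7),
                               expect = character())

    # 3. blocks of length 2 and 1: length-2 block wins rule (e),
    #    classified unstable
    t3 <- mkTree(list(c(0.9, 0.85, 0.4, 0.8, 0.3)))
    fx$lenTwoUnstable <- list(tree = t3, q = c(Q2 = 0.5, Q3 = 0.7),
                              expect = c(`2.1` = "unstable"))

    # 4. rule (b): block maximum below Q3 yields nothing
    t4 <- mkTree(list(c(0.65, 0.6, 0.55, 0.2)))
    fx$ruleBBelowQ3 <- list(tree = t4, q = c(Q2 = 0.5, Q3 = 0.7),
                            expect = character())

    # 5. rule (d): candidate is the block's maximum, not its first
    t5 <- mkTree(list(c(0.6, 0.95, 0.7, 0.2)))
    fx$ruleDMidBlock <- list(tree = t5, q = c(Q2 = 0.5, Q3 = 0.7),
                             expect = c(`3.1` = "major"))

    # 6. rule (e): blocks of length 3 and 4, the longer wins
    t6 <- mkTree(list(c(0.8, 0.75, 0.72, 0.3, 0.9, 0.85, 0.8, 0.78, 0.3)))
    fx$ruleELongerBlock <- list(tree = t6, q = c(Q2 = 0.5, Q3 = 0.7),
                                expect = c(`6.1` = "major"))

    # 7. rule (e): equal-length blocks, greater maximum wins
    t7 <- mkTree(list(c(0.8, 0.75, 0.72, 0.3, 0.85, 0.72, 0.71, 0.3)))
    fx$ruleETieScore <- list(tree = t7, q = c(Q2 = 0.5, Q3 = 0.7),
                             expect = c(`6.1` = "major"))

    # 8. branch split: each sub-branch carries its own major
    t8 <- mkTree(list(c(0.6),                    # root a2
                      c(0.8, 0.82, 0.8, 0.2),    # b3..b6
                      c(0.78, 0.79, 0.77, 0.2)), # c3..c6
                 parents = list(NULL, list(1L, 1L), list(1L, 1L)))
    fx$branchSplitTwoMajors <- list(
        tree = t8, q = c(Q2 = 0.5, Q3 = 0.7),
        expect = c(`4.1` = "major", `4.2` = "major"))

    # 9. two separated high blocks on one root-to-leaf path (a score
    #    dip between them); length-4 block beats length-3 by rule (e)
    #    on the long branch, the short branch still emits the early
    #    major; 150 shared genes relabel the larger-rank one minor
    t9chains <- list(c(0.9, 0.88, 0.86),      # a2 a3 a4 (block, len 3)
                     c(0.3),                  # leaf under a4 (short branch)
                     c(0.4, 0.8, 0.78, 0.76, 0.75, 0.3)) # dip + block len 4
    t9 <- mkTree(t9chains,
                 parents = list(NULL, list(1L, 3L), list(1L, 3L)))
    t9@topGenes <- list(`2.1` = geneList(0),
                        `6.1` = c(geneList(0, 150), geneList(1000, 100)))
    fx$minorSameBranch <- list(
        tree = t9, q = c(Q2 = 0.5, Q3 = 0.7),
        expect = c(`2.1` = "major", `6.1` = "minor"))

    # 10. overlap of exactly 100 genes: strict rule, no relabel
    t10 <- mkTree(t9chains,
                  parents = list(NULL, list(1L, 3L), list(1L, 3L)))
    t10@topGenes <- list(`2.1` = geneList(0),
                         `6.1` = c(geneList(0, 100), geneList(1000, 150)))
    fx$minorBoundary100 <- list(
        tree = t10, q = c(Q2 = 0.5, Q3 = 0.7),
        expect = c(`2.1` = "major", `6.1` = "major"))

    # 11. heavy overlap but different branches: no relabel
    t11 <- mkTree(list(c(0.6),
                       c(0.8, 0.82, 0.8, 0.2),
                       c(0.78, 0.79, 0.77, 0.2)),
                  parents = list(NULL, list(1L, 1L), list(1L, 1L)))
    t11@topGenes <- list(`4.1` = geneList(0),
                         `4.2` = c(geneList(0, 200), geneList(1000, 50)))
    fx$minorNeedsSameBranch <- list(
        tree = t11, q = c(Q2 = 0.5, Q3 = 0.7),
        expect = c(`4.1` = "major", `4.2` = "major"))

    # 12. newly emerged factor roots its own branch
    t12chains <- list(c(0.05, 0.9, 0.88, 0.86, 0.3))
    attr(t12chains, "k0") <- list(5L)
    t12 <- mkTree(t12chains)
    fx$newlyEmergedRoot <- list(
        tree = t12, q = c(Q2 = 0.5, Q3 = 0.7),
        expect = c(`6.1` = "major"))

    # 13. quartiles computed from the tree (type 7): scores
    #     {0.8, 0.6, 0.4, 0.2} give Q2 = 0.5, Q3 = 0.65; block
    #     [0.8, 0.6] is unstable with candidate 0.8 > Q3
    t13 <- mkTree(list(c(0.8, 0.6, 0.4, 0.2)))
    fx$quartilesFromTree <- list(tree = t13, q = NULL,
                                 expect = c(`2.1` = "unstable"))

    # 14. factor reachable from two branches is selected once
    t14 <- mkTree(list(c(0.9, 0.85),             # a2 a3
                       c(0.8, 0.3),              # b4 b5
                       c(0.79, 0.3)),            # c4 c5
                  parents = list(NULL, list(1L, 2L), list(1L, 2L)))
    fx$selectOncePerFactor <- list(
        tree = t14, q = c(Q2 = 0.5, Q3 = 0.7),
        expect = c(`2.1` = "major"))

    # 15. strict inequalities at both quartiles: scores equal to Q2
    #     break the block, candidate equal to Q3 fails rule (b)
    t15 <- mkTree(list(c(0.7, 0.5, 0.5, 0.2)))
    fx$strictBoundaries <- list(tree = t15, q = c(Q2 = 0.5, Q3 = 0.7),
                                expect = character())

    fx
}

# Independent rule-checking oracle: re-validates one emitted major
# against the raw factor table, without using treeBranches() or the
# selection code.
oracleValidMajor <- function(tree, factorId, q2, q3) {
    f <- tree@factors
    f <- f[f$k %in% tree@consideredK, , drop = FALSE]
    i <- match(factorId, f$factor_id)
    if (is.na(i)) return(FALSE)
    if (!(f$score[i] > q3)) return(FALSE)            # rule (b)
    # walk to the chain root and to every leaf; factor must sit in a
    # maximal consecutive >Q2 segment of length >= 3 on some path,
    # and be that segment's maximum
    up <- function(id) {
        chain <- id
        repeat {
            p <- f$parent_id[match(id, f$factor_id)]
            if (is.na(p) || !(p %in% f$factor_id)) break
            chain <- c(p, chain); id <- p
        }
        chain
    }
    downPaths <- function(id) {
        kids <- f$factor_id[!is.na(f$parent_id) & f$parent_id == id]
        if (!length(kids)) return(list(id))
        out <- list()
        for (kd in kids)
            out <- c(out, lapply(downPaths(kd), function(p) c(id, p)))
        out
    }
    pre <- up(factorId)
    for (suff in downPaths(factorId)) {
        path <- c(pre[-length(pre)], suff)
        if (length(path) <= 2L) next                 # rule (a)
        sc <- f$score[match(path, f$factor_id)]
        pos <- match(factorId, path)
        if (!(sc[pos] > q2)) next
        lo <- pos; hi <- pos
        while (lo > 1L && sc[lo - 1L] > q2) lo <- lo - 1L
        while (hi < length(path) && sc[hi + 1L] > q2) hi <- hi + 1L
        if (hi - lo + 1L < 3L) next                  # rule (c)
        if (max(sc[lo:hi]) > sc[pos]) next           # rule (d)
        return(TRUE)
    }
    FALSE
}
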