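## Tree-based phylogroup machinery: patristic distances, node depths,
## within/between group distance distributions, their intersection area, and
## a greedy monophyly-constrained optimiser that algorithmically reproduces
## the manual "edit membership to concord with monophyletic clades and
## minimise the intersection area between curves" procedure.

.checkTree <- function(tree) {
    if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
    if (anyDuplicated(tree$tip.label)) stop("leaf labels must be unique")
    if (is.null(tree$edge.length) || any(tree$edge.length < 0))
        stop("tree must have non-negative branch lengths")
    tree
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between each pair of leaves.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @return Symmetric numeric matrix with zero diagonal, ordered by
#'   `tree$tip.label`.
#' @export
patristicDistances <- function(tree) {
    tree <- .checkTree(tree)
    d <- ape::cophenetic.phylo(tree)
    d[tree$tip.label, tree$tip.label]
}

#' Node depth of a leaf (number of nodes to root)
#'
#' Counts the internal nodes on the path from a leaf to the root, excluding
#' the leaf and including the root: equivalently, the number of edges on the
#' path. A leaf that is a direct child of the root has depth 1.
#'
#' @param tree A rooted `phylo` tree.
#' @param taxon Leaf label (or vector of labels).
#' @return Integer depth(s), named by taxon.
#' @export
nodesToRoot <- function(tree, taxon) {
    tree <- .checkTree(tree)
    miss <- setdiff(taxon, tree$tip.label)
    if (length(miss)) stop("unknown taxon: ", paste(miss, collapse = ", "))
    parent <- integer(max(tree$edge))
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    root <- ape::Ntip(tree) + 1L
    depth1 <- function(tip) {
        node <- match(tip, tree$tip.label)
        k <- 0L
        while (node != root) {
            node <- parent[node]
            k <- k + 1L
        }
        k
    }
    setNames(vapply(taxon, depth1, integer(1)), taxon)
}

#' Mean node depth per trait class
#'
#' Average number of nodes to root per metabolic group (e.g. A obligately
#' homofermentative, B facultatively heterofermentative, C obligately
#' heterofermentative); a class close to the root-most ancestor has a low
#' mean depth.
#'
#' @param tree A rooted `phylo` tree.
#' @param traits Named character vector: leaf -> trait class; every leaf
#'   must be covered.
#' @return data.frame (`class`, `mean_depth`, `n`); classes with no members
#'   are absent.
#' @export
traitMeanDepth <- function(tree, traits) {
    tree <- .checkTree(tree)
    miss <- setdiff(tree$tip.label, names(traits))
    if (length(miss)) stop("traits missing for: ",
                           paste(miss, collapse = ", "))
    d <- nodesToRoot(tree, tree$tip.label)
    cl <- traits[tree$tip.label]
    agg <- tapply(d, cl, mean)
    data.frame(class = names(agg), mean_depth = as.numeric(agg),
               n = as.integer(table(cl)[names(agg)]),
               stringsAsFactors = FALSE)
}

#' Intersection area of two empirical distributions
#'
#' Histograms both value sets on shared bin edges spanning their pooled
#' range and returns `sum(min(f1, f2)) * binwidth` of the normalised
#' densities: 1 for identical distributions, 0 for disjoint supports.
#'
#' @param values1,values2 Numeric vectors (at least one value each).
#' @param bins Number of shared bins.
#' @param edges Optional explicit bin edges overriding `bins`.
#' @return Intersection area in `[0, 1]`.
#' @export
intersectionArea <- function(values1, values2, bins = 100L, edges = NULL) {
    if (!length(values1) || !length(values2))
        return(NA_real_)
    if (is.null(edges)) {
        rng <- range(c(values1, values2))
        if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
        edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    }
    d1 <- .binDensity(values1, edges)
    d2 <- .binDensity(values2, edges)
    min(1, sum(pmin(d1, d2)) * diff(edges)[1])
}

#' Within- and between-group distance distributions
#'
#' Pools all intra-group pair distances (within) and all inter-group pair
#' distances (between), histograms both on shared bin edges and computes
#' their intersection area. Groups of size one contribute no within-pairs.
#'
#' @param groups Named character vector: taxon -> group label.
#' @param dist Symmetric distance matrix covering all grouped taxa
#'   (patristic, node depth based, or `1 - TNI`).
#' @param bins Number of shared bins.
#' @return List of class `DistributionPair`: `within`, `between` (values),
#'   `edges`, `within_density`, `between_density`, `intersection_area`.
#' @export
groupDistanceDistributions <- function(groups, dist, bins = 100L) {
    taxa <- names(groups)
    if (!all(taxa %in% rownames(dist)))
        stop("distance matrix must cover all grouped taxa")
    d <- dist[taxa, taxa]
    prs <- which(upper.tri(d), arr.ind = TRUE)
    same <- groups[prs[, 1]] == groups[prs[, 2]]
    within <- d[prs][same]
    between <- d[prs][!same]
    if (!length(within) || !length(between)) {
        out <- list(within = within, between = between, edges = NULL,
                    within_density = NULL, between_density = NULL,
                    intersection_area = NA_real_)
        class(out) <- "DistributionPair"
        return(out)
    }
    rng <- range(c(within, between))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    wd <- .binDensity(within, edges)
    bd <- .binDensity(between, edges)
    out <- list(within = within, between = between, edges = edges,
                within_density = wd, between_density = bd,
                intersection_area = min(1, sum(pmin(wd, bd)) *
                                            diff(edges)[1]))
    class(out) <- "DistributionPair"
    out
}

#' @export
print.DistributionPair <- function(x, ...) {
    cat("DistributionPair |", length(x$within), "within pairs,",
        length(x$between), "between pairs | intersection area",
        signif(x$intersection_area, 4), "\n")
    invisible(x)
}

#' Monophyly of a taxon set
#'
#' TRUE iff the smallest clade containing `taxon_set` contains no other
#' leaves; singletons are monophyletic by convention.
#'
#' @param tree A rooted `phylo` tree.
#' @param taxon_set Non-empty subset of leaf labels.
#' @return Logical.
#' @export
monophylyCheck <- function(tree, taxon_set) {
    tree <- .checkTree(tree)
    if (!length(taxon_set)) stop("taxon_set must be non-empty")
    miss <- setdiff(taxon_set, tree$tip.label)
    if (length(miss)) stop("unknown taxa: ", paste(miss, collapse = ", "))
    if (length(taxon_set) <= 1L) return(TRUE)
    ape::is.monophyletic(tree, taxon_set)
}

.groupObjective <- function(groups, dist, bins) {
    groupDistanceDistributions(groups, dist, bins)$intersection_area
}

.allMonophyletic <- function(tree, groups) {
    all(vapply(split(names(groups), groups), function(tx)
        monophylyCheck(tree, tx), logical(1)))
}

#' Greedy monophyly-constrained phylogroup optimisation
#'
#' Local search over phylogroupings that minimises the intersection area
#' between the within-group and between-group distance distributions. The
#' move set is: reassign one taxon to another existing group; merge two
#' groups; split a group into the child clades of its most recent common
#' ancestor. A move is admissible only if every resulting group is
#' monophyletic on `tree` and the objective remains defined (at least one
#' within- and one between-pair); it is accepted only if the objective
#' strictly decreases. The first admissible improving move in scan order
#' (taxa in tip order x groups in sorted label order, then merges, then
#' splits) is taken, so the procedure is deterministic, the objective is
#' monotone non-increasing, and rerunning on the output changes nothing.
#'
#' @param tree A rooted `phylo` tree over the grouped taxa.
#' @param initial Named character vector taxon -> group (need not be
#'   monophyletic; the optimiser can only accept moves whose result is).
#' @param dist Distance matrix; defaults to [patristicDistances()] of
#'   `tree`. Supply `1 - idValues(tni_matrix)` for the whole-genome variant.
#' @param bins Shared histogram bins for the objective.
#' @param max_iter Maximum accepted moves.
#' @return A [Phylogrouping-class] with the objective trace.
#' @export
optimizePhylogroups <- function(tree, initial, dist = NULL, bins = 100L,
                                max_iter = 100L) {
    tree <- .checkTree(tree)
    miss <- setdiff(names(initial), tree$tip.label)
    if (length(miss)) stop("unknown taxa in grouping: ",
                           paste(miss, collapse = ", "))
    if (!setequal(names(initial), tree$tip.label))
        stop("initial grouping must cover every leaf")
    if (is.null(dist)) dist <- patristicDistances(tree)
    groups <- initial[tree$tip.label]
    obj <- .groupObjective(groups, dist, bins)
    trace <- obj

    candidateMoves <- function(groups) {
        labs <- sort(unique(groups))
        moves <- list()
        for (tx in tree$tip.label) for (g in labs) {
            if (groups[[tx]] == g) next
            moves[[length(moves) + 1L]] <- list(kind = "reassign",
                                                taxon = tx, to = g)
        }
        if (length(labs) > 1L)
            for (i in seq_len(length(labs) - 1L))
                for (j in seq.int(i + 1L, length(labs)))
                    moves[[length(moves) + 1L]] <- list(
                        kind = "merge", a = labs[i], b = labs[j])
        for (g in labs) {
            tx <- names(groups)[groups == g]
            if (length(tx) < 2L) next
            moves[[length(moves) + 1L]] <- list(kind = "split", group = g)
        }
        moves
    }
    applyMove <- function(groups, mv) {
        if (mv$kind == "reassign") {
            groups[[mv$taxon]] <- mv$to
        } else if (mv$kind == "merge") {
            groups[groups == mv$b] <- mv$a
        } else {
            tx <- names(groups)[groups == mv$group]
            mrca <- ape::getMRCA(tree, tx)
            if (is.null(mrca)) return(NULL)
            kids <- tree$edge[tree$edge[, 1] == mrca, 2]
            for (k in seq_along(kids)) {
                sub <- if (kids[k] <= ape::Ntip(tree))
                    tree$tip.label[kids[k]]
                else ape::extract.clade(tree, kids[k])$tip.label
                sub <- intersect(sub, tx)
                if (!length(sub)) next
                groups[sub] <- paste0(mv$group, letters[k])
            }
        }
        groups
    }

    for (it in seq_len(max_iter)) {
        improved <- FALSE
        for (mv in candidateMoves(groups)) {
            cand <- applyMove(groups, mv)
            if (is.null(cand)) next
            if (length(unique(cand)) < 2L) next
            if (!.allMonophyletic(tree, cand)) next
            co <- .groupObjective(cand, dist, bins)
            if (is.na(co)) next
            if (!is.na(obj) && co >= obj - 1e-12) next
            groups <- cand
            obj <- co
            trace <- c(trace, obj)
            improved <- TRUE
            break
        }
        if (!improved) break
    }
    mono <- vapply(split(names(groups), groups), function(tx)
        monophylyCheck(tree, tx), logical(1))
    new("Phylogrouping", assignment = groups, monophyletic = mono,
        objective = obj, trace = trace)
}

#' Cut a tree into k monophyletic groups
#'
#' Deterministic helper producing an initial phylogrouping: starting from
#' one group holding all leaves, repeatedly splits the largest group at its
#' MRCA until `k` groups exist (or no group can be split).
#'
#' @param tree A rooted `phylo` tree.
#' @param k Desired number of groups.
#' @return Named character vector taxon -> group label.
#' @export
cladeGroups <- function(tree, k) {
    tree <- .checkTree(tree)
    groups <- setNames(rep("G1", ape::Ntip(tree)), tree$tip.label)
    nxt <- 2L
    while (length(unique(groups)) < k) {
        sizes <- sort(table(groups), decreasing = TRUE)
        target <- NULL
        for (g in names(sizes)) {
            if (sizes[[g]] >= 2L) { target <- g; break }
        }
        if (is.null(target)) break
        tx <- names(groups)[groups == target]
        mrca <- ape::getMRCA(tree, tx)
        kids <- tree$edge[tree$edge[, 1] == mrca, 2]
        for (kid in kids) {
            sub <- if (kid <= ape::Ntip(tree)) tree$tip.label[kid]
                else ape::extract.clade(tree, kid)$tip.label
            sub <- intersect(sub, tx)
            if (!length(sub)) next
            groups[sub] <- paste0("G", nxt)
            nxt <- nxt + 1L
        }
    }
    groups
}
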