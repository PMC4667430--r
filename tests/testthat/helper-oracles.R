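## Independent oracles used across the suite. These deliberately re-derive
## results by the most naive route available (full dynamic programming,
## exhaustive enumeration, direct rank arithmetic) and never call the code
## paths they check.

.oDNA <- c("A", "C", "G", "T")
.oAA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

randomDna <- function(n) paste(sample(.oDNA, n, TRUE), collapse = "")
randomProtein <- function(n) paste(sample(.oAA, n, TRUE), collapse = "")

## substitute exactly n_sites positions (no indels), never to the same base
mutateSites <- function(seq, n_sites) {
    x <- strsplit(seq, "", fixed = TRUE)[[1]]
    idx <- sample(length(x), n_sites)
    for (i in idx) x[i] <- sample(setdiff(.oDNA, x[i]), 1)
    paste(x, collapse = "")
}

mutateProtein <- function(seq, n_sites) {
    x <- strsplit(seq, "", fixed = TRUE)[[1]]
    idx <- sample(length(x), n_sites)
    for (i in idx) x[i] <- sample(setdiff(.oAA, x[i]), 1)
    paste(x, collapse = "")
}

## --------------------------------------------------------------------------
## Naive affine-gap Smith-Waterman (Gotoh), pure R, small inputs only.
## Gap of length L costs open + L * ext, matching the package convention.
## --------------------------------------------------------------------------
oracleLocalScore <- function(a, b, submat, open, ext) {
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    n <- length(av); m <- length(bv)
    NEG <- -1e9
    M <- matrix(0, n + 1, m + 1)
    Ix <- matrix(NEG, n + 1, m + 1)   # gap in b (vertical)
    Iy <- matrix(NEG, n + 1, m + 1)   # gap in a (horizontal)
    best <- 0
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
        s <- submat[av[i - 1], bv[j - 1]]
        M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                       Iy[i - 1, j - 1] + s)
        Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
        Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
        best <- max(best, M[i, j])
    }
    best
}

## --------------------------------------------------------------------------
## Transitive-closure clustering oracle: every pair of genes is aligned
## (no prefilter) and genes passing the thresholds in either direction are
## connected; families are connected components.
## --------------------------------------------------------------------------
oracleClosureFamilies <- function(proteomes, min_identity = 25,
                                  min_query_cov = 40) {
    seqs <- unlist(lapply(proteomes, as.character))
    names(seqs) <- unlist(lapply(proteomes, names))
    ids <- names(seqs)
    n <- length(ids)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
        h <- localAlign(seqs[[i]], seqs[[j]], proteinScheme())
        if (is.null(h)) next
        pass <- h$identity_pct >= min_identity &&
            (h$query_cov_pct >= min_query_cov ||
             h$subject_cov_pct >= min_query_cov)
        if (pass) parent[find(j)] <- find(i)
    }
    roots <- vapply(seq_len(n), find, integer(1))
    unname(lapply(split(ids, roots), sort))
}

## canonical form of a partition (list of member vectors) for set comparison
canonicalPartition <- function(fams) {
    fams <- lapply(fams, function(f) unname(sort(f)))
    unname(fams[order(vapply(fams, `[`, character(1), 1))])
}

## --------------------------------------------------------------------------
## Full-matrix Markov clustering oracle (no component decomposition):
## clusters read off the attractor rows of the limit matrix.
## --------------------------------------------------------------------------
oracleMcl <- function(W, inflation = 2, expansion = 2, iters = 200) {
    diag(W) <- pmax(apply(W, 2, max), 1e-6)
    M <- sweep(W, 2, colSums(W), "/")
    for (k in seq_len(iters)) {
        E <- M
        for (e in seq_len(expansion - 1)) E <- E %*% M
        E <- E ^ inflation
        E <- sweep(E, 2, colSums(E), "/")
        if (max(abs(E - M)) < 1e-9) { M <- E; break }
        M <- E
    }
    attr_rows <- which(diag(M) > 1e-6)
    clusters <- lapply(attr_rows, function(r) which(M[r, ] > 1e-6))
    ## merge attractor systems that overlap
    out <- list()
    for (cl in clusters) {
        hit <- which(vapply(out, function(o) length(intersect(o, cl)) > 0,
                            logical(1)))
        if (length(hit)) {
            out[[hit[1]]] <- sort(unique(c(out[[hit[1]]],
                                           unlist(out[hit]), cl)))
            out <- out[-setdiff(hit, hit[1])]
        } else out[[length(out) + 1]] <- sort(cl)
    }
    out
}

## --------------------------------------------------------------------------
## Patristic distance oracle: explicit path walk through the edge table.
## --------------------------------------------------------------------------
oraclePatristic <- function(tree) {
    n <- ape::Ntip(tree)
    parent <- integer(max(tree$edge)); blen <- numeric(max(tree$edge))
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    blen[tree$edge[, 2]] <- tree$edge.length
    root <- n + 1L
    pathToRoot <- function(i) {
        nodes <- integer(0)
        while (i != root) { nodes <- c(nodes, i); i <- parent[i] }
        c(nodes, root)
    }
    D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
        pi <- pathToRoot(i); pj <- pathToRoot(j)
        mrca <- pi[pi %in% pj][1]
        di <- sum(blen[pi[seq_len(which(pi == mrca) - 1)]])
        dj <- sum(blen[pj[seq_len(which(pj == mrca) - 1)]])
        D[i, j] <- D[j, i] <- di + dj
    }
    D
}

## --------------------------------------------------------------------------
## All partitions of a tree's leaves into monophyletic blocks (each block a
## clade), by recursion over the topology.
## --------------------------------------------------------------------------
oracleMonophyleticPartitions <- function(tree) {
    n <- ape::Ntip(tree)
    kids <- function(node) tree$edge[tree$edge[, 1] == node, 2]
    leavesUnder <- function(node) {
        if (node <= n) return(tree$tip.label[node])
        unlist(lapply(kids(node), leavesUnder))
    }
    rec <- function(node) {
        whole <- list(list(sort(leavesUnder(node))))
        if (node <= n) return(whole)
        parts_per_child <- lapply(kids(node), rec)
        combo <- list(list())
        for (pc in parts_per_child) {
            combo <- unlist(lapply(combo, function(acc)
                lapply(pc, function(p) c(acc, p))), recursive = FALSE)
        }
        c(whole, combo)
    }
    rec(n + 1L)
}

## --------------------------------------------------------------------------
## Direct Kruskal-Wallis H with tie correction, from first principles.
## --------------------------------------------------------------------------
oracleKruskalH <- function(values, groups) {
    r <- rank(values)
    n <- length(values)
    h <- 12 / (n * (n + 1)) *
        sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) -
        3 * (n + 1)
    ties <- table(values)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

## small helper: fixed trees used across tests
balancedTree4 <- function() ape::read.tree(text =
    "((A:1,B:1):1,(C:1,D:1):1);")
caterpillarTree5 <- function() ape::read.tree(text =
    "((((A:1,B:1):1,C:1):1,D:1):1,E:1);")
plantedCladeTree <- function() ape::read.tree(text = paste0(
    "(((a1:0.1,a2:0.1):0.1,a3:0.2):1.0,",
    "((b1:0.1,b2:0.1):1.0,((c1:0.1,c2:0.1):0.1,c3:0.2):1.0):0.5);"))
plantedCladeGroups <- function() setNames(
    c("A", "A", "A", "B", "B", "C", "C", "C"),
    c("a1", "a2", "a3", "b1", "b2", "c1", "c2", "c3"))

## planted proteome builder: `spec` is a list of family definitions, each a
## character vector of genome names; every listed genome receives one gene
## of that family derived from a common ancestor at ~90% identity
plantedProteomes <- function(spec, genomes, len = 120) {
    prot <- setNames(lapply(genomes, function(g) character(0)), genomes)
    for (f in seq_along(spec)) {
        anc <- randomProtein(len)
        for (g in spec[[f]]) {
            gene <- mutateProtein(anc, round(0.05 * len))
            prot[[g]][sprintf("%s_f%02d", g, f)] <- gene
        }
    }
    lapply(prot, Biostrings::AAStringSet)
}
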