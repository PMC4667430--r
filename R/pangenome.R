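## Pan-genome construction: greedy family accumulation against family
## representatives, reciprocal-best-hit orthology, two-stage clustering
## (Markov clustering refined clusters re-joined by single linkage),
## core-gene selection, taxon drop-out robustness and contig-fragmentation
## sensitivity.

.proteomeList <- function(x) {
    out <- lapply(x, function(g)
        if (is(g, "GenomeRecord")) proteins(g) else Biostrings::AAStringSet(g))
    if (is.null(names(out)) || any(!nzchar(names(out))))
        stop("proteomes must be named by genome")
    out
}

## pan/core rarefaction curves from a family x genome presence matrix;
## the first genome of the realised order stays first in every permutation
.panCurvesFromPresence <- function(presence, first_genome, n_perm, seed) {
    genomes <- colnames(presence)
    rest <- setdiff(genomes, first_genome)
    ng <- length(genomes)
    pan <- matrix(NA_real_, n_perm, ng)
    core <- matrix(NA_real_, n_perm, ng)
    .withSeed(seed, for (p in seq_len(n_perm)) {
        ord <- c(first_genome, sample(rest))
        seen <- rep(0L, nrow(presence))
        allin <- rep(TRUE, nrow(presence))
        for (k in seq_len(ng)) {
            v <- presence[, ord[k]] > 0
            seen <- seen | v
            allin <- allin & v
            pan[p, k] <- sum(seen)
            core[p, k] <- sum(allin)
        }
    })
    list(pan = data.frame(k = seq_len(ng), mean = colMeans(pan),
                          sd = apply(pan, 2, sd)),
         core = data.frame(k = seq_len(ng), mean = colMeans(core),
                           sd = apply(core, 2, sd)),
         pan_perm = pan, core_perm = core)
}

#' Greedy pan-genome family accumulation
#'
#' Genomes are taken in a fixed-first, then seed-shuffled order. Each
#' incoming gene is compared against the representatives (founder genes) of
#' the families accumulated so far and joins the earliest-founded family
#' whose representative it hits at or above the identity/coverage thresholds
#' (default 25% identity over 40% of the gene length); otherwise it founds a
#' new family. Within-genome paralogs above threshold therefore collapse
#' into one family. Pan and core rarefaction curves (mean and sd over
#' `n_perm` seeded permutations of the non-first genomes) are computed from
#' the resulting family presence matrix.
#'
#' @param proteomes Named list of `AAStringSet` (or [GenomeRecord-class]s).
#' @param first_genome Genome fixed at position one (defaults to the first
#'   element).
#' @param min_identity,min_query_cov Thresholds in percent, inclusive;
#'   coverage is relative to the incoming gene.
#' @param seed Seed for the accumulation order and curve permutations.
#' @param n_perm Number of order permutations for the curves.
#' @param scheme Protein [ScoringScheme-class].
#' @param word_size,min_shared_kmers Seeding prefilter (see [allPairsHits()]).
#' @return A [PanResult-class].
#' @export
accumulatePanFamilies <- function(proteomes, first_genome = NULL,
                                  min_identity = 25, min_query_cov = 40,
                                  seed = 1L, n_perm = 10L,
                                  scheme = proteinScheme(),
                                  word_size = 5, min_shared_kmers = 2) {
    prot <- .proteomeList(proteomes)
    if (length(prot) == 0L) stop("need at least one proteome")
    if (is.null(first_genome)) first_genome <- names(prot)[1]
    stopifnot(first_genome %in% names(prot))
    ord <- .withSeed(seed, c(first_genome,
                             sample(setdiff(names(prot), first_genome))))
    mat <- .substitutionMatrix(scheme)

    rep_seq <- character(0)          # representative (founder) sequences
    rep_gene <- character(0)
    members <- list()                # per family: data.frame(genome, gene)
    step_counts <- integer(0)

    for (gname in ord) {
        gs <- prot[[gname]]
        if (is.null(names(gs)) || anyDuplicated(names(gs)))
            stop("gene ids must be unique within genome ", gname)
        cand_old <- if (length(rep_seq) && min_shared_kmers > 0)
            .sharedKmerCounts(as.character(gs), rep_seq, word_size) >=
                min_shared_kmers
        else matrix(TRUE, length(gs), length(rep_seq))
        within <- if (min_shared_kmers > 0)
            .sharedKmerCounts(as.character(gs), as.character(gs), word_size) >=
                min_shared_kmers
        else matrix(TRUE, length(gs), length(gs))
        n_old <- length(rep_seq)
        ## batch-align every (gene, old-representative) candidate pair once;
        ## the old representatives cannot change while this genome is added
        old_pass <- vector("list", length(gs))
        if (n_old) {
            idx <- which(cand_old, arr.ind = TRUE)
            if (nrow(idx)) {
                pa <- Biostrings::pairwiseAlignment(
                    gs[idx[, 1]],
                    Biostrings::AAStringSet(rep_seq)[idx[, 2]],
                    type = "local", substitutionMatrix = mat,
                    gapOpening = scheme@gap_open,
                    gapExtension = scheme@gap_extend)
                idn <- 100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
                cov <- 100 * IRanges::width(
                    IRanges::ranges(Biostrings::pattern(pa))) /
                    Biostrings::width(gs)[idx[, 1]]
                okp <- Biostrings::score(pa) > 0 & idn >= min_identity &
                    cov >= min_query_cov
                for (r in which(okp)) {
                    i <- idx[r, 1]
                    old_pass[[i]] <- c(old_pass[[i]], idx[r, 2])
                }
            }
        }
        alignsToRep <- function(i, fidx) {
            ## same-genome founder check (new families only)
            pa <- Biostrings::pairwiseAlignment(
                gs[[i]], Biostrings::AAString(rep_seq[fidx]),
                type = "local", substitutionMatrix = mat,
                gapOpening = scheme@gap_open,
                gapExtension = scheme@gap_extend)
            idn <- 100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
            cov <- 100 * IRanges::width(
                IRanges::ranges(Biostrings::pattern(pa))) /
                Biostrings::width(gs)[i]
            Biostrings::score(pa) > 0 && idn >= min_identity &&
                cov >= min_query_cov
        }
        new_idx <- integer(0)        # families founded by this genome
        for (i in seq_along(gs)) {
            fam <- NA_integer_
            hits_old <- sort(old_pass[[i]])
            if (length(hits_old)) fam <- hits_old[1]
            if (is.na(fam) && length(new_idx)) {
                local_new <- new_idx[within[i, match(rep_gene[new_idx],
                                                     names(gs))]]
                for (fidx in sort(local_new)) {
                    if (alignsToRep(i, fidx)) { fam <- fidx; break }
                }
            }
            if (is.na(fam)) {
                rep_seq <- c(rep_seq, as.character(gs[[i]]))
                rep_gene <- c(rep_gene, names(gs)[i])
                members[[length(members) + 1L]] <- data.frame(
                    genome_id = gname, gene_id = names(gs)[i],
                    stringsAsFactors = FALSE)
                new_idx <- c(new_idx, length(rep_seq))
            } else {
                members[[fam]] <- rbind(members[[fam]], data.frame(
                    genome_id = gname, gene_id = names(gs)[i],
                    stringsAsFactors = FALSE))
            }
        }
        step_counts <- c(step_counts, length(members))
    }

    fam_ids <- sprintf("PF%05d", seq_along(members))
    presence <- matrix(0L, length(members), length(ord),
                       dimnames = list(fam_ids, ord))
    for (f in seq_along(members))
        presence[f, unique(members[[f]]$genome_id)] <- 1L
    curves <- .panCurvesFromPresence(presence, first_genome,
                                     n_perm = n_perm, seed = seed + 1L)
    families <- lapply(seq_along(members), function(f)
        list(family_id = fam_ids[f], members = members[[f]],
             representative = rep_gene[f]))
    new("PanResult", families = families, genome_order = ord,
        presence = presence, pan_curve = curves$pan,
        core_curve = curves$core, step_counts = step_counts)
}

#' Pan/core curves for explicit permutations
#'
#' Recomputes pan (families seen) and core (families shared) trajectories for
#' `n_perm` seeded permutations from a presence matrix, returning the
#' per-permutation matrices as well as summaries. Used for monotonicity
#' checks and fragmentation-sensitivity curves.
#'
#' @param presence family x genome 0/1 matrix.
#' @param first_genome Genome fixed first in every permutation.
#' @param n_perm,seed Permutation count and seed.
#' @return List with `pan`, `core` (data.frames k/mean/sd) and the
#'   per-permutation matrices `pan_perm`, `core_perm`.
#' @export
panCurves <- function(presence, first_genome = colnames(presence)[1],
                      n_perm = 10L, seed = 1L)
    .panCurvesFromPresence(presence, first_genome, n_perm, seed)

## ---------------------------------------------------------------------------
## RBH orthology + two-stage clustering
## ---------------------------------------------------------------------------

#' Reciprocal-best-hit orthologs between two proteomes
#'
#' Pairs of genes that are each other's highest-scoring passing hit at the
#' given cutoffs (default 25% identity over 40% of the query length, both
#' inclusive). Coverage is checked in each direction relative to that
#' direction's query. Ties are broken by higher identity, then
#' lexicographically smaller partner id.
#'
#' @param proteome_a,proteome_b Named `AAStringSet`s of two distinct genomes.
#' @inheritParams accumulatePanFamilies
#' @return data.frame (`gene_a`, `gene_b`, `identity_pct`, `score`).
#' @export
rbhOrthologs <- function(proteome_a, proteome_b, min_identity = 25,
                         min_query_cov = 40, scheme = proteinScheme(),
                         word_size = 5, min_shared_kmers = 2) {
    raw <- allPairsHits(proteome_a, proteome_b, scheme,
                        min_identity = 0, min_query_cov = 0,
                        word_size = word_size,
                        min_shared_kmers = min_shared_kmers)
    if (nrow(raw) == 0L)
        return(data.frame(gene_a = character(0), gene_b = character(0),
                          identity_pct = numeric(0), score = numeric(0),
                          stringsAsFactors = FALSE))
    fwd <- raw[raw$identity_pct >= min_identity &
               raw$query_cov_pct >= min_query_cov, , drop = FALSE]
    rev <- raw
    names(rev)[names(rev) == "query_id"] <- ".tmp"
    names(rev)[names(rev) == "subject_id"] <- "query_id"
    names(rev)[names(rev) == ".tmp"] <- "subject_id"
    qc <- rev$query_cov_pct
    rev$query_cov_pct <- rev$subject_cov_pct
    rev$subject_cov_pct <- qc
    rev <- rev[rev$identity_pct >= min_identity &
               rev$query_cov_pct >= min_query_cov, , drop = FALSE]
    bf <- selectBestHits(fwd)
    bb <- selectBestHits(rev)
    key_f <- paste(bf$query_id, bf$subject_id)
    key_b <- paste(bb$subject_id, bb$query_id)
    keep <- bf[key_f %in% key_b, , drop = FALSE]
    data.frame(gene_a = keep$query_id, gene_b = keep$subject_id,
               identity_pct = keep$identity_pct, score = keep$score,
               stringsAsFactors = FALSE)
}

## Markov clustering on a weighted adjacency matrix (dense, used per
## connected component): column-stochastic normalisation, expansion by
## matrix power, inflation by entrywise power, until the matrix change
## drops below tol. Self-loops are set to the maximum incident weight.
.mclCluster <- function(W, inflation = 2, expansion = 2L, tol = 1e-6,
                        max_iter = 100L) {
    n <- nrow(W)
    if (n == 1L) return(list(1L))
    diag(W) <- pmax(apply(W, 2, max), 1e-6)
    M <- sweep(W, 2, colSums(W), "/")
    for (it in seq_len(max_iter)) {
        E <- M
        for (e in seq_len(expansion - 1L)) E <- E %*% M
        E <- E ^ inflation
        E <- sweep(E, 2, colSums(E), "/")
        delta <- max(abs(E - M))
        M <- E
        if (delta < tol) break
    }
    ## attractor-based interpretation: nodes sharing an attractor row form a
    ## cluster; realised as components of the symmetrised support graph
    sup <- (M + t(M)) > 1e-8
    g <- igraph::graph_from_adjacency_matrix(sup, mode = "undirected",
                                             diag = FALSE)
    cl <- igraph::components(g)$membership
    split(seq_len(n), cl)
}

#' Two-stage clustering of an ortholog graph
#'
#' Stage one runs Markov clustering (expansion 2, inflation 2.0 by default)
#' on the identity-weighted reciprocal-best-hit graph, independently per
#' connected component. Stage two applies single-linkage merging: clusters
#' that share any RBH edge between their members are merged. The output
#' partitions the full gene universe; genes without edges become singleton
#' families. Note the single-linkage stage can re-join clusters that Markov
#' clustering split across a weak bridge, up to whole connected components.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `identity_pct`
#'   (edge weight), e.g. the union of [rbhOrthologs()] tables over genome
#'   pairs.
#' @param nodes Character vector: the full gene universe to partition.
#' @param inflation,expansion,tol,max_iter Markov clustering controls.
#' @return List of character vectors, one per family.
#' @export
twoStageCluster <- function(edges, nodes, inflation = 2, expansion = 2L,
                            tol = 1e-6, max_iter = 100L) {
    nodes <- unique(nodes)
    if (nrow(edges)) {
        stopifnot(all(c(edges$gene_a, edges$gene_b) %in% nodes))
    }
    g <- igraph::graph_from_data_frame(
        if (nrow(edges)) edges[, c("gene_a", "gene_b")] else
            data.frame(from = character(0), to = character(0)),
        directed = FALSE, vertices = data.frame(name = nodes))
    comp <- igraph::components(g)$membership
    fams <- list()
    for (cid in unique(comp)) {
        vs <- names(comp)[comp == cid]
        if (length(vs) == 1L) { fams[[length(fams) + 1L]] <- vs; next }
        sub <- edges[edges$gene_a %in% vs & edges$gene_b %in% vs, ,
                     drop = FALSE]
        W <- matrix(0, length(vs), length(vs), dimnames = list(vs, vs))
        W[cbind(sub$gene_a, sub$gene_b)] <- sub$identity_pct
        W[cbind(sub$gene_b, sub$gene_a)] <- sub$identity_pct
        cl <- .mclCluster(W, inflation, expansion, tol, max_iter)
        clusters <- lapply(cl, function(ii) vs[ii])
        ## single-linkage merge over clusters sharing any RBH edge
        cl_of <- integer(length(vs)); names(cl_of) <- vs
        for (k in seq_along(clusters)) cl_of[clusters[[k]]] <- k
        mg <- igraph::graph_from_data_frame(
            unique(data.frame(from = cl_of[sub$gene_a],
                              to = cl_of[sub$gene_b])),
            directed = FALSE,
            vertices = data.frame(name = seq_along(clusters)))
        mcomp <- igraph::components(mg)$membership
        for (mid in unique(mcomp)) {
            ks <- as.integer(names(mcomp)[mcomp == mid])
            fams[[length(fams) + 1L]] <-
                sort(unlist(clusters[ks], use.names = FALSE))
        }
    }
    fams
}

#' Gene families over a genome set via RBH + two-stage clustering
#'
#' Runs [rbhOrthologs()] over every unordered genome pair, pools the edges
#' and partitions all genes with [twoStageCluster()].
#'
#' @inheritParams accumulatePanFamilies
#' @return List with `families` (list of gene-id vectors), `edges` (pooled
#'   RBH table) and `gene_genome` (named vector gene -> genome).
#' @export
buildGeneFamilies <- function(proteomes, min_identity = 25,
                              min_query_cov = 40, scheme = proteinScheme(),
                              word_size = 5, min_shared_kmers = 2) {
    prot <- .proteomeList(proteomes)
    if (length(prot) < 2L) stop("need at least two proteomes")
    gene_genome <- unlist(lapply(names(prot), function(g)
        setNames(rep(g, length(prot[[g]])), names(prot[[g]]))))
    if (anyDuplicated(names(gene_genome)))
        stop("gene ids must be unique across genomes")
    pairs <- combn(names(prot), 2)
    edges <- vector("list", ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
        edges[[p]] <- rbhOrthologs(prot[[pairs[1, p]]], prot[[pairs[2, p]]],
                                   min_identity, min_query_cov, scheme,
                                   word_size, min_shared_kmers)
    }
    edges <- do.call(rbind, edges)
    fams <- twoStageCluster(edges, nodes = names(gene_genome))
    list(families = fams, edges = edges, gene_genome = gene_genome)
}

#' Core gene families
#'
#' Families containing at least one member from every genome.
#'
#' @param families List of gene-id vectors (from [buildGeneFamilies()] or
#'   [twoStageCluster()]).
#' @param gene_genome Named vector mapping gene id to genome id.
#' @param genome_ids Genome set that must be covered.
#' @return The subset of `families` present in all genomes.
#' @export
coreFamilies <- function(families, gene_genome, genome_ids) {
    Filter(function(f) all(genome_ids %in% gene_genome[f]), families)
}

#' Core genome after dropping taxa
#'
#' Re-runs RBH orthology, two-stage clustering and core selection on the
#' genomes that remain after excluding `excluded_taxa`; peripheral taxa
#' depress the core, so dropping them grows it.
#'
#' @inheritParams buildGeneFamilies
#' @param excluded_taxa Genome names to drop (strict subset).
#' @return List with `core_count`, `core_families` and the full `families`.
#' @export
taxonDropoutCore <- function(proteomes, excluded_taxa = character(0),
                             min_identity = 25, min_query_cov = 40,
                             scheme = proteinScheme(), word_size = 5,
                             min_shared_kmers = 2) {
    prot <- .proteomeList(proteomes)
    keep <- setdiff(names(prot), excluded_taxa)
    if (length(keep) < 2L) stop("exclusion must leave at least two genomes")
    bg <- buildGeneFamilies(prot[keep], min_identity, min_query_cov, scheme,
                            word_size, min_shared_kmers)
    core <- coreFamilies(bg$families, bg$gene_genome, keep)
    list(core_count = length(core), core_families = core,
         families = bg$families, gene_genome = bg$gene_genome)
}

## Spearman correlation with the documented ties policy: average ranks; a
## zero-variance vector yields rho = 0 (not NA) and p = 1.
.spearman <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(list(rho = 0, p = 1))
    rho <- cor(x, y, method = "spearman")
    n <- length(x)
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    list(rho = rho, p = p)
}

#' Contig-fragmentation sensitivity of pan and core curves
#'
#' For each fragmentation level, genomes with more contigs than the level
#' are removed and pan/core accumulation curves are recomputed on the
#' retained subset. Also reports the Spearman correlation between a
#' per-genome marker-family count and contig count (the check that draft
#' fragmentation does not depress marker recovery).
#'
#' @inheritParams accumulatePanFamilies
#' @param contig_counts Named integer vector: contigs per genome.
#' @param levels Fragmentation levels (maximum admissible contig count).
#' @param marker_counts Optional named vector of per-genome marker-family
#'   counts; defaults to the per-genome count of families recovered for all
#'   genomes minus one (near-core markers), computed from the full-set
#'   accumulation.
#' @return List with `levels` (per level: retained genomes and curves, or
#'   `NULL` when fewer than two genomes remain) and `marker_spearman`
#'   (`rho`, `p`).
#' @export
fragmentationSensitivity <- function(proteomes, contig_counts,
                                     levels = c(20, 50, 100, 200, 300, 400,
                                                500),
                                     min_identity = 25, min_query_cov = 40,
                                     seed = 1L, n_perm = 5L,
                                     scheme = proteinScheme(),
                                     word_size = 5, min_shared_kmers = 2,
                                     marker_counts = NULL) {
    prot <- .proteomeList(proteomes)
    stopifnot(all(names(prot) %in% names(contig_counts)))
    full <- accumulatePanFamilies(prot, min_identity = min_identity,
                                  min_query_cov = min_query_cov, seed = seed,
                                  n_perm = n_perm, scheme = scheme,
                                  word_size = word_size,
                                  min_shared_kmers = min_shared_kmers)
    if (is.null(marker_counts)) {
        pres <- familyPresence(full)
        wide <- pres[rowSums(pres) >= ncol(pres) - 1L, , drop = FALSE]
        marker_counts <- colSums(wide)
    }
    out <- list()
    for (lv in levels) {
        retained <- names(prot)[contig_counts[names(prot)] <= lv]
        if (length(retained) < 2L) {
            out[[as.character(lv)]] <- list(retained = retained,
                                            pan_curve = NULL,
                                            core_curve = NULL)
            next
        }
        pr <- accumulatePanFamilies(prot[retained],
                                    min_identity = min_identity,
                                    min_query_cov = min_query_cov,
                                    seed = seed, n_perm = n_perm,
                                    scheme = scheme, word_size = word_size,
                                    min_shared_kmers = min_shared_kmers)
        out[[as.character(lv)]] <- list(retained = retained,
                                        pan_curve = panCurve(pr),
                                        core_curve = coreCurve(pr))
    }
    cc <- contig_counts[names(marker_counts)]
    list(levels = out,
         marker_spearman = .spearman(as.numeric(marker_counts),
                                     as.numeric(cc)),
         marker_counts = marker_counts, full = full)
}
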