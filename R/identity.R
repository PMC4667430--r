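## Fragment-based average nucleotide identity (ANI) and total nucleotide
## identity (TNI). The fragment parameters follow the classic fragment-ANI
## protocol: the query genome is chopped into consecutive 1020-nt pieces,
## each is locally aligned against the whole subject genome on both strands,
## and only fragments aligning at >= 30% identity over >= 70% of their length
## are kept. ANI averages the kept fragment identities (reciprocal mean of
## the two directions); TNI counts identically aligned nucleotides against
## the summed genome lengths, penalising low alignable fraction.

#' Configuration for fragment-based identity
#'
#' @param fragment_len Fragment length in nt.
#' @param min_fragment_identity Minimum percent identity for a fragment to be
#'   kept.
#' @param min_fragment_alignable Minimum aligned span as percent of the
#'   fragment length.
#' @param min_tail_fragment Trailing fragments shorter than this are
#'   discarded (identity on tiny fragments is unstable).
#' @return A named list used by [ani()], [tni()] and
#'   [pairwiseIdentityMatrix()].
#' @export
aniConfig <- function(fragment_len = 1020L, min_fragment_identity = 30,
                      min_fragment_alignable = 70, min_tail_fragment = 100L) {
    stopifnot(fragment_len > min_tail_fragment, min_tail_fragment > 0)
    list(fragment_len = as.integer(fragment_len),
         min_fragment_identity = min_fragment_identity,
         min_fragment_alignable = min_fragment_alignable,
         min_tail_fragment = as.integer(min_tail_fragment))
}

.chopFragments <- function(s, config) {
    L <- nchar(s)
    starts <- seq.int(1L, L, by = config$fragment_len)
    ends <- pmin(starts + config$fragment_len - 1L, L)
    keep <- (ends - starts + 1L) >= config$min_tail_fragment
    Biostrings::DNAStringSet(substring(s, starts[keep], ends[keep]))
}

## one direction: fragments of a against whole genome b, both strands;
## returns per-kept-fragment identity and match counts
.aniDirectional <- function(a, b, config, scheme) {
    frags <- .chopFragments(a, config)
    nf <- length(frags)
    if (nf == 0L) return(list(identity = numeric(0), matches = numeric(0)))
    pats <- c(frags, Biostrings::reverseComplement(frags))
    mat <- .substitutionMatrix(scheme)
    pa <- Biostrings::pairwiseAlignment(
        pats, Biostrings::DNAString(b), type = "local",
        substitutionMatrix = mat, gapOpening = scheme@gap_open,
        gapExtension = scheme@gap_extend)
    sc <- Biostrings::score(pa)
    use <- ifelse(sc[seq_len(nf)] >= sc[nf + seq_len(nf)],
                  seq_len(nf), nf + seq_len(nf))
    idn <- 100 * Biostrings::nmatch(pa) / Biostrings::nchar(pa)
    span <- IRanges::width(IRanges::ranges(Biostrings::pattern(pa)))
    flen <- Biostrings::width(pats)
    alignable <- 100 * span / flen
    sel <- use[idn[use] >= config$min_fragment_identity &
               alignable[use] >= config$min_fragment_alignable &
               sc[use] > 0]
    list(identity = idn[sel], matches = Biostrings::nmatch(pa)[sel])
}

.asDnaChar <- function(x) {
    if (is(x, "GenomeRecord")) x <- genomeSequence(x)
    toupper(as.character(x))
}

#' Average nucleotide identity between two genomes
#'
#' Chops each genome into consecutive fragments, aligns every fragment
#' locally against the other genome (both strands, better one kept), retains
#' fragments passing the identity/alignable-fraction filters, and averages
#' the kept fragment identities; the reported value is the mean of the two
#' directions. When no fragment passes in either direction the value is
#' undefined and returned as `NA` (never 0).
#'
#' @param genome_a,genome_b Character/`DNAString` genome sequences or
#'   [GenomeRecord-class]s (contigs are concatenated).
#' @param config From [aniConfig()].
#' @param scheme Nucleotide [ScoringScheme-class].
#' @return ANI in percent, or `NA_real_`.
#' @export
ani <- function(genome_a, genome_b, config = aniConfig(),
                scheme = nucleotideScheme()) {
    a <- .asDnaChar(genome_a); b <- .asDnaChar(genome_b)
    if (nchar(a) < 2L * config$fragment_len ||
        nchar(b) < 2L * config$fragment_len)
        stop("genomes must be at least twice the fragment length")
    ab <- .aniDirectional(a, b, config, scheme)
    ba <- .aniDirectional(b, a, config, scheme)
    dir_means <- c(if (length(ab$identity)) mean(ab$identity),
                   if (length(ba$identity)) mean(ba$identity))
    if (is.null(dir_means)) return(NA_real_)
    mean(dir_means)
}

#' Total nucleotide identity between two genomes
#'
#' `TNI = 2 M / (L_a + L_b)` where `M` is the number of identically aligned
#' nucleotides summed over kept fragment alignments (averaged over the two
#' directions, making the value symmetric) and `L` are the genome lengths.
#' Unlike ANI, a pair with no passing fragments scores 0 (`M = 0`), and a
#' pair in which only part of the genomes aligns is penalised by the
#' unaligned remainder: `TNI <= 2 min(L_a, L_b) / (L_a + L_b)`.
#'
#' @inheritParams ani
#' @return TNI as a fraction in `[0, 1]`.
#' @export
tni <- function(genome_a, genome_b, config = aniConfig(),
                scheme = nucleotideScheme()) {
    a <- .asDnaChar(genome_a); b <- .asDnaChar(genome_b)
    if (nchar(a) < 2L * config$fragment_len ||
        nchar(b) < 2L * config$fragment_len)
        stop("genomes must be at least twice the fragment length")
    ab <- .aniDirectional(a, b, config, scheme)
    ba <- .aniDirectional(b, a, config, scheme)
    m <- (sum(ab$matches) + sum(ba$matches)) / 2
    2 * m / (nchar(a) + nchar(b))
}

#' Pairwise ANI or TNI matrix
#'
#' @param genomes Named list of genome sequences or [GenomeRecord-class]s.
#' @param metric `"ANI"` (percent) or `"TNI"` (fraction).
#' @inheritParams ani
#' @return An [IdentityMatrix-class].
#' @export
pairwiseIdentityMatrix <- function(genomes, metric = c("ANI", "TNI"),
                                   config = aniConfig(),
                                   scheme = nucleotideScheme()) {
    metric <- match.arg(metric)
    if (length(genomes) < 2L) stop("need at least two genomes")
    nm <- names(genomes)
    if (is.null(nm)) stop("genomes must be named")
    n <- length(genomes)
    v <- matrix(if (metric == "ANI") 100 else 1, n, n,
                dimnames = list(nm, nm))
    fun <- if (metric == "ANI") ani else tni
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        val <- fun(genomes[[i]], genomes[[j]], config, scheme)
        v[i, j] <- v[j, i] <- val
    }
    new("IdentityMatrix", taxa = nm, values = v, metric = metric)
}

#' Summary statistics of an identity matrix
#'
#' Mean, min and max over the off-diagonal entries, optionally restricted to
#' a labelled taxon subset (e.g. one genus).
#'
#' @param x An [IdentityMatrix-class].
#' @param subset Optional character vector of taxa.
#' @return Named list (`mean`, `min`, `max`, `n_pairs`).
#' @export
identitySummary <- function(x, subset = NULL) {
    v <- idValues(x)
    if (!is.null(subset)) v <- v[subset, subset, drop = FALSE]
    off <- v[upper.tri(v)]
    list(mean = mean(off, na.rm = TRUE), min = suppressWarnings(
             min(off, na.rm = TRUE)),
         max = suppressWarnings(max(off, na.rm = TRUE)),
         n_pairs = sum(!is.na(off)))
}

## ---------------------------------------------------------------------------
## Per-taxonomic-rank distributions
## ---------------------------------------------------------------------------

.RANKS <- c("species", "genus", "family", "order", "class")

#' Identity distributions per shared taxonomic rank
#'
#' Each off-diagonal pair is assigned to the lowest rank shared by the two
#' taxa (conspecific pairs to `species`, congeneric-but-not-conspecific pairs
#' to `genus`, ...); pairs sharing no listed rank fall into the most distant
#' bucket, `class`. Values are histogrammed per rank on shared bin edges over
#' the global observed range (100 bins by default), so intersection areas
#' between rank curves are well defined, and the pairwise overlap matrix of
#' the rank curves is reported.
#'
#' @param x An [IdentityMatrix-class].
#' @param taxonomy data.frame with columns `taxon`, `species`, `genus`,
#'   `family`, `order`, `class` covering all taxa of `x`.
#' @param bins Number of shared histogram bins.
#' @return List with `distributions` (per rank: `bin_edges`, `density`
#'   normalised so that sum(density * width) = 1, `n_pairs`, `values`) and
#'   `overlap` (rank x rank intersection-area matrix).
#' @export
rankDistributions <- function(x, taxonomy, bins = 100L) {
    stopifnot(all(c("taxon", .RANKS) %in% names(taxonomy)))
    taxa <- idTaxa(x)
    if (!all(taxa %in% taxonomy$taxon))
        stop("taxonomy must cover every taxon: missing ",
             paste(setdiff(taxa, taxonomy$taxon), collapse = ", "))
    tax <- taxonomy[match(taxa, taxonomy$taxon), , drop = FALSE]
    if (anyNA(tax[, .RANKS]))
        stop("every taxon needs a full rank path")
    v <- idValues(x)
    prs <- which(upper.tri(v), arr.ind = TRUE)
    vals <- v[prs]
    rank_of <- vapply(seq_len(nrow(prs)), function(k) {
        i <- prs[k, 1]; j <- prs[k, 2]
        shared <- .RANKS[tax[i, .RANKS] == tax[j, .RANKS]]
        if (length(shared)) shared[1] else "class"
    }, character(1))
    ok <- !is.na(vals)
    vals <- vals[ok]; rank_of <- rank_of[ok]
    if (!length(vals)) stop("no defined pair values")
    rng <- range(vals)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    width <- diff(edges)[1]
    dists <- list()
    for (r in .RANKS) {
        rv <- vals[rank_of == r]
        if (!length(rv)) next
        h <- .binDensity(rv, edges)
        dists[[r]] <- list(rank = r, bin_edges = edges, density = h,
                           n_pairs = length(rv), values = rv)
    }
    rr <- names(dists)
    ov <- matrix(NA_real_, length(rr), length(rr), dimnames = list(rr, rr))
    for (i in seq_along(rr)) for (j in seq_along(rr))
        ov[i, j] <- sum(pmin(dists[[i]]$density, dists[[j]]$density)) * width
    list(distributions = dists, overlap = ov)
}

## histogram density on fixed edges, normalised to integrate to 1
.binDensity <- function(values, edges) {
    cnt <- tabulate(findInterval(values, edges, rightmost.closed = TRUE,
                                 all.inside = TRUE),
                    nbins = length(edges) - 1L)
    cnt / (sum(cnt) * diff(edges)[1])
}
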