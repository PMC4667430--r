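## Pairwise local alignment and identity/coverage metrics.
##
## A deterministic Smith-Waterman stage (Biostrings engine) replaces the
## BLAST searches used in large-scale practice; e-values are deliberately not
## computed (they depend on database size) and all downstream decisions use
## identity + coverage thresholds, which is what the clustering stages key on.

#' Default protein scoring scheme (BLOSUM62, gap 11/1)
#'
#' @param matrix_name Substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM50"`).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`. Set `gap_open = 0` for linear gaps.
#' @return A [ScoringScheme-class].
#' @examples
#' proteinScheme()
#' @export
proteinScheme <- function(matrix_name = "BLOSUM62", gap_open = 11,
                          gap_extend = 1) {
    new("ScoringScheme", alphabet = "protein", matrix_name = matrix_name,
        match = 0, mismatch = 0, gap_open = gap_open, gap_extend = gap_extend)
}

#' Default nucleotide scoring scheme (match +1 / mismatch -1, gap 5/2)
#'
#' @param match,mismatch Match reward and mismatch penalty (mismatch given as
#'   a positive number).
#' @param gap_open,gap_extend Affine gap penalties.
#' @return A [ScoringScheme-class].
#' @export
nucleotideScheme <- function(match = 1, mismatch = 1, gap_open = 5,
                             gap_extend = 2) {
    new("ScoringScheme", alphabet = "nucleotide", matrix_name = "",
        match = match, mismatch = -abs(mismatch),
        gap_open = gap_open, gap_extend = gap_extend)
}

.matrixCache <- new.env(parent = emptyenv())

.substitutionMatrix <- function(scheme) {
    if (scheme@alphabet == "protein") {
        nm <- scheme@matrix_name
        if (is.null(.matrixCache[[nm]])) {
            e <- new.env()
            utils::data(list = nm, package = "Biostrings", envir = e)
            .matrixCache[[nm]] <- get(nm, envir = e)
        }
        .matrixCache[[nm]]
    } else {
        mat <- Biostrings::nucleotideSubstitutionMatrix(
            match = scheme@match, mismatch = scheme@mismatch, baseOnly = FALSE)
        mat
    }
}

.checkAlphabet <- function(seq, scheme) {
    s <- toupper(as.character(seq))
    ok <- if (scheme@alphabet == "nucleotide")
        grepl("^[ACGTRYSWKMBDHVN]*$", s) else
        grepl("^[ARNDCQEGHILKMFPSTWYVXBZ]*$", s)
    if (!all(ok))
        stop("sequence contains characters outside the ", scheme@alphabet,
             " alphabet")
    s
}

## vectorised hit table from a PairwiseAlignments object
.hitRows <- function(pa, qids, sids, qlens, slens, strand = "+") {
    aln_len <- Biostrings::nchar(pa)
    nm <- Biostrings::nmatch(pa)
    pw <- IRanges::width(IRanges::ranges(Biostrings::pattern(pa)))
    sw <- IRanges::width(IRanges::ranges(Biostrings::subject(pa)))
    data.frame(
        query_id = qids, subject_id = sids,
        identity_pct = 100 * nm / aln_len,
        aln_len = aln_len,
        query_cov_pct = 100 * pw / qlens,
        subject_cov_pct = 100 * sw / slens,
        score = Biostrings::score(pa),
        strand = strand,
        stringsAsFactors = FALSE)
}

.hitRow <- function(pa, i, qid, sid, qlen, slen, strand = "+")
    .hitRows(pa[i], qid, sid, qlen, slen, strand)

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment with affine gaps under `scheme`. For
#' nucleotide schemes both strands of `b` are tried and the better-scoring
#' orientation is kept (recorded in `strand`). Returns `NULL` when the optimal
#' local score is not positive (no local similarity).
#'
#' @param a,b Character strings, `AAString`/`DNAString` or length-1 StringSets.
#' @param scheme A [ScoringScheme-class]; defaults to [proteinScheme()].
#' @param query_id,subject_id Labels copied into the hit row.
#' @return A one-row data.frame with columns `query_id`, `subject_id`,
#'   `identity_pct` (matches / alignment columns x 100), `aln_len`,
#'   `query_cov_pct`, `subject_cov_pct` (aligned span / sequence length x
#'   100), `score` and `strand`; or `NULL`.
#' @examples
#' localAlign("ACGT", "ACGT", nucleotideScheme())
#' @export
localAlign <- function(a, b, scheme = proteinScheme(),
                       query_id = "query", subject_id = "subject") {
    a <- .checkAlphabet(a, scheme); b <- .checkAlphabet(b, scheme)
    if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
    mat <- .substitutionMatrix(scheme)
    cls <- if (scheme@alphabet == "protein") Biostrings::AAString else
        Biostrings::DNAString
    pa <- Biostrings::pairwiseAlignment(
        cls(a), cls(b), type = "local", substitutionMatrix = mat,
        gapOpening = scheme@gap_open, gapExtension = scheme@gap_extend)
    strand <- "+"
    if (scheme@alphabet == "nucleotide") {
        pa_rc <- Biostrings::pairwiseAlignment(
            Biostrings::reverseComplement(Biostrings::DNAString(a)),
            Biostrings::DNAString(b), type = "local",
            substitutionMatrix = mat, gapOpening = scheme@gap_open,
            gapExtension = scheme@gap_extend)
        if (Biostrings::score(pa_rc) > Biostrings::score(pa)) {
            pa <- pa_rc; strand <- "-"
        }
    }
    if (Biostrings::score(pa) <= 0) return(NULL)
    .hitRow(pa, 1L, query_id, subject_id, nchar(a), nchar(b), strand)
}

#' Identity/coverage threshold filter
#'
#' TRUE iff `identity_pct >= min_identity` and `query_cov_pct >=
#' min_query_cov`, both inclusive -- the reading of "25% identity over 40% of
#' the gene length" used throughout the clustering stages.
#'
#' @param hit A hit row as returned by [localAlign()] (or any data.frame with
#'   `identity_pct` and `query_cov_pct`).
#' @param min_identity,min_query_cov Thresholds in percent.
#' @return Logical vector, one per hit row.
#' @export
passesThresholds <- function(hit, min_identity = 25, min_query_cov = 40) {
    if (is.null(hit) || nrow(hit) == 0L) return(logical(0))
    hit$identity_pct >= min_identity & hit$query_cov_pct >= min_query_cov
}

## --------------------------------------------------------------------------
## k-mer seeding prefilter (word seeding, as BLAST-style search engines do):
## candidate pairs must share at least `min_shared_kmers` words of length
## `word_size`. min_shared_kmers = 0 disables the filter (exact mode).
## --------------------------------------------------------------------------

.kmerIndicator <- function(seqs, word_size) {
    ## sparse 0/1 matrix: sequence x distinct k-mer (global dictionary by hash)
    seqs <- as.character(seqs)
    kml <- lapply(seqs, function(s) {
        n <- nchar(s)
        if (n < word_size) return(character(0))
        unique(substring(s, 1:(n - word_size + 1), word_size:n))
    })
    dict <- unique(unlist(kml, use.names = FALSE))
    if (length(dict) == 0L)
        return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                    dims = c(length(seqs), 0L)))
    i <- rep.int(seq_along(kml), lengths(kml))
    j <- match(unlist(kml, use.names = FALSE), dict)
    Matrix::sparseMatrix(i = i, j = j, x = 1,
                         dims = c(length(seqs), length(dict)),
                         dimnames = list(names(seqs), dict))
}

.sharedKmerCounts <- function(qseqs, sseqs, word_size) {
    all <- c(as.character(qseqs), as.character(sseqs))
    M <- .kmerIndicator(all, word_size)
    nq <- length(qseqs)
    Q <- M[seq_len(nq), , drop = FALSE]
    S <- M[nq + seq_len(length(sseqs)), , drop = FALSE]
    as.matrix(Q %*% Matrix::t(S))
}

#' All-vs-all passing hits between two protein sets
#'
#' Computes, for every query/subject pair that survives the k-mer seeding
#' prefilter, the optimal local alignment, and returns the rows passing the
#' identity/coverage thresholds. The alignment score matrix is symmetric for
#' symmetric substitution matrices, so for reciprocal analyses the table can
#' be reused in both directions by swapping the coverage columns.
#'
#' @param query_set,subject_set Named `AAStringSet` (or named character
#'   vectors) of proteins.
#' @param scheme A protein [ScoringScheme-class].
#' @param min_identity,min_query_cov Thresholds applied to each hit
#'   (query coverage is relative to the query).
#' @param word_size,min_shared_kmers Seeding prefilter; pairs sharing fewer
#'   than `min_shared_kmers` distinct words are skipped without alignment.
#'   `min_shared_kmers = 0` aligns every pair.
#' @param exclude_self Drop pairs with identical query and subject names.
#' @return data.frame of passing hit rows (possibly empty).
#' @export
allPairsHits <- function(query_set, subject_set, scheme = proteinScheme(),
                         min_identity = 25, min_query_cov = 40,
                         word_size = 5, min_shared_kmers = 2,
                         exclude_self = FALSE) {
    qs <- Biostrings::AAStringSet(query_set)
    ss <- Biostrings::AAStringSet(subject_set)
    if (length(qs) == 0L || length(ss) == 0L)
        stop("query and subject sets must be non-empty")
    if (is.null(names(qs)) || is.null(names(ss)))
        stop("sequence sets must be named")
    cand <- if (min_shared_kmers > 0)
        .sharedKmerCounts(qs, ss, word_size) >= min_shared_kmers
    else matrix(TRUE, length(qs), length(ss))
    idx <- which(cand, arr.ind = TRUE)
    if (exclude_self && nrow(idx))
        idx <- idx[names(qs)[idx[, 1]] != names(ss)[idx[, 2]], ,
                   drop = FALSE]
    empty <- data.frame(query_id = character(0), subject_id = character(0),
                        identity_pct = numeric(0), aln_len = integer(0),
                        query_cov_pct = numeric(0),
                        subject_cov_pct = numeric(0), score = numeric(0),
                        strand = character(0), stringsAsFactors = FALSE)
    if (nrow(idx) == 0L) return(empty)
    mat <- .substitutionMatrix(scheme)
    qi <- idx[, 1]; sj <- idx[, 2]
    pa <- Biostrings::pairwiseAlignment(
        qs[qi], ss[sj], type = "local", substitutionMatrix = mat,
        gapOpening = scheme@gap_open, gapExtension = scheme@gap_extend)
    hits <- .hitRows(pa, names(qs)[qi], names(ss)[sj],
                     Biostrings::width(qs)[qi], Biostrings::width(ss)[sj])
    hits <- hits[hits$score > 0, , drop = FALSE]
    hits <- hits[passesThresholds(hits, min_identity, min_query_cov), ,
                 drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Best passing hit per query
#'
#' For each query, its highest-scoring passing subject hit; ties broken by
#' higher identity, then lexicographically smaller subject id.
#'
#' @inheritParams allPairsHits
#' @return data.frame with at most one row per query.
#' @export
bestHits <- function(query_set, subject_set, scheme = proteinScheme(),
                     min_identity = 25, min_query_cov = 40,
                     word_size = 5, min_shared_kmers = 2,
                     exclude_self = FALSE) {
    hits <- allPairsHits(query_set, subject_set, scheme,
                         min_identity, min_query_cov,
                         word_size, min_shared_kmers, exclude_self)
    selectBestHits(hits)
}

#' Reduce a hit table to the best hit per query
#'
#' @param hits A hit table with at least `query_id`, `subject_id`,
#'   `score`, `identity_pct`.
#' @return One row per query, using the documented tie-break
#'   (score desc, identity desc, subject_id asc).
#' @export
selectBestHits <- function(hits) {
    if (nrow(hits) == 0L) return(hits)
    o <- order(hits$query_id, -hits$score, -hits$identity_pct,
               hits$subject_id)
    hits <- hits[o, , drop = FALSE]
    hits[!duplicated(hits$query_id), , drop = FALSE]
}
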