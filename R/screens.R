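## Feature screens: contig-spacer handling and partial-gene status,
## cell-envelope protease (CEP) classification, plasmid contig assignment,
## CAZyme hit reconciliation, glycolysis presence matrix, and niche
## association testing.

#' The 36-nt six-frame start/stop contig spacer
#'
#' Inserted between contigs before gene prediction so that genes running
#' into a contig boundary are emitted with a recognisable artificial end.
#' The spacer contains stop codons in all six frames between its N-blocks
#' and is its own reverse complement.
#'
#' @return Character string of length 36.
#' @export
contigSpacer <- function() "NNNNNCACACACTTAATTAATTAAGTGTGTGNNNNN"

#' Artificial end motifs marking truncated genes
#'
#' `end3` is the motif found at the 3' end of a gene truncated at a contig
#' boundary; `end5` (its reverse complement) marks a truncated 5' end on the
#' coding strand.
#'
#' @return Named character vector with elements `end3` and `end5`.
#' @export
artificialEnds <- function() {
    end3 <- "NNNNNCACACACTTAA"
    c(end3 = end3,
      end5 = as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(end3))))
}

#' Join contigs with the six-frame spacer
#'
#' @param contigs Character vector (or `DNAStringSet`) of contigs, all
#'   non-empty.
#' @return List with `sequence` (the pseudo-molecule) and `offsets`
#'   (data.frame `contig`, `start`, `end`, 0-based half-open positions of
#'   each contig in the pseudo-molecule), allowing exact inversion via
#'   [removeContigSpacers()].
#' @examples
#' insertContigSpacers(c("ACGT", "GGCC"))$sequence
#' @export
insertContigSpacers <- function(contigs) {
    contigs <- as.character(contigs)
    if (length(contigs) < 1L || any(!nzchar(contigs)))
        stop("need at least one non-empty contig")
    sp <- contigSpacer()
    seqs <- character(2L * length(contigs) - 1L)
    seqs[seq(1L, length(seqs), by = 2L)] <- contigs
    if (length(contigs) > 1L) seqs[seq(2L, length(seqs), by = 2L)] <- sp
    pseudo <- paste(seqs, collapse = "")
    lens <- nchar(contigs)
    starts <- cumsum(c(0L, head(lens, -1L) + nchar(sp)))
    list(sequence = pseudo,
         offsets = data.frame(
             contig = if (is.null(names(contigs)))
                 sprintf("ctg%03d", seq_along(contigs)) else names(contigs),
             start = starts, end = starts + lens, stringsAsFactors = FALSE))
}

#' Recover contigs from a spacered pseudo-molecule
#'
#' Exact inverse of [insertContigSpacers()] given its offset map.
#'
#' @param pseudo Character pseudo-molecule.
#' @param offsets Offset map as returned by [insertContigSpacers()].
#' @return Character vector of contigs (named per the offset map).
#' @export
removeContigSpacers <- function(pseudo, offsets) {
    setNames(substring(pseudo, offsets$start + 1L, offsets$end),
             offsets$contig)
}

#' Partial-gene status from artificial ends
#'
#' A gene predicted over the spacered pseudo-molecule that runs into a
#' contig boundary carries the artificial end motif: at its 3' end the
#' spacer prefix (`NNNNNCACACACTTAA`), at its 5' end the reverse complement.
#' Both motifs are checked on the coding strand.
#'
#' @param gene_seqs Character vector of gene sequences (coding strand).
#' @return Character vector: `complete`, `missing5`, `missing3` or
#'   `missing_both`.
#' @export
classifyPartialGenes <- function(gene_seqs) {
    ends <- artificialEnds()
    m5 <- startsWith(gene_seqs, ends[["end5"]])
    m3 <- endsWith(gene_seqs, ends[["end3"]])
    status <- rep("complete", length(gene_seqs))
    status[m5 & !m3] <- "missing5"
    status[!m5 & m3] <- "missing3"
    status[m5 & m3] <- "missing_both"
    status
}

## ---------------------------------------------------------------------------
## CEP classification
## ---------------------------------------------------------------------------

.DOMAIN_ALIASES <- c(PA = "PA", Fn1 = "Fn1", DUF1034 = "Fn1",
                     Fn2 = "Fn2", CHU_C = "Fn2", SLAP = "SLAP")
.SUBTILASE_LABELS <- c("Peptidase_S8", "Subtilase", "subtilase")

#' Classify a cell-envelope protease candidate
#'
#' A candidate (already captured by similarity or HMM search; the hit table
#' is supplied) is accepted only if a subtilase-domain span is present and
#' the catalytic triad is detectable within it in the order Asp, His, Ser.
#' Triad positions come from the packaged reference motif windows around the
#' three catalytic residues. The cell-wall anchor is then assigned by
#' precedence: `truncated` (gene carries an artificial 3' end at a contig
#' boundary) > canonical `LPXTG` motif within the C-terminal window >
#' derivative motif (`[LIVFM]-P-x-[TSA]-[GSNDA]`, excluding canonical
#' matches) > `SLAP` domain present > `none`.
#'
#' @param protein Character or `AAString` protein sequence.
#' @param domain_hits data.frame with columns `domain`, `start`, `end`
#'   (1-based inclusive, amino acids); recognised labels: `Peptidase_S8` /
#'   `Subtilase`, `PA`, `Fn1`/`DUF1034`, `Fn2`/`CHU_C`, `SLAP`.
#' @param c_terminal_window Anchor search window in aa from the C-terminus.
#' @param partial_status The gene's partial status (`missing3` or
#'   `missing_both` mark a contig-boundary truncation).
#' @param length_range Plausible protein length range in aa; candidates
#'   outside it are rejected.
#' @param protein_id Identifier for the returned record.
#' @return A list record (`protein_id`, `length`, `triad` with D/H/S
#'   positions, `domains`, `anchor`) or `NULL` when the candidate is
#'   rejected.
#' @export
classifyCEP <- function(protein, domain_hits, c_terminal_window = 60L,
                        partial_status = "complete",
                        length_range = c(800L, 2600L),
                        protein_id = "cep") {
    x <- toupper(as.character(protein))
    L <- nchar(x)
    if (nrow(domain_hits) &&
        any(domain_hits$end > L | domain_hits$start < 1L))
        stop("domain span outside protein length")
    if (L < length_range[1] || L > length_range[2]) return(NULL)
    sub_rows <- domain_hits[domain_hits$domain %in% .SUBTILASE_LABELS, ,
                            drop = FALSE]
    if (nrow(sub_rows) == 0L) return(NULL)
    span <- c(min(sub_rows$start), max(sub_rows$end))
    region <- substr(x, span[1], span[2])
    findMotif <- function(region, key, from) {
        m <- regexpr(.TRIAD_MOTIFS[[key]]$motif,
                     substr(region, from, nchar(region)), fixed = TRUE)
        if (m == -1L) return(NA_integer_)
        from + as.integer(m) - 1L + .TRIAD_MOTIFS[[key]]$offset
    }
    dpos <- findMotif(region, "D", 1L)
    if (is.na(dpos)) return(NULL)
    hpos <- findMotif(region, "H", dpos + 1L)
    if (is.na(hpos)) return(NULL)
    spos <- findMotif(region, "S", hpos + 1L)
    if (is.na(spos)) return(NULL)
    triad <- span[1] - 1L + c(D = dpos, H = hpos, S = spos)

    doms <- sort(unique(unname(
        .DOMAIN_ALIASES[domain_hits$domain[domain_hits$domain %in%
                                           names(.DOMAIN_ALIASES)]])))
    window <- substr(x, max(1L, L - c_terminal_window + 1L), L)
    has_canon <- grepl(.CANONICAL_LPXTG, window)
    has_deriv <- FALSE
    if (!has_canon) {
        m <- gregexpr(.DERIVATIVE_LPXTG, window)[[1]]
        if (m[1] != -1L) {
            hits <- regmatches(window, gregexpr(.DERIVATIVE_LPXTG, window))[[1]]
            has_deriv <- any(!grepl(.CANONICAL_LPXTG, hits))
        }
    }
    anchor <- if (partial_status %in% c("missing3", "missing_both"))
        "truncated"
    else if (has_canon) "LPXTG"
    else if (has_deriv) "LPXTG_derivative"
    else if ("SLAP" %in% doms) "SLAP"
    else "none"
    list(protein_id = protein_id, length = L, triad = triad,
         domains = doms, anchor = anchor)
}

## ---------------------------------------------------------------------------
## Plasmid contig assignment
## ---------------------------------------------------------------------------

#' Assign contig groups to reference plasmids
#'
#' For each plasmid, the group of contigs with hits to it is assigned iff
#' (i) the summed aligned contig length is at least 25% of the summed length
#' of those contigs, (ii) the covered plasmid length is at least 25% of the
#' plasmid length, and (iii) the alignment-length-weighted mean identity is
#' at least 70%. All three inequalities are inclusive.
#'
#' @param hits data.frame with columns `contig_id`, `plasmid_id`,
#'   `contig_aligned_len`, `plasmid_covered_len`, `identity`.
#' @param contig_lengths,plasmid_lengths Named vectors (nt); every molecule
#'   referenced by `hits` must be present with positive length.
#' @param min_contig_frac,min_plasmid_frac,min_identity The three
#'   thresholds.
#' @return data.frame per plasmid: `plasmid_id`, `contigs`
#'   (comma-separated), `contig_frac`, `plasmid_frac`, `mean_identity`,
#'   `assigned`.
#' @export
assignPlasmidContigs <- function(hits, contig_lengths, plasmid_lengths,
                                 min_contig_frac = 0.25,
                                 min_plasmid_frac = 0.25,
                                 min_identity = 70) {
    need <- c("contig_id", "plasmid_id", "contig_aligned_len",
              "plasmid_covered_len", "identity")
    stopifnot(all(need %in% names(hits)))
    mols <- c(contig_lengths[unique(hits$contig_id)],
              plasmid_lengths[unique(hits$plasmid_id)])
    if (anyNA(mols) || any(mols <= 0))
        stop("all referenced molecules need a positive length")
    out <- lapply(split(hits, hits$plasmid_id), function(h) {
        ctgs <- unique(h$contig_id)
        contig_frac <- sum(h$contig_aligned_len) /
            sum(contig_lengths[ctgs])
        plasmid_frac <- sum(h$plasmid_covered_len) /
            plasmid_lengths[[h$plasmid_id[1]]]
        mean_id <- sum(h$identity * h$contig_aligned_len) /
            sum(h$contig_aligned_len)
        data.frame(plasmid_id = h$plasmid_id[1],
                   contigs = paste(sort(ctgs), collapse = ","),
                   contig_frac = contig_frac, plasmid_frac = plasmid_frac,
                   mean_identity = mean_id,
                   assigned = contig_frac >= min_contig_frac &
                       plasmid_frac >= min_plasmid_frac &
                       mean_id >= min_identity,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$plasmid_id), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## CAZyme reconciliation
## ---------------------------------------------------------------------------

#' Reconcile CAZyme calls from HMM and similarity searches
#'
#' Two-source reconciliation: gene-family calls supported by both the HMM
#' scan and the similarity (BLAST-style) search are retained; calls unique
#' to one source are retained only when a profile-database check confirmed
#' the GH/GT domain (`pfam_confirmed`). A common gene carrying conflicting
#' family labels keeps both, flagged. Thresholds are applied internally to
#' raw tables: HMM e-value < 1e-5; similarity identity >= 40%, coverage >=
#' 50%, e-value < 1e-5.
#'
#' @param hmm_hits data.frame `gene_id`, `family`, `evalue`, optional
#'   `pfam_confirmed`.
#' @param blast_hits data.frame `gene_id`, `family`, `evalue`, `identity`,
#'   `coverage`, optional `pfam_confirmed`.
#' @param gene_genome Named vector gene -> genome (for the copy-number
#'   matrix).
#' @param max_evalue,min_identity,min_coverage Filtering thresholds.
#' @return List with `calls` (data.frame `gene_id`, `family`, `support`,
#'   `conflict`) and `copy_number` (genome x family matrix counting retained
#'   gene-family calls).
#' @export
reconcileCazymeHits <- function(hmm_hits, blast_hits, gene_genome,
                                max_evalue = 1e-5, min_identity = 40,
                                min_coverage = 50) {
    if (is.null(hmm_hits$pfam_confirmed)) hmm_hits$pfam_confirmed <- FALSE
    if (is.null(blast_hits$pfam_confirmed))
        blast_hits$pfam_confirmed <- FALSE
    stopifnot(grepl("^G[HT][0-9]+$", c(hmm_hits$family, blast_hits$family)))
    hmm <- hmm_hits[hmm_hits$evalue < max_evalue, , drop = FALSE]
    bl <- blast_hits[blast_hits$evalue < max_evalue &
                     blast_hits$identity >= min_identity &
                     blast_hits$coverage >= min_coverage, , drop = FALSE]
    hk <- unique(paste(hmm$gene_id, hmm$family))
    bk <- unique(paste(bl$gene_id, bl$family))
    key2df <- function(keys, support) {
        if (!length(keys)) return(NULL)
        parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
        data.frame(gene_id = parts[, 1], family = parts[, 2],
                   support = support, stringsAsFactors = FALSE)
    }
    common <- key2df(intersect(hk, bk), "both")
    conf_keys <- unique(c(
        paste(hmm$gene_id, hmm$family)[hmm$pfam_confirmed],
        paste(bl$gene_id, bl$family)[bl$pfam_confirmed]))
    only_h <- setdiff(hk, bk)
    only_b <- setdiff(bk, hk)
    uniq <- rbind(key2df(intersect(only_h, conf_keys), "hmm+pfam"),
                  key2df(intersect(only_b, conf_keys), "blast+pfam"))
    calls <- rbind(common, uniq)
    if (is.null(calls))
        calls <- data.frame(gene_id = character(0), family = character(0),
                            support = character(0), stringsAsFactors = FALSE)
    calls <- calls[order(calls$gene_id, calls$family), , drop = FALSE]
    ## common genes (supported by both sources) with >1 family are kept and
    ## flagged as conflicting
    nfam <- tapply(calls$family, calls$gene_id,
                   function(f) length(unique(f)))
    calls$conflict <- unname(nfam[calls$gene_id] > 1L)
    rownames(calls) <- NULL
    genomes <- sort(unique(gene_genome))
    fams <- sort(unique(calls$family))
    cn <- matrix(0L, length(genomes), length(fams),
                 dimnames = list(genomes, fams))
    if (nrow(calls)) {
        gg <- gene_genome[calls$gene_id]
        if (anyNA(gg)) stop("gene_genome must cover every called gene")
        tt <- table(gg, calls$family)
        cn[rownames(tt), colnames(tt)] <- as.integer(tt)
    }
    list(calls = calls, copy_number = cn)
}

## ---------------------------------------------------------------------------
## Glycolysis presence matrix
## ---------------------------------------------------------------------------

#' Presence/absence matrix of core glycolytic genes
#'
#' A gene is present in a genome if it is annotated there, or if a
#' confirmed homology hit exists. Phosphoglycerate mutase (`pgm`) follows
#' its dedicated rule: present iff any query hit has bit score strictly
#' greater than 100.
#'
#' @param annotations data.frame `genome_id`, `gene` (annotation evidence).
#' @param confirmed_hits data.frame `genome_id`, `gene` of
#'   alignment-confirmed homologue hits (may be empty).
#' @param pgm_hits data.frame `genome_id`, `bitscore` of phosphoglycerate
#'   mutase query hits (may be empty).
#' @param genomes Character vector of all genomes (rows).
#' @param genes Character vector of gene columns; `"pgm"` triggers the
#'   bit-score rule.
#' @return genome x gene 0/1 integer matrix.
#' @export
glycolysisMatrix <- function(annotations, confirmed_hits = NULL,
                             pgm_hits = NULL, genomes = NULL,
                             genes = c("glk", "pgi", "pfk", "fba", "tpi",
                                       "gap", "pgk", "pgm", "eno", "pyk")) {
    if (is.null(genomes))
        genomes <- sort(unique(c(annotations$genome_id,
                                 confirmed_hits$genome_id,
                                 pgm_hits$genome_id)))
    m <- matrix(0L, length(genomes), length(genes),
                dimnames = list(genomes, genes))
    mark <- function(m, df) {
        if (is.null(df) || nrow(df) == 0L) return(m)
        df <- df[df$genome_id %in% genomes & df$gene %in% genes, ,
                 drop = FALSE]
        m[cbind(df$genome_id, df$gene)] <- 1L
        m
    }
    m <- mark(m, annotations)
    m <- mark(m, confirmed_hits)
    if ("pgm" %in% genes && !is.null(pgm_hits) && nrow(pgm_hits)) {
        pg <- pgm_hits[pgm_hits$bitscore > 100, , drop = FALSE]  # strict
        hit <- intersect(unique(pg$genome_id), genomes)
        m[, "pgm"] <- 0L
        m[hit, "pgm"] <- 1L
    }
    m
}

## ---------------------------------------------------------------------------
## Niche association
## ---------------------------------------------------------------------------

#' Kruskal-Wallis niche association per feature
#'
#' Tests each feature column for differences across niche categories (food,
#' animal, plant, wine product, environment, unknown in the motivating data
#' set) with the tie-corrected Kruskal-Wallis H and its chi-squared
#' approximation. Niches with fewer than `min_group_size` genomes are
#' excluded with a warning. Constant features return H = 0, p = 1.
#'
#' @param feature_table Numeric matrix or data.frame, genomes x features.
#' @param niches Named character vector genome -> niche label.
#' @param min_group_size Minimum genomes a niche needs to enter the test.
#' @return data.frame (`feature`, `H`, `df`, `p_value`, `n_groups`, `n`).
#' @export
nicheAssociation <- function(feature_table, niches, min_group_size = 3L) {
    ft <- as.matrix(feature_table)
    genomes <- rownames(ft)
    if (is.null(genomes) || !all(genomes %in% names(niches)))
        stop("niches must be named and cover every genome row")
    grp <- niches[genomes]
    sizes <- table(grp)
    small <- names(sizes)[sizes < min_group_size]
    if (length(small)) {
        warning("excluding niche group(s) below minimum size: ",
                paste(small, collapse = ", "))
        keep <- !grp %in% small
        ft <- ft[keep, , drop = FALSE]
        grp <- grp[keep]
    }
    if (length(unique(grp)) < 2L)
        stop("need at least two niche groups after exclusion")
    grp <- factor(grp)
    res <- lapply(colnames(ft), function(f) {
        v <- ft[, f]
        if (length(unique(v)) == 1L) {
            return(data.frame(feature = f, H = 0, df = nlevels(grp) - 1L,
                              p_value = 1, n_groups = nlevels(grp),
                              n = length(v), stringsAsFactors = FALSE))
        }
        kt <- kruskal.test(v, grp)
        data.frame(feature = f, H = unname(kt$statistic),
                   df = unname(kt$parameter), p_value = kt$p.value,
                   n_groups = nlevels(grp), n = length(v),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}
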