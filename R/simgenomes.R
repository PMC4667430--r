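## Genome-evolution simulator: birth-death tree, fixed core + accessory gene
## families gained at most once and lost by a Poisson process, Jukes-Cantor
## nucleotide divergence with in-frame stop codons avoided, draft
## fragmentation at intergenic positions, and planted screen features.
## Everything downstream of the simulator can therefore be checked against
## known truth.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.DNA <- c("A", "C", "G", "T")
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

## run expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()),
                    add = TRUE)
        } else {
            on.exit(suppressWarnings(
                rm(".Random.seed", envir = globalenv())), add = TRUE)
        }
        set.seed(as.integer(seed))
    }
    force(expr)
}

.sampleBases <- function(n, gc) {
    sample(.DNA, n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## random coding sequence: ATG + (n_codons - 1) non-stop codons, no terminal
## stop (proteins are translated directly from the full frame)
.randomCodingSequence <- function(n_codons, gc) {
    bases <- .sampleBases(3L * (n_codons - 1L), gc)
    codons <- paste0(bases[c(TRUE, FALSE, FALSE)],
                     bases[c(FALSE, TRUE, FALSE)],
                     bases[c(FALSE, FALSE, TRUE)])
    bad <- which(codons %in% .STOP_CODONS)
    while (length(bad)) {
        for (i in bad) codons[i] <- paste(.sampleBases(3L, gc), collapse = "")
        bad <- bad[codons[bad] %in% .STOP_CODONS]
    }
    paste0("ATG", paste(codons, collapse = ""))
}

#' Evolve a nucleotide sequence under Jukes-Cantor divergence
#'
#' Each site changes with probability `p = 3/4 (1 - exp(-4/3 d))` where `d`
#' is the expected number of substitutions per site; the replacement base is
#' uniform over the three alternatives, i.e. exactly the JC69 transition
#' kernel, so kernels compose along branches. With `coding = TRUE` a
#' substitution that would create an in-frame stop codon is redrawn among the
#' remaining non-stop alternatives (kept unchanged if none exists); this
#' leaves the per-site substitution probability intact while keeping the
#' frame translatable.
#'
#' @param seq Character string (nucleotides, frame starts at position 1 when
#'   `coding = TRUE`).
#' @param d Expected substitutions per site (>= 0).
#' @param coding Avoid creating in-frame stop codons.
#' @return The evolved sequence (character string).
#' @export
evolveSequence <- function(seq, d, coding = TRUE) {
    stopifnot(d >= 0)
    if (d == 0) return(seq)
    x <- strsplit(seq, "", fixed = TRUE)[[1]]
    p <- 0.75 * (1 - exp(-4 / 3 * d))
    hit <- which(runif(length(x)) < p)
    for (i in hit) {
        alt <- setdiff(.DNA, x[i])
        alt <- sample(alt)          # uniform order, first acceptable kept
        if (coding) {
            cod0 <- 3L * ((i - 1L) %/% 3L)   # 0-based codon start
            idx <- cod0 + 1:3
            for (b in alt) {
                cand <- x[idx]; cand[i - cod0] <- b
                if (!(paste(cand, collapse = "") %in% .STOP_CODONS)) {
                    x[i] <- b; break
                }
            }
        } else {
            x[i] <- alt[1]
        }
    }
    paste(x, collapse = "")
}

.revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

.translate <- function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s)))

## deterministic reverse translation (first codon listed per amino acid)
.CODON_OF <- local({
    gc <- Biostrings::GENETIC_CODE
    sense <- gc[!gc %in% "*"]
    tapply(names(sense), sense, function(v) sort(v)[1])
})

.reverseTranslate <- function(protein) {
    aa <- strsplit(protein, "", fixed = TRUE)[[1]]
    paste(unname(.CODON_OF[aa]), collapse = "")
}

#' Fragment a genome sequence into contigs
#'
#' Breakpoints are drawn uniformly without replacement over the internal
#' positions of the sequence; the resulting contigs partition the input
#' exactly (concatenating them reproduces it).
#'
#' @param genome_seq Character string or `DNAString`.
#' @param n_contigs Number of contigs; must satisfy
#'   `1 <= n_contigs <= nchar(genome_seq) / 100`.
#' @param seed Integer seed (the caller's RNG state is restored afterwards).
#' @return Character vector of contigs, named `ctg001`, `ctg002`, ...
#' @examples
#' fragmentAssembly(strrep("ACGT", 250), 5, seed = 1)
#' @export
fragmentAssembly <- function(genome_seq, n_contigs, seed = 1L) {
    s <- as.character(genome_seq)
    L <- nchar(s)
    n_contigs <- as.integer(n_contigs)
    if (n_contigs < 1L || n_contigs > L / 100)
        stop("n_contigs must be between 1 and length/100")
    cuts <- if (n_contigs == 1L) integer(0) else
        .withSeed(seed, sort(sample.int(L - 1L, n_contigs - 1L)))
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, L)
    ctgs <- substring(s, starts, ends)
    names(ctgs) <- sprintf("ctg%03d", seq_along(ctgs))
    ctgs
}

## ---------------------------------------------------------------------------
## CEP planting
## ---------------------------------------------------------------------------

## packaged triad profile: three short windows around the catalytic Asp, His
## and Ser of the subtilase domain; the triad residue offset within each
## window is fixed
.TRIAD_MOTIFS <- list(D = list(motif = "DSGI", offset = 0L),
                      H = list(motif = "HGTH", offset = 0L),
                      S = list(motif = "GTSM", offset = 2L))
.CANONICAL_LPXTG <- "LP[A-Z]TG"
.DERIVATIVE_LPXTG <- "[LIVFM]P[A-Z][TSA][GSNDA]"

.scrubPattern <- function(x, pattern, keep_start = integer(0)) {
    ## destroy regex matches except those starting at keep_start (1-based)
    repeat {
        m <- gregexpr(pattern, x)[[1]]
        if (m[1] == -1L) break
        bad <- setdiff(as.integer(m), keep_start)
        if (length(bad) == 0L) break
        substr(x, bad[1], bad[1]) <- "A"
    }
    x
}

#' Draw a random valid CEP descriptor
#'
#' Samples an anchor class, a compatible domain set, ordered catalytic-triad
#' positions and a protein length, for use with [plantCEP()].
#'
#' @param length Protein length in amino acids.
#' @return A descriptor list (`d_pos`, `h_pos`, `s_pos`, `domains`, `anchor`,
#'   `length`).
#' @export
randomCEPDescriptor <- function(length = 1200L) {
    anchor <- sample(c("LPXTG", "LPXTG_derivative", "SLAP", "none",
                       "truncated"), 1L)
    pool <- c("PA", "Fn1", "Fn2", "SLAP")
    domains <- pool[runif(4) < 0.5]
    if (anchor == "SLAP") domains <- union(domains, "SLAP")
    ## anchor "none" is unsatisfiable with a SLAP domain present (the SLAP
    ## fallback would fire), so keep such descriptors consistent
    if (anchor == "none") domains <- setdiff(domains, "SLAP")
    pos <- sort(sample(seq(60L, 600L), 3L))
    while (min(diff(pos)) < 10L) pos <- sort(sample(seq(60L, 600L), 3L))
    list(d_pos = pos[1], h_pos = pos[2], s_pos = pos[3],
         domains = domains, anchor = anchor, length = as.integer(length))
}

#' Plant a cell-envelope protease with a known architecture
#'
#' Emits a protein carrying the packaged catalytic-triad motif windows at the
#' requested Asp/His/Ser positions, a subtilase-domain hit spanning them,
#' optional PA/Fn1/Fn2/SLAP domain hits, and the requested C-terminal anchor
#' signal; accidental motif matches are scrubbed so [classifyCEP()] recovers
#' exactly the requested classification.
#'
#' @param descriptor A list as from [randomCEPDescriptor()]: triad positions
#'   `d_pos`, `h_pos`, `s_pos` (need not be ordered -- disordered triads are
#'   useful for negative tests), `domains` (subset of PA/Fn1/Fn2/SLAP),
#'   `anchor` (LPXTG, LPXTG_derivative, SLAP, none, truncated), `length`.
#' @param protein_id Identifier used in the emitted hit table.
#' @return List with `protein` (character), `domain_hits` (data.frame:
#'   `protein_id`, `domain`, `start`, `end`, `evalue`, `bitscore`),
#'   `partial_status` and `expected` (the classification a correct screen
#'   must return).
#' @export
plantCEP <- function(descriptor, protein_id = "cep1") {
    d <- descriptor
    stopifnot(all(c("d_pos", "h_pos", "s_pos", "anchor", "length")
                  %in% names(d)))
    if (identical(d$anchor, "SLAP") && !"SLAP" %in% d$domains)
        stop("contradictory descriptor: anchor SLAP requires the SLAP domain")
    if (identical(d$anchor, "none") && "SLAP" %in% d$domains)
        stop("contradictory descriptor: anchor 'none' excludes the SLAP domain")
    if (!all(d$domains %in% c("PA", "Fn1", "Fn2", "SLAP")))
        stop("domains must be a subset of {PA, Fn1, Fn2, SLAP}")
    L <- as.integer(d$length)
    if (L < max(d$d_pos, d$h_pos, d$s_pos) + 120L)
        stop("protein length too short for the requested triad positions")
    x <- paste(sample(.AA20, L, replace = TRUE), collapse = "")
    stamp <- function(x, motif, start) {
        substr(x, start, start + nchar(motif) - 1L) <- motif
        x
    }
    dm <- .TRIAD_MOTIFS
    starts <- c(D = d$d_pos - dm$D$offset, H = d$h_pos - dm$H$offset,
                S = d$s_pos - dm$S$offset)
    span <- c(max(1L, min(starts) - 20L),
              min(L, max(starts + 4L) + 20L))
    ## scrub accidental triad motifs inside the scanned span, then stamp
    for (k in names(dm))
        x <- .scrubPattern(x, dm[[k]]$motif, keep_start = integer(0))
    for (k in names(dm)) x <- stamp(x, dm[[k]]$motif, starts[[k]])
    ## C-terminal anchor window: scrub accidental anchor motifs there only
    ## (the classifier scans nowhere else, and a global scrub could damage
    ## the stamped triad motifs)
    win_start <- L - 59L
    win <- substr(x, win_start, L)
    win <- .scrubPattern(win, .CANONICAL_LPXTG)
    win <- .scrubPattern(win, .DERIVATIVE_LPXTG)
    substr(x, win_start, L) <- win
    if (identical(d$anchor, "LPXTG")) {
        x <- stamp(x, "LPKTG", L - 25L)
    } else if (identical(d$anchor, "LPXTG_derivative")) {
        x <- stamp(x, "IPNSN", L - 25L)
    }
    hits <- data.frame(protein_id = protein_id, domain = "Peptidase_S8",
                       start = span[1], end = span[2], evalue = 1e-40,
                       bitscore = 250, stringsAsFactors = FALSE)
    dom_at <- span[2] + 10L
    for (dom in intersect(c("PA", "Fn1", "Fn2", "SLAP"), d$domains)) {
        dlen <- c(PA = 100L, Fn1 = 90L, Fn2 = 80L, SLAP = 60L)[[dom]]
        dend <- min(win_start - 5L, dom_at + dlen)
        hits <- rbind(hits, data.frame(
            protein_id = protein_id, domain = dom, start = dom_at,
            end = dend, evalue = 1e-12, bitscore = 80,
            stringsAsFactors = FALSE))
        dom_at <- dend + 5L
    }
    partial <- if (identical(d$anchor, "truncated")) "missing3" else "complete"
    list(protein = x, domain_hits = hits, partial_status = partial,
         expected = list(protein_id = protein_id,
                         triad = c(D = unname(d$d_pos), H = unname(d$h_pos),
                                   S = unname(d$s_pos)),
                         domains = sort(d$domains), anchor = d$anchor,
                         length = L))
}

## ---------------------------------------------------------------------------
## Clade simulation
## ---------------------------------------------------------------------------

.famId <- function(i) sprintf("fam%04d", i)

#' Simulate a clade of genomes with full ground truth
#'
#' Simulates a birth-death tree (or evolves along a supplied one), places a
#' fixed core of gene families at the root, gains accessory families at most
#' once each by a Poisson process along branches (losses likewise Poisson;
#' core families are never lost by construction), evolves all genes and
#' intergenic spacers under Jukes-Cantor divergence, assembles each tip
#' genome as alternating genes and spacers, fragments it into contigs at
#' intergenic positions, and optionally plants cell-envelope proteases,
#' plasmid-derived contigs and CAZyme hit sets.
#'
#' All stochastic draws come from one generator stream seeded by
#' `config@seed`, in a fixed documented order (tree, root sequences, then
#' branches in preorder), so equal configurations give identical output.
#'
#' @param config A [SimConfig-class].
#' @param tree Optional fixed `phylo` tree (rooted, branch lengths); when
#'   supplied, its tips are relabelled `g01`, `g02`, ... and the birth-death
#'   step is skipped.
#' @return A list with `genomes` (named list of [GenomeRecord-class]) and
#'   `truth` (a [TruthSet-class]).
#' @examples
#' sim <- simulateClade(simConfig(n_taxa = 3, core_size = 10,
#'                                accessory_pool = 4, n_contigs = 2,
#'                                seed = 7))
#' names(sim$genomes)
#' @export
simulateClade <- function(config, tree = NULL) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    .withSeed(config@seed, .simulateCladeImpl(config, tree))
}

.simulateCladeImpl <- function(config, tree) {
    n <- config@n_taxa
    if (is.null(tree)) {
        tree <- ape::rphylo(n, config@birth_rate, config@death_rate,
                            fossils = FALSE)
    } else {
        tree <- ape::reorder.phylo(tree, "cladewise")
        if (ape::Ntip(tree) != n)
            stop("supplied tree must have n_taxa tips")
    }
    tree$tip.label <- sprintf("g%02d", seq_len(n))
    tree <- ape::reorder.phylo(tree, "cladewise")

    n_core <- config@core_size
    n_acc <- config@accessory_pool
    fam_ids <- .famId(seq_len(n_core + n_acc))
    gc <- config@gc_content

    ## root state: core genes + per-family intergenic spacers + strands
    lens <- pmax(90, round(rnorm(n_core + n_acc, config@gene_len_mean,
                                 config@gene_len_sd)))
    n_codons <- pmax(30L, as.integer(round(lens / 3)))
    strands <- sample(c("+", "-"), n_core + n_acc, replace = TRUE)
    root_genes <- setNames(vector("list", n_core + n_acc), fam_ids)
    for (i in seq_len(n_core))
        root_genes[[i]] <- .randomCodingSequence(n_codons[i], gc)
    root_spacers <- vapply(seq_len(n_core + n_acc), function(i)
        paste(.sampleBases(config@intergenic_len, gc), collapse = ""),
        character(1))

    ## node states, indexed by ape node number
    n_nodes <- ape::Ntip(tree) + tree$Nnode
    root <- ape::Ntip(tree) + 1L
    genes_at <- vector("list", n_nodes)
    spacers_at <- vector("list", n_nodes)
    present_at <- vector("list", n_nodes)
    genes_at[[root]] <- root_genes
    spacers_at[[root]] <- root_spacers
    present_at[[root]] <- c(rep(TRUE, n_core), rep(FALSE, n_acc))

    gained <- rep(FALSE, n_acc)          # accessory families gained anywhere
    ev <- data.frame(branch = character(0), length = numeric(0),
                     gain_draws = integer(0), gain_events = integer(0),
                     loss_draws = integer(0), loss_events = integer(0),
                     stringsAsFactors = FALSE)

    edge <- tree$edge
    elen <- tree$edge.length
    for (e in seq_len(nrow(edge))) {
        par <- edge[e, 1]; chd <- edge[e, 2]; len <- elen[e]
        pres <- present_at[[par]]
        genes <- genes_at[[par]]
        ## accessory gains: at most one gain per family across the whole tree
        open <- which(!gained)
        gain_draws <- if (length(open)) rpois(length(open),
                                              config@gain_rate * len)
                      else integer(0)
        newly <- open[gain_draws >= 1L]
        ## accessory losses: any Poisson event on a branch removes the family
        ## from the child lineage (core families are exempt by construction)
        acc_present <- which(pres & c(rep(FALSE, n_core), rep(TRUE, n_acc)))
        loss_draws <- if (length(acc_present))
            rpois(length(acc_present), config@loss_rate * len) else integer(0)
        lost <- acc_present[loss_draws >= 1L]
        ev <- rbind(ev, data.frame(
            branch = paste0(par, "->", chd), length = len,
            gain_draws = length(gain_draws),
            gain_events = sum(gain_draws),
            loss_draws = length(loss_draws),
            loss_events = sum(loss_draws), stringsAsFactors = FALSE))
        pres[lost] <- FALSE
        for (i in newly) {
            fi <- n_core + i
            genes[[fi]] <- .randomCodingSequence(n_codons[fi], gc)
            pres[fi] <- TRUE
            gained[i] <- TRUE
        }
        ## sequence evolution along the branch
        d <- config@subst_rate * len
        spac <- spacers_at[[par]]
        if (d > 0) {
            for (fi in which(pres)) genes[[fi]] <-
                evolveSequence(genes[[fi]], d, coding = TRUE)
            spac <- vapply(spac, evolveSequence, character(1), d = d,
                           coding = FALSE, USE.NAMES = FALSE)
        }
        genes[!pres] <- list(NULL)
        genes_at[[chd]] <- genes
        spacers_at[[chd]] <- spac
        present_at[[chd]] <- pres
    }

    ## assemble tip genomes
    tips <- tree$tip.label
    fm <- matrix(0L, nrow = n, ncol = n_core + n_acc,
                 dimnames = list(tips, fam_ids))
    genomes <- setNames(vector("list", n), tips)
    map <- list()
    planted <- data.frame(taxon = character(0), feature_kind = character(0),
                          descriptor = character(0), stringsAsFactors = FALSE)
    feature_data <- list()

    cep_taxa <- if (config@n_cep > 0) tips[seq_len(config@n_cep)] else
        character(0)
    plas_taxa <- if (config@n_plasmid > 0) tips[seq_len(config@n_plasmid)]
        else character(0)
    cazy_taxa <- if (config@n_cazy > 0) tips[seq_len(config@n_cazy)] else
        character(0)
    plasmid_ref <- paste(.sampleBases(6000L, gc), collapse = "")

    for (t in seq_len(n)) {
        tip <- tips[t]
        pres <- which(present_at[[t]])
        fm[t, pres] <- 1L
        genes <- genes_at[[t]]
        spac <- spacers_at[[t]]
        parts <- character(0)
        gene_rows <- list()
        pos <- 0L
        gene_seqs <- character(0)
        for (fi in pres) {
            cds <- genes[[fi]]
            glen <- nchar(cds)
            emb <- if (strands[fi] == "+") cds else .revcomp(cds)
            gid <- sprintf("%s_%s", tip, .famId(fi))
            gene_rows[[length(gene_rows) + 1L]] <- data.frame(
                gene_id = gid, start = pos, end = pos + glen,
                strand = strands[fi], stringsAsFactors = FALSE)
            gene_seqs[gid] <- cds
            parts <- c(parts, emb, spac[fi])
            pos <- pos + glen + nchar(spac[fi])
        }
        genome_seq <- paste(parts, collapse = "")
        gtab <- do.call(rbind, gene_rows)
        map[[tip]] <- data.frame(genome_id = tip, gene_id = gtab$gene_id,
                                 family_id = .famId(pres),
                                 stringsAsFactors = FALSE)

        ## fragmentation at intergenic positions only (genes stay intact)
        L <- nchar(genome_seq)
        in_gene <- rep(FALSE, L)
        for (r in seq_len(nrow(gtab)))
            in_gene[(gtab$start[r] + 1L):gtab$end[r]] <- TRUE
        allowed <- which(!in_gene)
        allowed <- allowed[allowed > 1L & allowed <= L]  # cut before base i
        k <- min(config@n_contigs, length(allowed))
        cuts <- if (k > 1L) sort(sample(allowed, k - 1L)) - 1L else integer(0)
        starts0 <- c(0L, cuts); ends0 <- c(cuts, L)      # 0-based half-open
        ctgs <- substring(genome_seq, starts0 + 1L, ends0)
        names(ctgs) <- sprintf("%s_ctg%03d", tip, seq_along(ctgs))
        ctg_of <- findInterval(gtab$start, starts0)
        gtab$contig_id <- names(ctgs)[ctg_of]
        gtab$start <- gtab$start - starts0[ctg_of]
        gtab$end <- gtab$end - starts0[ctg_of]
        gtab$partial_status <- "complete"
        prot <- vapply(gene_seqs, .translate, character(1))

        meta <- list()
        ## planted features
        if (tip %in% cep_taxa) {
            desc <- randomCEPDescriptor()
            pid <- sprintf("%s_cep1", tip)
            cep <- plantCEP(desc, protein_id = pid)
            cds <- .reverseTranslate(cep$protein)
            last <- length(ctgs)
            off <- nchar(ctgs[last])
            ctgs[last] <- paste0(ctgs[last], cds)
            gtab <- rbind(gtab, data.frame(
                gene_id = pid, start = off, end = off + nchar(cds),
                strand = "+", contig_id = names(ctgs)[last],
                partial_status = cep$partial_status, stringsAsFactors = FALSE))
            prot[pid] <- cep$protein
            planted <- rbind(planted, data.frame(
                taxon = tip, feature_kind = "CEP-architecture",
                descriptor = pid, stringsAsFactors = FALSE))
            feature_data[[pid]] <- cep
        }
        if (tip %in% plas_taxa) {
            seg <- substr(plasmid_ref, 1L, 2000L)
            pctg <- sprintf("%s_ctgP01", tip)
            ctgs[pctg] <- seg
            hit <- data.frame(contig_id = pctg, plasmid_id = "plasmid1",
                              contig_aligned_len = 2000L,
                              plasmid_covered_len = 2000L,
                              identity = 100, stringsAsFactors = FALSE)
            planted <- rbind(planted, data.frame(
                taxon = tip, feature_kind = "plasmid-contig",
                descriptor = pctg, stringsAsFactors = FALSE))
            feature_data[[pctg]] <- list(
                hits = hit, contig_lengths = setNames(2000L, pctg),
                plasmid_lengths = c(plasmid1 = 6000L))
        }
        if (tip %in% cazy_taxa && nrow(gtab) > 0) {
            gid <- gtab$gene_id[1]
            fam <- "GH13"
            feature_data[[paste0(tip, "_cazy")]] <- list(
                hmm = data.frame(gene_id = gid, family = fam,
                                 evalue = 1e-10, stringsAsFactors = FALSE),
                blast = data.frame(gene_id = gid, family = fam,
                                   evalue = 1e-20, identity = 85,
                                   coverage = 92, stringsAsFactors = FALSE),
                family = fam)
            planted <- rbind(planted, data.frame(
                taxon = tip, feature_kind = "CAZy-family",
                descriptor = paste0(gid, ":", fam), stringsAsFactors = FALSE))
        }
        genomes[[tip]] <- new(
            "GenomeRecord", genome_id = tip,
            contigs = Biostrings::DNAStringSet(ctgs),
            genes = gtab[, c("gene_id", "contig_id", "start", "end",
                             "strand", "partial_status")],
            proteins = Biostrings::AAStringSet(prot), metadata = meta)
    }

    ## drop never-gained accessory families and those gained but driven
    ## extinct again by losses: truth covers realised families only
    keep <- c(rep(TRUE, n_core), gained) & colSums(fm) > 0
    truth <- new("TruthSet", tree = tree,
                 family_matrix = fm[, keep, drop = FALSE],
                 gene_family_map = do.call(rbind, map),
                 event_counts = ev, planted_features = planted,
                 feature_data = feature_data)
    list(genomes = genomes, truth = truth)
}
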