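## Format readers/writers and the top-level pipeline that chains the
## simulator, pan-genome, identity, phylogroup and screen stages. All TSV
## outputs carry headers, are stable-sorted, and are stamped with the config
## hash and seed so that identical configurations give byte-identical
## output.

.IUPAC_DNA <- "ACGTRYSWKMBDHVN"
.AA_CHARS <- "ARNDCQEGHILKMFPSTWYVXBZ*"

#' Read a FASTA file
#'
#' Wrapped or unwrapped lines are accepted; sequences are normalised to
#' upper case. Duplicate ids and characters outside the IUPAC alphabet are
#' rejected with the offending position; an empty file yields an empty set
#' with a warning.
#'
#' @param path FASTA file path.
#' @param alphabet `"DNA"` or `"AA"`.
#' @return A `DNAStringSet` or `AAStringSet` named by record id (first
#'   whitespace-delimited token; full descriptions kept in
#'   `metadata(x)` names are not used).
#' @export
readFasta <- function(path, alphabet = c("DNA", "AA")) {
    alphabet <- match.arg(alphabet)
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) {
        warning("empty FASTA file: ", path)
        return(if (alphabet == "DNA") Biostrings::DNAStringSet() else
                   Biostrings::AAStringSet())
    }
    ids <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(ids))
        stop("duplicate FASTA ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- toupper(as.character(raw))
    legal <- if (alphabet == "DNA") .IUPAC_DNA else .AA_CHARS
    bad <- regexpr(sprintf("[^%s]", legal), seqs)
    if (any(bad > 0)) {
        i <- which(bad > 0)[1]
        stop(sprintf("illegal %s character '%s' in record '%s' at position %d",
                     alphabet, substr(seqs[i], bad[i], bad[i]), ids[i],
                     bad[i]))
    }
    names(seqs) <- ids
    if (alphabet == "DNA") Biostrings::DNAStringSet(seqs) else
        Biostrings::AAStringSet(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs Named `XStringSet` or character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
    if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
    if (is.null(names(seqs))) stop("sequences must be named")
    Biostrings::writeXStringSet(seqs, path, width = width)
    invisible(path)
}

#' Read a rooted Newick tree
#'
#' Parses a single rooted tree with branch lengths, after a bracket-balance
#' pre-check that reports the byte offset of the first imbalance. Unlabeled
#' leaves and negative branch lengths are rejected.
#'
#' @param path Newick file path.
#' @return An ape `phylo` object.
#' @export
readNewick <- function(path) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
    depth <- 0L
    chars <- strsplit(txt, "", fixed = TRUE)[[1]]
    for (i in seq_along(chars)) {
        if (chars[i] == "(") depth <- depth + 1L
        if (chars[i] == ")") depth <- depth - 1L
        if (depth < 0L)
            stop("malformed Newick: unmatched ')' at offset ", i)
    }
    if (depth != 0L)
        stop("malformed Newick: ", depth, " unclosed '(' at offset ",
             length(chars))
    tree <- tryCatch(ape::read.tree(text = txt),
                     error = function(e)
                         stop("Newick parse error: ", conditionMessage(e)),
                     warning = function(w)
                         stop("Newick parse error: ", conditionMessage(w)))
    if (!inherits(tree, "phylo")) stop("Newick parse error in ", path)
    if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label)))
        stop("unlabeled leaves are not allowed")
    if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
        stop("negative branch lengths are not allowed")
    tree
}

#' Write a tree to Newick
#'
#' @param tree An ape `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}

#' Write a gene coordinate table
#'
#' Columns: genome, gene_id, contig, start, end, strand; coordinates are
#' 0-based half-open throughout.
#'
#' @param genomes Named list of [GenomeRecord-class]s.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genomes, path) {
    rows <- lapply(genomes, function(g) {
        tb <- geneTable(g)
        data.frame(genome = genomeId(g), gene_id = tb$gene_id,
                   contig = tb$contig_id, start = tb$start, end = tb$end,
                   strand = tb$strand, partial_status = tb$partial_status,
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- df[order(df$genome, df$gene_id), , drop = FALSE]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a gene coordinate table written by [writeGeneTable()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readGeneTable <- function(path)
    read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)

.configHash <- function(config) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(yaml::as.yaml(config), tf)
    unname(tools::md5sum(tf))
}

.stampedTsv <- function(df, path, stamp) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", stamp), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> pan-genome -> identity -> phylogroups ->
#' screens according to a configuration list (or YAML file). Every output
#' TSV is stamped with the configuration hash and seed; rerunning the same
#' configuration produces byte-identical files. Any stage failure aborts
#' with the stage name and cause.
#'
#' Recognised configuration blocks (all optional except `outdir`):
#' `seed`; `simulate` (fields of [simConfig()]); `pangenome`
#' (`min_identity`, `min_query_cov`, `n_perm`); `identity` (`metric`,
#' fields of [aniConfig()]); `phylo` (`k_groups`, `bins`); `screens`
#' (`enabled`).
#'
#' @param config List or path to a YAML file.
#' @return Invisible list of stage results (`genomes`, `truth`, `pan`,
#'   `core_count`, `identity`, `phylogroups`, `screens`, `outputs`).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config), !is.null(config$outdir))
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    cfg_nohash <- config[setdiff(names(config), "outdir")]
    stamp <- sprintf("config=%s seed=%d", .configHash(cfg_nohash), seed)
    outputs <- character(0)
    emit <- function(df, name) {
        p <- file.path(outdir, name)
        .stampedTsv(df, p, stamp)
        outputs <<- c(outputs, p)
    }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    ## -- simulate ----------------------------------------------------------
    sim <- stage("simulate", {
        sc <- config$simulate
        if (is.null(sc)) stop("this pipeline requires a 'simulate' block")
        sc$seed <- seed
        simulateClade(do.call(simConfig, sc))
    })
    genomes <- sim$genomes
    truth <- sim$truth
    for (g in genomes) {
        writeFasta(contigs(g), file.path(outdir, paste0(genomeId(g),
                                                        "_contigs.fasta")))
        writeFasta(proteins(g), file.path(outdir, paste0(genomeId(g),
                                                         "_proteins.fasta")))
    }
    writeGeneTable(genomes, file.path(outdir, "genes.tsv"))
    writeNewick(truthTree(truth), file.path(outdir, "true_tree.nwk"))

    ## -- pangenome ---------------------------------------------------------
    pg <- if (is.null(config$pangenome)) list() else config$pangenome
    pan <- stage("pangenome", accumulatePanFamilies(
        genomes,
        min_identity = if (is.null(pg$min_identity)) 25 else pg$min_identity,
        min_query_cov = if (is.null(pg$min_query_cov)) 40 else
            pg$min_query_cov,
        seed = seed,
        n_perm = if (is.null(pg$n_perm)) 10L else as.integer(pg$n_perm)))
    fam_rows <- do.call(rbind, lapply(panFamilies(pan), function(f)
        data.frame(family_id = f$family_id, genome_id = f$members$genome_id,
                   gene_id = f$members$gene_id, stringsAsFactors = FALSE)))
    emit(fam_rows[order(fam_rows$family_id, fam_rows$genome_id,
                        fam_rows$gene_id), ], "families.tsv")
    emit(cbind(curve = "pan", panCurve(pan)), "pan_curve.tsv")
    emit(cbind(curve = "core", coreCurve(pan)), "core_curve.tsv")
    pres <- familyPresence(pan)
    core_count <- sum(rowSums(pres > 0) == ncol(pres))

    ## -- identity ----------------------------------------------------------
    idc <- if (is.null(config$identity)) list() else config$identity
    metric <- if (is.null(idc$metric)) "TNI" else idc$metric
    acfg <- aniConfig(
        fragment_len = if (is.null(idc$fragment_len)) 1020L else
            idc$fragment_len,
        min_fragment_identity = if (is.null(idc$min_fragment_identity)) 30
            else idc$min_fragment_identity,
        min_fragment_alignable = if (is.null(idc$min_fragment_alignable)) 70
            else idc$min_fragment_alignable,
        min_tail_fragment = if (is.null(idc$min_tail_fragment)) 100L else
            idc$min_tail_fragment)
    im <- stage("identity",
                pairwiseIdentityMatrix(genomes, metric = metric,
                                       config = acfg))
    emit(data.frame(taxon = idTaxa(im),
                    as.data.frame(idValues(im), check.names = FALSE)),
         "identity_matrix.tsv")

    ## -- phylogroups -------------------------------------------------------
    ph <- if (is.null(config$phylo)) list() else config$phylo
    k <- if (is.null(ph$k_groups)) 2L else as.integer(ph$k_groups)
    bins <- if (is.null(ph$bins)) 100L else as.integer(ph$bins)
    tree <- truthTree(truth)
    if (is.null(tree)) stop("pipeline stage 'phylo' failed: no tree available")
    groups <- stage("phylo", optimizePhylogroups(
        tree, cladeGroups(tree, k), bins = bins))
    emit(data.frame(taxon = names(grouping(groups)),
                    group = unname(grouping(groups)),
                    objective = objectiveValue(groups)),
         "phylogroups.tsv")

    ## -- screens -----------------------------------------------------------
    scr <- stage("screens", {
        out <- list()
        pf <- plantedFeatures(truth)
        ceprows <- list()
        for (pid in pf$descriptor[pf$feature_kind == "CEP-architecture"]) {
            fd <- truth@feature_data[[pid]]
            rec <- classifyCEP(fd$protein, fd$domain_hits,
                               partial_status = fd$partial_status,
                               protein_id = pid)
            ceprows[[pid]] <- data.frame(
                protein_id = pid,
                anchor = if (is.null(rec)) "rejected" else rec$anchor,
                expected = fd$expected$anchor, stringsAsFactors = FALSE)
        }
        if (length(ceprows)) {
            df <- do.call(rbind, ceprows)
            rownames(df) <- NULL
            emit(df[order(df$protein_id), ], "cep_report.tsv")
            out$cep <- df
        }
        pl <- pf$descriptor[pf$feature_kind == "plasmid-contig"]
        if (length(pl)) {
            fd <- truth@feature_data[pl]
            asg <- do.call(rbind, lapply(fd, function(d)
                assignPlasmidContigs(d$hits, d$contig_lengths,
                                     d$plasmid_lengths)))
            rownames(asg) <- NULL
            emit(asg, "plasmid_assignments.tsv")
            out$plasmid <- asg
        }
        out
    })

    res <- list(genomes = genomes, truth = truth, pan = pan,
                core_count = core_count, identity = im,
                phylogroups = groups, screens = scr, outputs = outputs)
    invisible(res)
}
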