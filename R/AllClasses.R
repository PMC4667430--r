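#' @import methods
#' @importFrom stats rpois rnorm runif sd setNames quantile cor kruskal.test pchisq pt
#' @importFrom utils head tail write.table read.table combn
NULL

## ---------------------------------------------------------------------------
## Simulator configuration
## ---------------------------------------------------------------------------

#' Configuration for the clade simulator
#'
#' Holds every tunable of the genome-evolution simulator: the birth-death tree
#' model, gene-content dynamics (a fixed core plus an accessory pool gained at
#' most once and lost by a Poisson process), Jukes-Cantor nucleotide
#' divergence, gene geometry, draft fragmentation and planted screen features.
#'
#' @slot n_taxa Number of extant genomes to simulate (>= 2).
#' @slot birth_rate,death_rate Birth-death tree rates (events per unit time).
#' @slot core_size Number of gene families present in every taxon (never lost).
#' @slot accessory_pool Number of accessory families available to be gained.
#' @slot gain_rate,loss_rate Accessory gain/loss rates per family per unit
#'   branch length.
#' @slot subst_rate Substitutions per site per unit branch length
#'   (Jukes-Cantor).
#' @slot gene_len_mean,gene_len_sd Gene length distribution in nt; realised
#'   lengths are rounded to multiples of 3.
#' @slot intergenic_len Length in nt of each intergenic spacer.
#' @slot n_contigs Number of contigs each genome is fragmented into.
#' @slot gc_content Target GC fraction of generated sequence (0.30-0.60).
#' @slot n_cep,n_plasmid,n_cazy Number of taxa receiving a planted
#'   cell-envelope protease, plasmid-derived contig or CAZyme hit set.
#' @slot seed Integer seed; the same seed gives byte-identical output.
#' @seealso [simConfig()], [simulateClade()]
#' @export
setClass("SimConfig", representation(
    n_taxa = "integer", birth_rate = "numeric", death_rate = "numeric",
    core_size = "integer", accessory_pool = "integer",
    gain_rate = "numeric", loss_rate = "numeric", subst_rate = "numeric",
    gene_len_mean = "numeric", gene_len_sd = "numeric",
    intergenic_len = "integer", n_contigs = "integer",
    gc_content = "numeric",
    n_cep = "integer", n_plasmid = "integer", n_cazy = "integer",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@n_taxa < 2L) msg <- c(msg, "n_taxa must be >= 2")
    rates <- c(object@birth_rate, object@death_rate, object@gain_rate,
               object@loss_rate, object@subst_rate)
    if (any(rates < 0)) msg <- c(msg, "all rates must be >= 0")
    if (object@birth_rate <= object@death_rate)
        msg <- c(msg, "birth_rate must exceed death_rate")
    if (object@core_size < 1L) msg <- c(msg, "core_size must be >= 1")
    if (object@accessory_pool < 0L) msg <- c(msg, "accessory_pool must be >= 0")
    if (object@gene_len_mean < 30) msg <- c(msg, "gene_len_mean must be >= 30 nt")
    if (object@intergenic_len < 1L) msg <- c(msg, "intergenic_len must be >= 1")
    if (object@n_contigs < 1L) msg <- c(msg, "n_contigs must be >= 1")
    if (object@gc_content < 0.3 || object@gc_content > 0.6)
        msg <- c(msg, "gc_content must lie in [0.30, 0.60]")
    if (any(c(object@n_cep, object@n_plasmid, object@n_cazy) > object@n_taxa))
        msg <- c(msg, "planted-feature counts cannot exceed n_taxa")
    if (length(msg)) msg else TRUE
})

#' Create a simulator configuration
#'
#' Defaults describe a small, fully verifiable clade: eight taxa on a
#' birth-death tree, a 200-family core with a 60-family accessory pool,
#' moderate gain/loss, realistic bacterial gene lengths (~900 nt) and low
#' nucleotide divergence so that homologs remain well above the 25%
#' identity clustering threshold.
#'
#' @param n_taxa,birth_rate,death_rate,core_size,accessory_pool,gain_rate,loss_rate,subst_rate,gene_len_mean,gene_len_sd,intergenic_len,n_contigs,gc_content,n_cep,n_plasmid,n_cazy,seed
#'   See the slot documentation of [SimConfig-class].
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(n_taxa = 4, core_size = 20, accessory_pool = 10, seed = 1)
#' @export
simConfig <- function(n_taxa = 8L, birth_rate = 1, death_rate = 0,
                      core_size = 200L, accessory_pool = 60L,
                      gain_rate = 0.2, loss_rate = 0.1, subst_rate = 0.02,
                      gene_len_mean = 900, gene_len_sd = 150,
                      intergenic_len = 30L, n_contigs = 5L,
                      gc_content = 0.42,
                      n_cep = 0L, n_plasmid = 0L, n_cazy = 0L, seed = 1L) {
    new("SimConfig", n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
        death_rate = death_rate, core_size = as.integer(core_size),
        accessory_pool = as.integer(accessory_pool), gain_rate = gain_rate,
        loss_rate = loss_rate, subst_rate = subst_rate,
        gene_len_mean = gene_len_mean, gene_len_sd = gene_len_sd,
        intergenic_len = as.integer(intergenic_len),
        n_contigs = as.integer(n_contigs), gc_content = gc_content,
        n_cep = as.integer(n_cep), n_plasmid = as.integer(n_plasmid),
        n_cazy = as.integer(n_cazy), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@n_taxa, "taxa | core", object@core_size,
        "| accessory pool", object@accessory_pool,
        "| subst rate", object@subst_rate,
        "| seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## One simulated or observed genome
## ---------------------------------------------------------------------------

#' A single genome: contigs, gene set and metadata
#'
#' @slot genome_id Strain identifier.
#' @slot contigs A [Biostrings::DNAStringSet] of assembly contigs.
#' @slot genes data.frame with columns `gene_id`, `contig_id`, `start`, `end`
#'   (0-based half-open, nt on the contig), `strand` ("+"/"-") and
#'   `partial_status` (`complete`, `missing5`, `missing3`, `missing_both`).
#' @slot proteins A [Biostrings::AAStringSet] named by `gene_id`.
#' @slot metadata Free-form list (niche label, planted features, ...).
#' @export
setClass("GenomeRecord", representation(
    genome_id = "character", contigs = "ANY", genes = "data.frame",
    proteins = "ANY", metadata = "list"))

setValidity("GenomeRecord", function(object) {
    msg <- character()
    g <- object@genes
    need <- c("gene_id", "contig_id", "start", "end", "strand", "partial_status")
    if (!all(need %in% names(g)))
        msg <- c(msg, paste("genes table must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (nrow(g) && any(g$end <= g$start))
            msg <- c(msg, "gene end must exceed start (0-based half-open)")
        if (nrow(g) && !all(g$gene_id %in% names(object@proteins)))
            msg <- c(msg, "every gene needs a protein sequence")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn GenomeRecord-class genome identifier
#' @param object,x A `GenomeRecord`.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname GenomeRecord-class
#' @export
setMethod("genomeId", "GenomeRecord", function(x) x@genome_id)

#' @rdname GenomeRecord-class
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname GenomeRecord-class
#' @export
setMethod("contigs", "GenomeRecord", function(x) x@contigs)

#' @rdname GenomeRecord-class
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @rdname GenomeRecord-class
#' @export
setMethod("geneTable", "GenomeRecord", function(x) x@genes)

#' @rdname GenomeRecord-class
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname GenomeRecord-class
#' @export
setMethod("proteins", "GenomeRecord", function(x) x@proteins)

#' Full genome sequence (contigs concatenated)
#' @rdname GenomeRecord-class
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @rdname GenomeRecord-class
#' @export
setMethod("genomeSequence", "GenomeRecord", function(x)
    Biostrings::DNAString(paste(as.character(x@contigs), collapse = "")))

setMethod("show", "GenomeRecord", function(object) {
    cat("GenomeRecord", object@genome_id, "|",
        length(object@contigs), "contigs |",
        nrow(object@genes), "genes |",
        sum(Biostrings::width(object@contigs)), "nt\n")
})

## ---------------------------------------------------------------------------
## Ground truth emitted alongside a simulated clade
## ---------------------------------------------------------------------------

#' Ground truth for a simulated clade
#'
#' @slot tree The true `phylo` tree (ape) with branch lengths.
#' @slot family_matrix taxon x family 0/1 presence matrix; core families are
#'   all-ones columns by construction.
#' @slot gene_family_map data.frame (`genome_id`, `gene_id`, `family_id`).
#' @slot event_counts data.frame per branch: `branch`, `length`,
#'   `gain_events`, `loss_draws`, `loss_events` (raw Poisson event counts, so
#'   their means are rate x length x number-of-families).
#' @slot planted_features data.frame (`taxon`, `feature_kind`, `descriptor`)
#'   plus per-feature payload in `feature_data`.
#' @slot feature_data Named list of payloads for planted features (domain-hit
#'   tables, plasmid hit tables, CAZy hit tables).
#' @export
setClass("TruthSet", representation(
    tree = "ANY", family_matrix = "matrix", gene_family_map = "data.frame",
    event_counts = "data.frame", planted_features = "data.frame",
    feature_data = "list"))

setValidity("TruthSet", function(object) {
    msg <- character()
    fm <- object@family_matrix
    if (!is.null(object@tree) &&
        !setequal(object@tree$tip.label, rownames(fm)))
        msg <- c(msg, "tree leaf set must equal the genome set")
    if (length(msg)) msg else TRUE
})

#' @rdname TruthSet-class
#' @param x A `TruthSet`.
#' @export
setGeneric("truthTree", function(x) standardGeneric("truthTree"))

#' @rdname TruthSet-class
#' @export
setMethod("truthTree", "TruthSet", function(x) x@tree)

#' @rdname TruthSet-class
#' @export
setGeneric("familyMatrix", function(x) standardGeneric("familyMatrix"))

#' @rdname TruthSet-class
#' @export
setMethod("familyMatrix", "TruthSet", function(x) x@family_matrix)

#' @rdname TruthSet-class
#' @export
setGeneric("plantedFeatures", function(x) standardGeneric("plantedFeatures"))

#' @rdname TruthSet-class
#' @export
setMethod("plantedFeatures", "TruthSet", function(x) x@planted_features)

setMethod("show", "TruthSet", function(object) {
    cat("TruthSet |", nrow(object@family_matrix), "taxa x",
        ncol(object@family_matrix), "families |",
        nrow(object@planted_features), "planted features\n")
})

## ---------------------------------------------------------------------------
## Alignment scoring scheme
## ---------------------------------------------------------------------------

#' Scoring scheme for local alignment
#'
#' @slot alphabet `"nucleotide"` or `"protein"`.
#' @slot matrix_name Named substitution matrix (e.g. `"BLOSUM62"`) or `""`
#'   when match/mismatch scores are used.
#' @slot match,mismatch Integer scores used when `matrix_name == ""`.
#' @slot gap_open,gap_extend Non-negative penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @export
setClass("ScoringScheme", representation(
    alphabet = "character", matrix_name = "character",
    match = "numeric", mismatch = "numeric",
    gap_open = "numeric", gap_extend = "numeric"))

setValidity("ScoringScheme", function(object) {
    msg <- character()
    if (!object@alphabet %in% c("nucleotide", "protein"))
        msg <- c(msg, "alphabet must be 'nucleotide' or 'protein'")
    if (object@gap_extend < 0 || object@gap_open < 0)
        msg <- c(msg, "gap penalties must be non-negative")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ScoringScheme", function(object) {
    sub <- if (nzchar(object@matrix_name)) object@matrix_name else
        sprintf("match %+d / mismatch %+d", object@match, object@mismatch)
    cat("ScoringScheme [", object@alphabet, "]: ", sub,
        ", gap ", object@gap_open, "/", object@gap_extend, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## Pan-genome result
## ---------------------------------------------------------------------------

#' Pan-genome families and rarefaction curves
#'
#' @slot families List of gene families; each a list with `family_id`,
#'   `members` (data.frame `genome_id`, `gene_id`) and `representative`.
#' @slot genome_order Accumulation order actually used.
#' @slot presence family x genome 0/1 matrix.
#' @slot pan_curve,core_curve data.frames (`k`, `mean`, `sd`) over seeded
#'   permutations of genome order: families seen after k genomes, and families
#'   present in all first k genomes.
#' @slot step_counts Pan size after each genome of the realised greedy order.
#' @export
setClass("PanResult", representation(
    families = "list", genome_order = "character", presence = "matrix",
    pan_curve = "data.frame", core_curve = "data.frame",
    step_counts = "integer"))

setValidity("PanResult", function(object) {
    msg <- character()
    all_members <- unlist(lapply(object@families, function(f)
        paste(f$members$genome_id, f$members$gene_id)))
    if (anyDuplicated(all_members))
        msg <- c(msg, "families must be pairwise disjoint over genes")
    if (length(msg)) msg else TRUE
})

#' @rdname PanResult-class
#' @param x A `PanResult`.
#' @export
setGeneric("panFamilies", function(x) standardGeneric("panFamilies"))

#' @rdname PanResult-class
#' @export
setMethod("panFamilies", "PanResult", function(x) x@families)

#' @rdname PanResult-class
#' @export
setGeneric("panCurve", function(x) standardGeneric("panCurve"))

#' @rdname PanResult-class
#' @export
setMethod("panCurve", "PanResult", function(x) x@pan_curve)

#' @rdname PanResult-class
#' @export
setGeneric("coreCurve", function(x) standardGeneric("coreCurve"))

#' @rdname PanResult-class
#' @export
setMethod("coreCurve", "PanResult", function(x) x@core_curve)

#' @rdname PanResult-class
#' @export
setGeneric("familyPresence", function(x) standardGeneric("familyPresence"))

#' @rdname PanResult-class
#' @export
setMethod("familyPresence", "PanResult", function(x) x@presence)

setMethod("show", "PanResult", function(object) {
    cat("PanResult |", length(object@families), "families over",
        length(object@genome_order), "genomes | core",
        sum(rowSums(object@presence > 0) == ncol(object@presence)), "\n")
})

## ---------------------------------------------------------------------------
## Identity matrix (ANI / TNI)
## ---------------------------------------------------------------------------

#' Symmetric ANI or TNI matrix over taxa
#'
#' ANI is reported in percent (diagonal 100); TNI as a fraction (diagonal 1).
#' Pairs for which no genome fragment passed the alignment filters carry `NA`
#' (ANI) -- never 0 -- while TNI reports 0 (no matched nucleotides).
#'
#' @slot taxa Ordered taxon labels.
#' @slot values Symmetric numeric matrix.
#' @slot metric `"ANI"` or `"TNI"`.
#' @export
setClass("IdentityMatrix", representation(
    taxa = "character", values = "matrix", metric = "character"))

setValidity("IdentityMatrix", function(object) {
    msg <- character()
    v <- object@values
    if (!identical(dim(v), c(length(object@taxa), length(object@taxa))))
        msg <- c(msg, "values must be n x n over taxa")
    if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8, check.attributes = FALSE)))
        msg <- c(msg, "values must be symmetric")
    if (!object@metric %in% c("ANI", "TNI"))
        msg <- c(msg, "metric must be 'ANI' or 'TNI'")
    rng <- range(v, na.rm = TRUE)
    lim <- if (identical(object@metric, "ANI")) c(0, 100) else c(0, 1)
    if (rng[1] < lim[1] - 1e-9 || rng[2] > lim[2] + 1e-9)
        msg <- c(msg, sprintf("%s values must lie in [%g, %g]",
                              object@metric, lim[1], lim[2]))
    if (length(msg)) msg else TRUE
})

#' @rdname IdentityMatrix-class
#' @param x An `IdentityMatrix`.
#' @export
setGeneric("idTaxa", function(x) standardGeneric("idTaxa"))

#' @rdname IdentityMatrix-class
#' @export
setMethod("idTaxa", "IdentityMatrix", function(x) x@taxa)

#' @rdname IdentityMatrix-class
#' @export
setGeneric("idValues", function(x) standardGeneric("idValues"))

#' @rdname IdentityMatrix-class
#' @export
setMethod("idValues", "IdentityMatrix", function(x) x@values)

#' @rdname IdentityMatrix-class
#' @export
setGeneric("idMetric", function(x) standardGeneric("idMetric"))

#' @rdname IdentityMatrix-class
#' @export
setMethod("idMetric", "IdentityMatrix", function(x) x@metric)

setMethod("show", "IdentityMatrix", function(object) {
    off <- object@values[upper.tri(object@values)]
    cat("IdentityMatrix [", object@metric, "] ", length(object@taxa),
        " taxa | off-diagonal mean ",
        signif(mean(off, na.rm = TRUE), 4), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## Phylogrouping
## ---------------------------------------------------------------------------

#' A phylogroup assignment with monophyly flags and objective value
#'
#' @slot assignment Named character vector: taxon -> group label.
#' @slot monophyletic Named logical vector per group.
#' @slot objective Intersection area between within-group and between-group
#'   distance distributions (in `[0, 1]`, `NA` when undefined).
#' @slot trace Objective values after each accepted optimisation move.
#' @export
setClass("Phylogrouping", representation(
    assignment = "character", monophyletic = "logical",
    objective = "numeric", trace = "numeric"))

setValidity("Phylogrouping", function(object) {
    msg <- character()
    if (is.null(names(object@assignment)) ||
        anyDuplicated(names(object@assignment)))
        msg <- c(msg, "assignment must be named uniquely by taxon")
    if (!is.na(object@objective) &&
        (object@objective < -1e-9 || object@objective > 1 + 1e-9))
        msg <- c(msg, "objective must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname Phylogrouping-class
#' @param x A `Phylogrouping`.
#' @export
setGeneric("grouping", function(x) standardGeneric("grouping"))

#' @rdname Phylogrouping-class
#' @export
setMethod("grouping", "Phylogrouping", function(x) x@assignment)

#' @rdname Phylogrouping-class
#' @export
setGeneric("monophylyFlags", function(x) standardGeneric("monophylyFlags"))

#' @rdname Phylogrouping-class
#' @export
setMethod("monophylyFlags", "Phylogrouping", function(x) x@monophyletic)

#' @rdname Phylogrouping-class
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname Phylogrouping-class
#' @export
setMethod("objectiveValue", "Phylogrouping", function(x) x@objective)

setMethod("show", "Phylogrouping", function(object) {
    cat("Phylogrouping |", length(unique(object@assignment)), "groups over",
        length(object@assignment), "taxa | objective",
        signif(object@objective, 4), "| monophyletic:",
        sum(object@monophyletic), "/", length(object@monophyletic), "\n")
})
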