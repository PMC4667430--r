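test_that("zero-rate configurations give sequence-identical genomes", {
    cfg <- simConfig(n_taxa = 2, core_size = 5, accessory_pool = 0,
                     subst_rate = 0, gain_rate = 0, loss_rate = 0,
                     gene_len_mean = 300, gene_len_sd = 30, n_contigs = 1,
                     seed = 3)
    sim <- simulateClade(cfg)
    expect_identical(as.character(genomeSequence(sim$genomes[[1]])),
                     as.character(genomeSequence(sim$genomes[[2]])))
    expect_identical(unname(as.character(proteins(sim$genomes[[1]]))),
                     unname(as.character(proteins(sim$genomes[[2]]))))
})

test_that("core families are all-ones columns of the truth matrix", {
    cfg <- simConfig(n_taxa = 4, core_size = 20, accessory_pool = 0,
                     gene_len_mean = 300, gene_len_sd = 30, n_contigs = 2,
                     seed = 5)
    fm <- familyMatrix(simulateClade(cfg)$truth)
    expect_equal(ncol(fm), 20)
    expect_true(all(fm == 1))
})

test_that("same seed gives byte-identical simulator output", {
    cfg <- simConfig(n_taxa = 3, core_size = 8, accessory_pool = 4,
                     gene_len_mean = 300, gene_len_sd = 30, seed = 11,
                     n_contigs = 2)
    s1 <- simulateClade(cfg)
    s2 <- simulateClade(cfg)
    expect_identical(lapply(s1$genomes, function(g)
        as.character(contigs(g))),
        lapply(s2$genomes, function(g) as.character(contigs(g))))
    expect_identical(familyMatrix(s1$truth), familyMatrix(s2$truth))
})

test_that("family matrix is consistent with the emitted gene sets", {
    cfg <- simConfig(n_taxa = 4, core_size = 10, accessory_pool = 8,
                     gain_rate = 1, loss_rate = 0.3, gene_len_mean = 300,
                     gene_len_sd = 30, n_contigs = 2, seed = 21)
    sim <- simulateClade(cfg)
    fm <- familyMatrix(sim$truth)
    map <- sim$truth@gene_family_map
    for (g in rownames(fm)) {
        emitted <- sort(map$family_id[map$genome_id == g])
        expect_identical(emitted, sort(colnames(fm)[fm[g, ] == 1]))
        expect_setequal(map$gene_id[map$genome_id == g],
                        geneTable(sim$genomes[[g]])$gene_id)
    }
})

test_that("observed sister divergence matches the Jukes-Cantor expectation", {
    ## fixed balanced tree, unit branches: sister pairs are 2 branch lengths
    ## apart, d = 2 * subst_rate, p = 3/4 (1 - exp(-4/3 d))
    subst <- 0.05
    p_expected <- 0.75 * (1 - exp(-4 / 3 * 2 * subst))
    reps <- vapply(seq_len(50), function(r) {
        cfg <- simConfig(n_taxa = 4, core_size = 10, accessory_pool = 0,
                         subst_rate = subst, gain_rate = 0, loss_rate = 0,
                         gene_len_mean = 300, gene_len_sd = 0,
                         n_contigs = 1, seed = 1000 + r)
        sim <- simulateClade(cfg, tree = balancedTree4())
        pdiff <- function(x, y) {
            a <- strsplit(as.character(genomeSequence(x)), "")[[1]]
            b <- strsplit(as.character(genomeSequence(y)), "")[[1]]
            mean(a != b)
        }
        g <- sim$genomes
        mean(c(pdiff(g[[1]], g[[2]]), pdiff(g[[3]], g[[4]])))
    }, numeric(1))
    se <- sd(reps) / sqrt(length(reps))
    expect_lt(abs(mean(reps) - p_expected), 3 * se)
})

test_that("gain and loss event counts are Poisson with mean rate x length", {
    tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
    cfg <- simConfig(n_taxa = 3, core_size = 2, accessory_pool = 400,
                     gain_rate = 0.4, loss_rate = 0.3, subst_rate = 0,
                     gene_len_mean = 150, gene_len_sd = 0, n_contigs = 1,
                     seed = 77)
    sim <- simulateClade(cfg, tree = tree)
    ev <- sim$truth@event_counts
    exp_gain <- cfg@gain_rate * sum(ev$length * ev$gain_draws)
    expect_lt(abs(sum(ev$gain_events) - exp_gain), 3 * sqrt(exp_gain))
    exp_loss <- cfg@loss_rate * sum(ev$length * ev$loss_draws)
    expect_lt(abs(sum(ev$loss_events) - exp_loss),
              3 * sqrt(max(exp_loss, 1)))
})

test_that("accessory survival matches the per-branch loss probability", {
    ## saturating gain plants every family at the top of the first branch
    ## (root -> ancestor of A,B); survival to tip A is exp(-loss * 1)
    tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
    loss <- 0.3
    cfg <- simConfig(n_taxa = 3, core_size = 2, accessory_pool = 400,
                     gain_rate = 50, loss_rate = loss, subst_rate = 0,
                     gene_len_mean = 150, gene_len_sd = 0, n_contigs = 1,
                     seed = 9)
    fm <- familyMatrix(simulateClade(cfg, tree = tree)$truth)
    acc <- setdiff(colnames(fm), c("fam0001", "fam0002"))
    p_surv <- exp(-loss)
    ## the truth matrix keeps realised families only, so condition on the
    ## family surviving in at least one of the two descendant tips
    p_cond <- p_surv / (1 - (1 - p_surv)^2)
    for (tip in c("g01", "g02")) {
        obs <- mean(fm[tip, acc])
        se <- sqrt(p_cond * (1 - p_cond) / length(acc))
        expect_lt(abs(obs - p_cond), 3 * se)
    }
    expect_true(all(fm["g03", acc] == 0))
})

test_that("fragmentAssembly partitions the input deterministically", {
    s <- randomDna(1000)
    expect_identical(unname(fragmentAssembly(s, 1)), s)
    ctgs <- fragmentAssembly(s, 5, seed = 4)
    expect_length(ctgs, 5)
    expect_identical(paste(ctgs, collapse = ""), s)
    expect_identical(fragmentAssembly(s, 5, seed = 4), ctgs)
    expect_false(identical(unname(fragmentAssembly(s, 5, seed = 5)),
                           unname(ctgs)))
    expect_error(fragmentAssembly(s, 11), "length/100")
    expect_error(fragmentAssembly(s, 0), "length/100")
})

test_that("simulated genomes round-trip through the FASTA/TSV writers", {
    cfg <- simConfig(n_taxa = 3, core_size = 6, accessory_pool = 2,
                     gene_len_mean = 300, gene_len_sd = 30, n_contigs = 2,
                     seed = 13)
    sim <- simulateClade(cfg)
    td <- withr::local_tempdir()
    for (g in sim$genomes) {
        fa <- file.path(td, paste0(genomeId(g), ".fna"))
        writeFasta(contigs(g), fa)
        expect_identical(as.character(readFasta(fa, "DNA")),
                         as.character(contigs(g)))
        pa <- file.path(td, paste0(genomeId(g), ".faa"))
        writeFasta(proteins(g), pa)
        expect_identical(as.character(readFasta(pa, "AA")),
                         as.character(proteins(g)))
    }
    gt <- file.path(td, "genes.tsv")
    writeGeneTable(sim$genomes, gt)
    back <- readGeneTable(gt)
    orig <- do.call(rbind, lapply(sim$genomes, function(g)
        cbind(genome = genomeId(g), geneTable(g))))
    orig <- orig[order(orig$genome, orig$gene_id), ]
    expect_equal(back$start, orig$start)
    expect_equal(back$end, orig$end)
    expect_identical(back$gene_id, orig$gene_id)
})

test_that("evolveSequence applies the JC kernel and spares the frame", {
    gene <- paste0("ATG", strrep("AAA", 60))
    set.seed(1)
    out <- evolveSequence(gene, 0.3, coding = TRUE)
    expect_identical(nchar(out), nchar(gene))
    prot <- suppressWarnings(as.character(
        Biostrings::translate(Biostrings::DNAString(out))))
    expect_false(grepl("\\*", prot))
    expect_identical(evolveSequence(gene, 0), gene)
})
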