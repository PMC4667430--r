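test_that("the spacer has the documented structure", {
    sp <- contigSpacer()
    expect_equal(nchar(sp), 36)
    ## palindromic core: the spacer is its own reverse complement over the
    ## non-N body, so both strands present the same stop-rich sequence
    expect_identical(
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(gsub("N", "", sp)))),
        gsub("N", "", sp))
    ## stop codons in all six frames between the N-blocks
    body <- gsub("N", "", sp)
    for (s in c(body, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(body))))) {
        for (f in 0:2) {
            codons <- substring(s, seq(1 + f, nchar(s) - 2, 3),
                                seq(3 + f, nchar(s), 3))
            expect_true(any(codons %in% c("TAA", "TAG", "TGA")))
        }
    }
})

test_that("spacer insertion places the spacer between contigs", {
    ins <- insertContigSpacers(c("ACGT", "GGCC"))
    expect_equal(nchar(ins$sequence), 44)
    expect_identical(substr(ins$sequence, 5, 40), contigSpacer())
    single <- insertContigSpacers("ACGTACGT")
    expect_identical(single$sequence, "ACGTACGT")
    expect_equal(nrow(single$offsets), 1)
    expect_error(insertContigSpacers(character(0)), "non-empty")
    expect_error(insertContigSpacers(c("ACG", "")), "non-empty")
})

test_that("spacer insertion and removal are an exact inversion pair", {
    set.seed(139)
    for (r in 1:10) {
        ctgs <- replicate(sample(1:6, 1), randomDna(sample(20:200, 1)))
        ins <- insertContigSpacers(ctgs)
        expect_identical(unname(removeContigSpacers(ins$sequence,
                                                    ins$offsets)),
                         ctgs)
    }
})

test_that("partial-gene status is read off the artificial ends", {
    ends <- artificialEnds()
    genes <- c(paste0("ATGAAACCC", ends[["end3"]]),
               paste0(ends[["end5"]], "AAACCCTGA"),
               "ATGAAACCCTGA",
               paste0(ends[["end5"]], "ATGCC", ends[["end3"]]))
    expect_identical(classifyPartialGenes(genes),
                     c("missing3", "missing5", "complete", "missing_both"))
})

test_that("planted CEP architectures are recovered exactly", {
    set.seed(149)
    for (i in 1:30) {
        d <- randomCEPDescriptor()
        p <- plantCEP(d, protein_id = sprintf("cep%02d", i))
        rec <- classifyCEP(p$protein, p$domain_hits,
                           partial_status = p$partial_status,
                           protein_id = sprintf("cep%02d", i))
        expect_false(is.null(rec))
        expect_identical(rec$anchor, d$anchor)
        expect_identical(unname(rec$triad), unname(p$expected$triad))
        expect_identical(rec$domains, p$expected$domains)
    }
})

test_that("triad residues out of order cause rejection", {
    set.seed(151)
    d <- randomCEPDescriptor()
    d$anchor <- "LPXTG"; d$domains <- c("PA")
    ## swap His before Asp
    tmp <- d$d_pos; d$d_pos <- d$h_pos; d$h_pos <- tmp
    p <- plantCEP(d)
    expect_null(classifyCEP(p$protein, p$domain_hits))
    ## Ser before His
    d2 <- randomCEPDescriptor()
    d2$anchor <- "none"; d2$domains <- character(0)
    tmp <- d2$h_pos; d2$h_pos <- d2$s_pos; d2$s_pos <- tmp
    p2 <- plantCEP(d2)
    expect_null(classifyCEP(p2$protein, p2$domain_hits))
})

test_that("anchor precedence follows truncated > LPXTG > derivative > SLAP", {
    set.seed(157)
    ## SLAP domain plus canonical motif: motif wins
    d <- randomCEPDescriptor()
    d$anchor <- "LPXTG"; d$domains <- c("Fn1", "SLAP")
    p <- plantCEP(d)
    expect_identical(classifyCEP(p$protein, p$domain_hits)$anchor, "LPXTG")
    ## truncation beats everything
    rec <- classifyCEP(p$protein, p$domain_hits, partial_status = "missing3")
    expect_identical(rec$anchor, "truncated")
    ## SLAP fallback when no motif present
    d2 <- randomCEPDescriptor()
    d2$anchor <- "SLAP"; d2$domains <- union(d2$domains, "SLAP")
    p2 <- plantCEP(d2)
    expect_identical(classifyCEP(p2$protein, p2$domain_hits)$anchor, "SLAP")
})

test_that("contradictory descriptors and bad spans are rejected", {
    set.seed(163)
    d <- randomCEPDescriptor()
    d$anchor <- "SLAP"; d$domains <- setdiff(d$domains, "SLAP")
    expect_error(plantCEP(d), "contradictory")
    d2 <- randomCEPDescriptor()
    d2$anchor <- "none"; d2$domains <- union(d2$domains, "SLAP")
    expect_error(plantCEP(d2), "contradictory")
    ## domain span outside the protein errors
    d3 <- randomCEPDescriptor(); d3$anchor <- "none"
    d3$domains <- setdiff(d3$domains, "SLAP")
    p3 <- plantCEP(d3)
    bad <- p3$domain_hits
    bad$end[1] <- d3$length + 50
    expect_error(classifyCEP(p3$protein, bad), "span outside")
})

test_that("candidates outside the plausible length range are rejected", {
    set.seed(167)
    d <- randomCEPDescriptor(length = 1200)
    d$anchor <- "none"; d$domains <- setdiff(d$domains, "SLAP")
    p <- plantCEP(d)
    expect_null(classifyCEP(p$protein, p$domain_hits,
                            length_range = c(1300, 2600)))
    expect_false(is.null(classifyCEP(p$protein, p$domain_hits,
                                     length_range = c(800, 2600))))
})

test_that("the plasmid rule is inclusive at 25/25/70 and monotone", {
    cl <- c(c1 = 10000)
    pl <- c(p1 = 10000)
    boundary <- data.frame(contig_id = "c1", plasmid_id = "p1",
                           contig_aligned_len = 2500,
                           plasmid_covered_len = 2500, identity = 70)
    expect_true(assignPlasmidContigs(boundary, cl, pl)$assigned)
    below_contig <- transform(boundary, contig_aligned_len = 2400)
    expect_false(assignPlasmidContigs(below_contig, cl, pl)$assigned)
    below_plasmid <- transform(boundary, plasmid_covered_len = 2400)
    expect_false(assignPlasmidContigs(below_plasmid, cl, pl)$assigned)
    below_id <- transform(boundary, identity = 69.9)
    expect_false(assignPlasmidContigs(below_id, cl, pl)$assigned)
    ## a clear pass
    clear <- data.frame(contig_id = "c1", plasmid_id = "p1",
                        contig_aligned_len = 3000,
                        plasmid_covered_len = 2600, identity = 80)
    expect_true(assignPlasmidContigs(clear, cl, pl)$assigned)
    ## monotone: adding a passing alignment never flips assigned -> not
    set.seed(173)
    for (r in 1:10) {
        h <- data.frame(contig_id = "c1", plasmid_id = "p1",
                        contig_aligned_len = sample(2500:6000, 1),
                        plasmid_covered_len = sample(2500:6000, 1),
                        identity = runif(1, 70, 100))
        extra <- data.frame(contig_id = "c2", plasmid_id = "p1",
                            contig_aligned_len = 1500,
                            plasmid_covered_len = sample(500:2000, 1),
                            identity = runif(1, 75, 100))
        cl2 <- c(c1 = 10000, c2 = 1500)   # extra contig fully aligned
        before <- assignPlasmidContigs(h, cl2, pl)$assigned
        after <- assignPlasmidContigs(rbind(h, extra), cl2, pl)$assigned
        if (before) expect_true(after)
    }
    expect_error(assignPlasmidContigs(boundary, c(c1 = 0), pl), "positive")
})

test_that("cazyme reconciliation keeps common and confirmed-unique calls", {
    hmm <- data.frame(gene_id = c("x", "y", "w"),
                      family = c("GH13", "GH49", "GT4"),
                      evalue = c(1e-10, 1e-8, 1e-3),
                      pfam_confirmed = c(FALSE, TRUE, TRUE))
    bl <- data.frame(gene_id = c("x", "z", "v"),
                     family = c("GH13", "GT2", "GH1"),
                     evalue = c(1e-20, 1e-9, 1e-9),
                     identity = c(80, 70, 30),
                     coverage = c(90, 80, 90),
                     pfam_confirmed = c(FALSE, FALSE, TRUE))
    gg <- c(x = "g1", y = "g1", z = "g2", w = "g2", v = "g2")
    rc <- reconcileCazymeHits(hmm, bl, gg)
    ## x: common -> kept; y: HMM-only but confirmed -> kept;
    ## z: blast-only unconfirmed -> dropped; w: HMM e-value fails -> dropped;
    ## v: blast identity fails -> dropped
    expect_setequal(rc$calls$gene_id, c("x", "y"))
    expect_equal(rc$copy_number["g1", "GH13"], 1)
    expect_equal(rc$copy_number["g1", "GH49"], 1)
    expect_false(any(rc$calls$conflict))
    ## conflicting families for a common gene: both kept, flagged
    hmm2 <- data.frame(gene_id = c("x", "x"), family = c("GH13", "GH31"),
                       evalue = 1e-10, pfam_confirmed = FALSE)
    bl2 <- data.frame(gene_id = c("x", "x"), family = c("GH13", "GH31"),
                      evalue = 1e-10, identity = 80, coverage = 90,
                      pfam_confirmed = FALSE)
    rc2 <- reconcileCazymeHits(hmm2, bl2, c(x = "g1"))
    expect_equal(nrow(rc2$calls), 2)
    expect_true(all(rc2$calls$conflict))
    ## output is a subset of the union and a superset of the intersection
    expect_true(all(paste(rc$calls$gene_id, rc$calls$family) %in%
                    c(paste(hmm$gene_id, hmm$family),
                      paste(bl$gene_id, bl$family))))
    expect_true("x GH13" %in% paste(rc$calls$gene_id, rc$calls$family))
})

test_that("screen outputs are invariant to input row order", {
    set.seed(179)
    hmm <- data.frame(gene_id = sprintf("g%d", 1:6),
                      family = sprintf("GH%d", c(13, 13, 2, 4, 5, 31)),
                      evalue = 1e-10, pfam_confirmed = TRUE)
    bl <- data.frame(gene_id = sprintf("g%d", c(1, 3, 5)),
                     family = sprintf("GH%d", c(13, 2, 5)),
                     evalue = 1e-10, identity = 80, coverage = 90,
                     pfam_confirmed = FALSE)
    gg <- setNames(rep(c("a", "b"), 3), sprintf("g%d", 1:6))
    r1 <- reconcileCazymeHits(hmm, bl, gg)
    r2 <- reconcileCazymeHits(hmm[sample(6), ], bl[sample(3), ], gg)
    expect_identical(r1$calls, r2$calls)
    expect_identical(r1$copy_number, r2$copy_number)
})

test_that("the glycolysis matrix honors both evidence paths and the PGM rule", {
    ann <- data.frame(genome_id = c("g1", "g2"), gene = c("glk", "fba"))
    conf <- data.frame(genome_id = "g1", gene = "eno")
    pgm <- data.frame(genome_id = c("g1", "g2", "g3"),
                      bitscore = c(101, 100, 250))
    m <- glycolysisMatrix(ann, conf, pgm, genomes = c("g1", "g2", "g3"))
    expect_equal(m["g1", "glk"], 1)   # annotation path
    expect_equal(m["g1", "eno"], 1)   # confirmed-hit path
    expect_equal(m["g2", "eno"], 0)
    expect_equal(m["g1", "pgm"], 1)   # bit score 101 > 100
    expect_equal(m["g2", "pgm"], 0)   # bit score 100 is not > 100
    expect_equal(m["g3", "pgm"], 1)
})

test_that("Kruskal-Wallis matches the direct rank-sum oracle", {
    set.seed(181)
    ## two fully separated groups, n = 5 each
    vals <- c(1:5, 101:105)
    grp <- rep(c("low", "high"), each = 5)
    ft <- matrix(vals, ncol = 1,
                 dimnames = list(sprintf("g%02d", 1:10), "feat"))
    res <- nicheAssociation(ft, setNames(grp, rownames(ft)),
                            min_group_size = 2)
    expect_equal(res$H, oracleKruskalH(vals, grp))
    ## a 2-group n=10 case with ties
    vals2 <- c(rpois(10, 4), rpois(10, 7))
    grp2 <- rep(c("a", "b"), each = 10)
    ft2 <- matrix(vals2, ncol = 1,
                  dimnames = list(sprintf("g%02d", 1:20), "feat"))
    res2 <- nicheAssociation(ft2, setNames(grp2, rownames(ft2)),
                             min_group_size = 2)
    expect_equal(res2$H, oracleKruskalH(vals2, grp2))
})

test_that("constant features give H = 0 and permutations change nothing", {
    set.seed(191)
    ft <- matrix(c(rep(2, 12), rpois(12, 5)), ncol = 2,
                 dimnames = list(sprintf("g%02d", 1:12),
                                 c("const", "var")))
    niches <- setNames(rep(c("food", "animal", "plant"), each = 4),
                       rownames(ft))
    res <- nicheAssociation(ft, niches)
    expect_equal(res$H[res$feature == "const"], 0)
    expect_equal(res$p_value[res$feature == "const"], 1)
    perm <- sample(rownames(ft))
    res2 <- nicheAssociation(ft[perm, ], niches)
    expect_equal(res2$H, res$H)
    expect_equal(res2$p_value, res$p_value)
})

test_that("undersized niche groups are excluded with a warning", {
    ft <- matrix(1:10, ncol = 1,
                 dimnames = list(sprintf("g%02d", 1:10), "f"))
    niches <- setNames(c(rep("food", 5), rep("animal", 4), "env"),
                       rownames(ft))
    expect_warning(res <- nicheAssociation(ft, niches, min_group_size = 3),
                   "env")
    expect_equal(res$n, 9)
    expect_error(suppressWarnings(
        nicheAssociation(ft[1:6, , drop = FALSE],
                         setNames(c(rep("food", 5), "env"),
                                  sprintf("g%02d", 1:6)),
                         min_group_size = 3)),
        "two niche groups")
})
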