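test_that("a single genome of unrelated genes yields one family per gene", {
    set.seed(31)
    prot <- list(g1 = Biostrings::AAStringSet(setNames(
        replicate(8, randomProtein(120)), sprintf("g1_%02d", 1:8))))
    pan <- accumulatePanFamilies(prot, seed = 1, n_perm = 3)
    expect_length(panFamilies(pan), 8)
})

test_that("two identical genomes add nothing to the pan size", {
    set.seed(37)
    seqs <- setNames(replicate(6, randomProtein(120)), sprintf("f%02d", 1:6))
    prot <- list(
        g1 = Biostrings::AAStringSet(setNames(seqs, paste0("g1_", names(seqs)))),
        g2 = Biostrings::AAStringSet(setNames(seqs, paste0("g2_", names(seqs)))))
    pan <- accumulatePanFamilies(prot, seed = 1, n_perm = 3)
    expect_length(panFamilies(pan), 6)
    expect_equal(unname(panCurve(pan)$mean), c(6, 6))
    expect_equal(unname(coreCurve(pan)$mean), c(6, 6))
})

test_that("planted shared families match the transitive-closure oracle", {
    ## families {A,B}, {A,C}, {A,D} share ~90%-identity homologs; everything
    ## else is unrelated, so greedy accumulation must find 4 families for
    ## the A-homolog group plus one per remaining planted family
    set.seed(41)
    prot <- plantedProteomes(
        spec = list(c("A", "B"), c("A", "C"), c("A", "D")),
        genomes = c("A", "B", "C", "D"))
    pan <- accumulatePanFamilies(prot, seed = 2, n_perm = 3)
    oracle <- oracleClosureFamilies(prot)
    got <- canonicalPartition(lapply(panFamilies(pan), function(f)
        f$members$gene_id))
    expect_equal(got, canonicalPartition(oracle))
    expect_length(panFamilies(pan), 3)
})

test_that("identical proteomes give a perfect reciprocal-best-hit matching", {
    set.seed(43)
    seqs <- setNames(replicate(6, randomProtein(110)), sprintf("f%02d", 1:6))
    a <- Biostrings::AAStringSet(setNames(seqs, paste0("a_", names(seqs))))
    b <- Biostrings::AAStringSet(setNames(seqs, paste0("b_", names(seqs))))
    rbh <- rbhOrthologs(a, b)
    expect_equal(nrow(rbh), 6)
    expect_identical(sub("^a_", "", rbh$gene_a), sub("^b_", "", rbh$gene_b))
})

test_that("genes private to one genome are excluded from the RBH set", {
    set.seed(47)
    shared <- randomProtein(110)
    a <- Biostrings::AAStringSet(c(a_s = shared, a_priv = randomProtein(110)))
    b <- Biostrings::AAStringSet(c(b_s = mutateProtein(shared, 8)))
    rbh <- rbhOrthologs(a, b)
    expect_equal(nrow(rbh), 1)
    expect_identical(rbh$gene_a, "a_s")
})

test_that("a duplicated gene contributes exactly one RBH pair, the best one", {
    set.seed(53)
    anc <- randomProtein(120)
    a <- Biostrings::AAStringSet(c(
        a_dup1 = mutateProtein(anc, 2),    # closer copy
        a_dup2 = mutateProtein(anc, 20)))  # farther paralog
    b <- Biostrings::AAStringSet(c(b_orth = anc))
    rbh <- rbhOrthologs(a, b)
    expect_equal(nrow(rbh), 1)
    expect_identical(rbh$gene_a, "a_dup1")
    ## exhaustive check: dup1 really does score higher than dup2 against b
    s1 <- localAlign(as.character(a[["a_dup1"]]), anc)$score
    s2 <- localAlign(as.character(a[["a_dup2"]]), anc)$score
    expect_gt(s1, s2)
})

test_that("two disconnected cliques cluster into two families", {
    e <- data.frame(gene_a = c("a1", "a1", "a2", "b1", "b1", "b2"),
                    gene_b = c("a2", "a3", "a3", "b2", "b3", "b3"),
                    identity_pct = 90)
    fams <- twoStageCluster(e, nodes = c("a1", "a2", "a3", "b1", "b2", "b3"))
    expect_equal(canonicalPartition(fams),
                 canonicalPartition(list(c("a1", "a2", "a3"),
                                         c("b1", "b2", "b3"))))
})

test_that("an empty edge set yields singleton families", {
    e <- data.frame(gene_a = character(0), gene_b = character(0),
                    identity_pct = numeric(0))
    fams <- twoStageCluster(e, nodes = c("x", "y", "z"))
    expect_equal(canonicalPartition(fams),
                 canonicalPartition(list("x", "y", "z")))
})

test_that("MCL splits a weak bridge and single linkage re-joins it", {
    ## two 6-node cliques (weight 90) joined by one weak bridge (weight 26)
    cliq <- function(p) {
        cmb <- t(combn(sprintf("%s%d", p, 1:6), 2))
        data.frame(gene_a = cmb[, 1], gene_b = cmb[, 2], identity_pct = 90)
    }
    e <- rbind(cliq("L"), cliq("R"),
               data.frame(gene_a = "L1", gene_b = "R1", identity_pct = 26))
    nodes <- c(sprintf("L%d", 1:6), sprintf("R%d", 1:6))
    ## stage one alone must split the bridge (checked against the
    ## independent full-matrix MCL oracle) ...
    W <- matrix(0, 12, 12, dimnames = list(nodes, nodes))
    W[cbind(e$gene_a, e$gene_b)] <- e$identity_pct
    W[cbind(e$gene_b, e$gene_a)] <- e$identity_pct
    oracle <- oracleMcl(W)
    expect_equal(length(oracle), 2)
    mcl <- CladeScope:::.mclCluster(W)
    expect_equal(canonicalPartition(lapply(mcl, function(i) nodes[i])),
                 canonicalPartition(lapply(oracle, function(i) nodes[i])))
    ## ... and the single-linkage stage re-joins the bridged clusters
    fams <- twoStageCluster(e, nodes = nodes)
    expect_equal(canonicalPartition(fams),
                 canonicalPartition(list(sort(nodes))))
})

test_that("core selection keeps exactly the families present in all genomes", {
    fams <- list(c("g1_a", "g2_a", "g3_a"), c("g1_b", "g2_b"),
                 c("g3_c"))
    gg <- setNames(sub("_.*", "", unlist(fams)), unlist(fams))
    core <- coreFamilies(fams, gg, c("g1", "g2", "g3"))
    expect_equal(core, fams[1])
})

test_that("families partition the gene universe", {
    set.seed(59)
    prot <- plantedProteomes(
        spec = list(c("A", "B", "C"), c("A", "B"), c("B", "C"), "A", "C"),
        genomes = c("A", "B", "C"))
    bg <- buildGeneFamilies(prot)
    all_genes <- sort(unlist(lapply(bg$families, identity)))
    expect_identical(all_genes, sort(names(bg$gene_genome)))
    expect_false(anyDuplicated(unlist(bg$families)) > 0)
})

test_that("dropping no taxa reproduces the full core", {
    set.seed(61)
    prot <- plantedProteomes(
        spec = list(c("A", "B", "C"), c("A", "B", "C"), c("A", "B")),
        genomes = c("A", "B", "C"))
    base <- buildGeneFamilies(prot)
    base_core <- coreFamilies(base$families, base$gene_genome,
                              c("A", "B", "C"))
    drop0 <- taxonDropoutCore(prot, character(0))
    expect_equal(drop0$core_count, length(base_core))
})

test_that("excluding the genome missing a family brings it into the core", {
    set.seed(67)
    ## families 1-3 universal; family 4 missing from C only
    prot <- plantedProteomes(
        spec = list(c("A", "B", "C"), c("A", "B", "C"), c("A", "B", "C"),
                    c("A", "B")),
        genomes = c("A", "B", "C"))
    full <- taxonDropoutCore(prot, character(0))
    dropC <- taxonDropoutCore(prot, "C")
    expect_equal(full$core_count, 3)
    expect_equal(dropC$core_count, 4)
    expect_error(taxonDropoutCore(prot, c("A", "B")), "two genomes")
})

test_that("pan curves are monotone and bounded by the core curves", {
    set.seed(71)
    spec <- lapply(1:12, function(i)
        sample(c("A", "B", "C", "D"), sample(1:4, 1)))
    spec <- c(spec, list(c("A", "B", "C", "D")))   # ensure a shared family
    prot <- plantedProteomes(spec, c("A", "B", "C", "D"))
    pan <- accumulatePanFamilies(prot, seed = 3, n_perm = 20)
    cur <- panCurves(familyPresence(pan), n_perm = 20, seed = 9)
    expect_true(all(apply(cur$pan_perm, 1, function(r) all(diff(r) >= 0))))
    expect_true(all(apply(cur$core_perm, 1, function(r) all(diff(r) <= 0))))
    expect_true(all(cur$pan_perm >= cur$core_perm))
    ## core <= smallest per-genome family count
    expect_lte(min(cur$core_perm),
               min(colSums(familyPresence(pan) > 0)))
})

test_that("fragmentation levels subset the genomes they should", {
    set.seed(73)
    prot <- plantedProteomes(
        spec = list(c("A", "B", "C", "D"), c("A", "B", "C", "D"),
                    c("A", "B"), c("C", "D")),
        genomes = c("A", "B", "C", "D"))
    cc <- c(A = 10, B = 30, C = 60, D = 300)
    fs <- fragmentationSensitivity(prot, cc, levels = c(20, 50, 100),
                                   n_perm = 3, seed = 5)
    expect_identical(fs$levels[["20"]]$retained, "A")
    expect_null(fs$levels[["20"]]$pan_curve)
    expect_identical(fs$levels[["50"]]$retained, c("A", "B"))
    expect_identical(fs$levels[["100"]]$retained, c("A", "B", "C"))
    expect_equal(nrow(fs$levels[["100"]]$pan_curve), 3)
})

test_that("constant marker counts give Spearman rho 0 under the ties policy", {
    set.seed(79)
    prot <- plantedProteomes(
        spec = list(c("A", "B", "C"), c("A", "B", "C")),
        genomes = c("A", "B", "C"))
    fs <- fragmentationSensitivity(
        prot, c(A = 5, B = 50, C = 500), levels = c(100),
        n_perm = 2, seed = 1, marker_counts = c(A = 2, B = 2, C = 2))
    expect_equal(fs$marker_spearman$rho, 0)
    ## and a perfectly anti-correlated case recovers rho = -1
    fs2 <- fragmentationSensitivity(
        prot, c(A = 5, B = 50, C = 500), levels = c(100),
        n_perm = 2, seed = 1, marker_counts = c(A = 9, B = 8, C = 7))
    expect_equal(fs2$marker_spearman$rho, -1)
})
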