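## Shared fixture: a 10-genome cohort with the partner planted in the
## query's directon in 6 genomes.
ctxCohort <- local({
    spec <- smallCohortSpec(seed = 2024L)
    co <- generateCohort(spec)
    seeds <- querySeeds(co$truth)
    edges <- buildSimilarityGraph(co$proteins[names(co$proteins) %in%
        co$truth$geneFamilies$gene_id[
            co$truth$geneFamilies$family_id != "background"]])
    cs <- annotateClusters(
        clusterSingleLinkage(names(co$proteins), edges),
        co$truth$architectures)
    list(co = co, seeds = seeds, cs = cs)
})

test_that("one neighborhood is collected per seed, none for absent genomes", {
    nbhs <- collectNeighborhoods(ctxCohort$co$genomes, ctxCohort$seeds)
    expect_equal(length(nbhs), length(unlist(ctxCohort$seeds)))
    sub <- collectNeighborhoods(ctxCohort$co$genomes,
                                ctxCohort$seeds[1:3])
    expect_equal(length(sub), length(unlist(ctxCohort$seeds[1:3])))
    expect_equal(length(collectNeighborhoods(ctxCohort$co$genomes,
                                             list())), 0L)
    badSeeds <- list(G01 = "not_a_gene")
    expect_error(collectNeighborhoods(ctxCohort$co$genomes, badSeeds),
                 "not_a_gene")
})

test_that("planted partners are recovered with ground-truth genome counts", {
    nbhs <- collectNeighborhoods(ctxCohort$co$genomes, ctxCohort$seeds)
    assoc <- scoreAssociations(nbhs, ctxCohort$cs,
                               contextConfig(minGenomes = 3L))
    expect_true("PTN" %in% assoc$partner_key)
    planted <- ctxCohort$co$truth$plantedAssociations
    expect_equal(assoc$n_genomes_same_directon[assoc$partner_key == "PTN"],
                 length(unique(planted$genome_id)))
    ## planted partner genes sit inside the query window in every genome
    for (nbh in nbhs) {
        gid <- genomeId(nbh)
        if (!gid %in% planted$genome_id) next
        tf <- ctxCohort$co$truth$geneFamilies
        ptn <- tf$gene_id[tf$genome_id == gid & tf$family_id == "PTN"]
        expect_true(any(ptn %in% neighbors(nbh)$gene_id))
    }
})

test_that("the query family itself is never reported as a partner", {
    nbhs <- collectNeighborhoods(ctxCohort$co$genomes, ctxCohort$seeds)
    assoc <- scoreAssociations(nbhs, ctxCohort$cs,
                               contextConfig(minGenomes = 1L))
    expect_false("QRY" %in% assoc$partner_key)
})

test_that("the minimum-genome threshold gates reporting", {
    nbhs <- collectNeighborhoods(ctxCohort$co$genomes, ctxCohort$seeds)
    assoc <- scoreAssociations(nbhs, ctxCohort$cs,
                               contextConfig(minGenomes = 3L))
    nPTN <- assoc$n_genomes_neighborhood[assoc$partner_key == "PTN"]
    high <- scoreAssociations(nbhs, ctxCohort$cs,
                              contextConfig(minGenomes = nPTN + 1L))
    expect_false("PTN" %in% high$partner_key)
})

test_that("RNA neighbors aggregate under normalized kind:product keys", {
    fam <- data.frame(
        family_id = c("QRY", "TLEU"), ancestor_length = c(150L, 90L),
        divergence = c(0.2, 0), presence_fraction = c(1, 1),
        kind = c("CDS", "tRNA"), product = c("", "tRNA-Leu-1"),
        stringsAsFactors = FALSE)
    ctx <- data.frame(query_family = "QRY", partner_family = "TLEU",
                      same_directon = TRUE, presence_fraction = 1,
                      max_offset = 5L)
    co <- generateCohort(simulationSpec(
        nGenomes = 5L, genesPerGenome = 30L, families = fam,
        plantedContexts = ctx, rngSeed = 31L))
    seeds <- querySeeds(co$truth)
    edges <- buildSimilarityGraph(co$proteins[names(co$proteins) %in%
        names(co$truth$architectures)])
    cs <- annotateClusters(clusterSingleLinkage(names(co$proteins), edges),
                           co$truth$architectures)
    nbhs <- collectNeighborhoods(co$genomes, seeds)
    assoc <- scoreAssociations(nbhs, cs, contextConfig(minGenomes = 3L))
    expect_true("tRNA:trna-leu" %in% assoc$partner_key)
    expect_equal(
        assoc$n_genomes_same_directon[assoc$partner_key == "tRNA:trna-leu"],
        5L)
})

test_that("taxon groups collapse genome counts to one per group", {
    nbhs <- collectNeighborhoods(ctxCohort$co$genomes, ctxCohort$seeds)
    groups <- stats::setNames(
        rep(c("cladeA", "cladeB"), length.out = 10L),
        sprintf("G%02d", 1:10))
    assoc <- scoreAssociations(nbhs, ctxCohort$cs,
                               contextConfig(minGenomes = 1L),
                               taxonGroups = groups)
    expect_lte(max(assoc$n_genomes_neighborhood), 2L)
})

test_that("permutation p reaches the add-one floor for a perfect context", {
    spec <- smallCohortSpec(seed = 2025L, nGenomes = 10L,
                            genesPerGenome = 60L, partnerFraction = 1)
    co <- generateCohort(spec)
    seeds <- querySeeds(co$truth)
    edges <- buildSimilarityGraph(co$proteins[names(co$proteins) %in%
        names(co$truth$architectures)])
    cs <- annotateClusters(clusterSingleLinkage(names(co$proteins), edges),
                           co$truth$architectures)
    pn <- permutationNull(co$genomes, seeds, "PTN", cs,
                          neighborhoodConfig(),
                          contextConfig(nPermutations = 999L,
                                        rngSeed = 9L))
    expect_equal(pn$observed, 10L)
    expect_equal(pn$p_empirical, 1 / 1000)
})

test_that("an absent partner gives observed 0 and p = 1", {
    pn <- permutationNull(ctxCohort$co$genomes, ctxCohort$seeds,
                          "tRNA:trna-xyz", ctxCohort$cs,
                          neighborhoodConfig(),
                          contextConfig(nPermutations = 49L, rngSeed = 4L))
    expect_equal(pn$observed, 0L)
    expect_equal(pn$p_empirical, 1)
})

test_that("permutation p-values are deterministic under the seed", {
    cfg <- contextConfig(nPermutations = 99L, rngSeed = 123L)
    p1 <- permutationNull(ctxCohort$co$genomes, ctxCohort$seeds, "PTN",
                          ctxCohort$cs, neighborhoodConfig(), cfg)
    p2 <- permutationNull(ctxCohort$co$genomes, ctxCohort$seeds, "PTN",
                          ctxCohort$cs, neighborhoodConfig(), cfg)
    expect_identical(p1, p2)
    expect_gte(p1$p_empirical, 1 / 100)
    expect_lte(p1$p_empirical, 1)
})

test_that("a shared family placed uniformly is not called significant", {
    ## null cohort: partner present everywhere but never planted near the
    ## query; the permutation p should look uniform, not extreme
    ps <- numeric(0)
    for (seed in 101:106) {
        fam <- data.frame(
            family_id = c("QRY", "RND"), ancestor_length = c(150L, 120L),
            divergence = c(0.2, 0.2), presence_fraction = c(1, 1))
        co <- generateCohort(simulationSpec(
            nGenomes = 8L, genesPerGenome = 50L, families = fam,
            rngSeed = seed))
        seeds <- querySeeds(co$truth)
        edges <- buildSimilarityGraph(co$proteins[names(co$proteins) %in%
            names(co$truth$architectures)])
        cs <- annotateClusters(
            clusterSingleLinkage(names(co$proteins), edges),
            co$truth$architectures)
        pn <- permutationNull(co$genomes, seeds, "RND", cs,
                              neighborhoodConfig(),
                              contextConfig(nPermutations = 99L,
                                            rngSeed = seed,
                                            countMode = "any_neighbor"))
        ps <- c(ps, pn$p_empirical)
    }
    expect_lte(mean(ps <= 0.05), 1 / 6)   # at most one accidental hit
})
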