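test_that("self-alignment gives full identity and coverage", {
    s <- rndProt(100)
    res <- alignPair(s, s)
    expect_equal(res$identity, 1.0)
    expect_equal(res$coverage_a, 1.0)
    expect_equal(res$coverage_b, 1.0)
    expect_gt(res$score, 0)
})

test_that("pairs with no positive-scoring residue give the empty alignment", {
    res <- alignPair("WWWW", "PPPP")
    expect_equal(res$score, 0)
    expect_equal(res$identity, 0)
    expect_equal(res$coverage_a, 0)
    expect_equal(res$coverage_b, 0)
    expect_error(alignPair("", "MKL"), "empty sequence")
})

test_that("alignment scores match an independent dynamic-programming oracle", {
    set.seed(404)
    for (i in 1:50) {
        a <- rndProt(sample(5:30, 1L))
        b <- rndProt(sample(5:30, 1L))
        expect_equal(alignPair(a, b)$score,
                     swScoreOracle(a, b, blosum62), tolerance = 1e-9)
    }
})

test_that("alignment metrics are symmetric in argument order", {
    set.seed(405)
    for (i in 1:20) {
        a <- rndProt(sample(30:80, 1L)); b <- rndProt(sample(30:80, 1L))
        ab <- alignPair(a, b); ba <- alignPair(b, a)
        expect_equal(ab$score, ba$score)
        expect_equal(ab$identity, ba$identity)
        expect_equal(ab$coverage_a, ba$coverage_b)
        expect_equal(ab$coverage_b, ba$coverage_a)
    }
})

test_that("similarity graph applies inclusive thresholds", {
    a <- rndProt(120)
    seqs <- c(x = a, y = a)
    e <- buildSimilarityGraph(seqs)
    expect_equal(nrow(e), 1L)
    expect_equal(e$identity, 1.0)

    ## measure a related pair, then bracket its identity: >= is inclusive
    set.seed(406)
    b <- evolveFamily(a, 0.3)
    m <- alignPair(a, b)
    pair <- c(x = a, y = b)
    atEdge <- buildSimilarityGraph(pair,
        clusterThresholds(minIdentity = m$identity, minCoverage = 0.5))
    expect_equal(nrow(atEdge), 1L)
    above <- buildSimilarityGraph(pair,
        clusterThresholds(minIdentity = m$identity + 1e-9,
                          minCoverage = 0.5))
    expect_equal(nrow(above), 0L)
})

test_that("similarity graph equals an unfiltered all-pairs recomputation", {
    set.seed(407)
    anc <- rndProt(90)
    seqs <- c(vapply(1:4, function(i) evolveFamily(anc, 0.2),
                     character(1)),
              vapply(1:6, function(i) rndProt(sample(60:140, 1L)),
                     character(1)))
    names(seqs) <- sprintf("s%02d", seq_along(seqs))
    th <- clusterThresholds()
    edges <- buildSimilarityGraph(seqs, th)
    got <- sort(paste(edges$id_a, edges$id_b))
    want <- character(0)
    for (j in 2:length(seqs)) {
        for (i in 1:(j - 1L)) {
            m <- alignPair(seqs[[i]], seqs[[j]])
            if (m$identity >= th$minIdentity &&
                min(m$coverage_a, m$coverage_b) >= th$minCoverage)
                want <- c(want, paste(names(seqs)[i], names(seqs)[j]))
        }
    }
    expect_identical(got, sort(want))
})

test_that("single linkage is transitive and keeps singletons apart", {
    edges <- data.frame(id_a = c("a", "b"), id_b = c("b", "c"))
    cs <- clusterSingleLinkage(c("a", "b", "c", "d", "e"), edges)
    expect_equal(lengths(clusters(cs)), c(C1 = 3L, C2 = 1L, C3 = 1L))
    expect_setequal(clusters(cs)$C1, c("a", "b", "c"))

    none <- clusterSingleLinkage(letters[1:5], edges[0, ])
    expect_equal(length(clusters(none)), 5L)
    expect_error(
        clusterSingleLinkage(c("a"), data.frame(id_a = "a", id_b = "zz")),
        "unknown ids")
})

test_that("clusters match a union-find oracle on random graphs", {
    set.seed(408)
    for (rep in 1:200) {
        n <- sample(2:50, 1L)
        ids <- sprintf("n%02d", seq_len(n))
        ne <- sample(0:min(60L, n * 2L), 1L)
        edges <- data.frame(id_a = sample(ids, ne, replace = TRUE),
                            id_b = sample(ids, ne, replace = TRUE),
                            stringsAsFactors = FALSE)
        edges <- edges[edges$id_a != edges$id_b, , drop = FALSE]
        cs <- clusterSingleLinkage(ids, edges)
        expect_identical(canonicalPartition(clusters(cs)),
                         canonicalPartition(unionFindClusters(ids, edges)))
    }
})

test_that("cluster ids are deterministic and edge-order invariant", {
    ids <- c("m", "a", "z", "k", "b", "q")
    edges <- data.frame(id_a = c("z", "m", "a"), id_b = c("k", "z", "b"))
    cs1 <- clusterSingleLinkage(ids, edges)
    cs2 <- clusterSingleLinkage(rev(ids), edges[c(3, 1, 2), ])
    expect_identical(clusters(cs1), clusters(cs2))
    ## decreasing size, ties by smallest member: {k,m,z} then {a,b} then {q}
    expect_equal(names(clusters(cs1)), c("C1", "C2", "C3"))
    expect_equal(clusters(cs1)$C1, c("k", "m", "z"))
    expect_equal(clusters(cs1)$C2, c("a", "b"))
})

test_that("raising thresholds only refines the partition", {
    set.seed(409)
    anc1 <- rndProt(100); anc2 <- rndProt(100)
    seqs <- c(vapply(1:5, function(i) evolveFamily(anc1, 0.25),
                     character(1)),
              vapply(1:5, function(i) evolveFamily(anc2, 0.25),
                     character(1)))
    names(seqs) <- sprintf("s%02d", 1:10)
    loose <- membership(clusterSingleLinkage(names(seqs),
        buildSimilarityGraph(seqs, clusterThresholds(0.25, 0.6))))
    tight <- membership(clusterSingleLinkage(names(seqs),
        buildSimilarityGraph(seqs, clusterThresholds(0.45, 0.8))))
    ## every tight cluster must lie inside one loose cluster
    for (cl in split(names(tight), tight))
        expect_equal(length(unique(loose[cl])), 1L)
})

test_that("cluster annotation takes the majority architecture", {
    cs <- clusterSingleLinkage(
        c("a", "b", "c", "d"),
        data.frame(id_a = c("a", "b", "a"), id_b = c("b", "c", "c")))
    arch <- c(a = "Hyd+ZnR", b = "Hyd+ZnR", c = "Hyd")
    labs <- clusterLabels(annotateClusters(cs, arch))
    expect_equal(unname(labs[["C1"]]), "Hyd+ZnR")
    expect_equal(unname(labs[["C2"]]), "unannotated")

    tie <- annotateClusters(cs, c(a = "B", b = "A", c = "B", d = "A"))
    expect_equal(unname(clusterLabels(tie)[["C1"]]), "B")  # majority
    cs2 <- clusterSingleLinkage(c("a", "b"),
                                data.frame(id_a = "a", id_b = "b"))
    expect_equal(
        unname(clusterLabels(annotateClusters(
            cs2, c(a = "B", b = "A")))[["C1"]]), "A")      # lexicographic
})

test_that("cluster TSV and architecture TSV round the data correctly", {
    cs <- annotateClusters(
        clusterSingleLinkage(c("a", "b", "c"),
                             data.frame(id_a = "a", id_b = "b")),
        c(a = "Hyd", b = "Hyd"))
    f <- withr::local_tempfile()
    writeClustersTsv(cs, f)
    tab <- utils::read.delim(f)
    expect_equal(tab$cluster_id, c("C1", "C2"))
    expect_equal(tab$members, c("a,b", "c"))
    expect_equal(tab$label, c("Hyd", "unannotated"))

    fa <- withr::local_tempfile(lines = c("protein_id\tarchitecture",
                                          "a\tHyd", "b\tHyd+ZnR"))
    arch <- readArchitectures(fa)
    expect_equal(arch, c(a = "Hyd", b = "Hyd+ZnR"))
})
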