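test_that("intergenic gap arithmetic covers abutting, spaced and overlap", {
    g <- makeGenome(c(1L, 101L), c(100L, 300L), c("+", "+"))
    expect_equal(intergenicGap(g, "g001", "g002"), 0L)
    g <- makeGenome(c(1L, 251L), c(100L, 500L), c("+", "+"))
    expect_equal(intergenicGap(g, "g001", "g002"), 150L)
    g <- makeGenome(c(1L, 90L), c(100L, 300L), c("+", "+"))
    expect_equal(intergenicGap(g, "g001", "g002"), -11L)
})

test_that("intergenic gap rejects non-adjacent pairs and wraps circles", {
    g <- makeGenome(c(1L, 200L, 400L), c(100L, 300L, 500L),
                    c("+", "+", "+"))
    expect_error(intergenicGap(g, "g001", "g003"), "not adjacent")
    expect_error(intergenicGap(g, "g002", "g001"), "not adjacent")
    gc <- makeGenome(c(50L, 200L), c(100L, 300L), c("+", "+"),
                     circular = TRUE, repLen = 340L)
    ## through the origin: 40 nt after g002, then 49 nt before g001
    expect_equal(intergenicGap(gc, "g002", "g001"), 89L)
})

test_that("directons split at large gaps and at strand switches", {
    g <- makeGenome(c(1L, 111L, 511L, 621L), c(100L, 300L, 600L, 700L),
                    c("+", "+", "+", "+"))
    d <- inferDirectons(g, maxGap = 150L)
    expect_equal(length(unique(d$directon_id)), 2L)
    expect_equal(d$directon_id[1L], d$directon_id[2L])
    expect_equal(d$directon_id[3L], d$directon_id[4L])

    g2 <- makeGenome(c(1L, 111L, 221L, 331L), c(100L, 210L, 320L, 430L),
                     c("+", "-", "+", "-"))
    d2 <- inferDirectons(g2, maxGap = 150L)
    expect_equal(length(unique(d2$directon_id)), 4L)
})

test_that("gap comparison is inclusive at the threshold and for overlaps", {
    g <- makeGenome(c(1L, 251L), c(100L, 400L), c("+", "+"))  # gap 150
    expect_equal(length(unique(inferDirectons(g, 150L)$directon_id)), 1L)
    expect_equal(length(unique(inferDirectons(g, 149L)$directon_id)), 2L)
    gov <- makeGenome(c(1L, 90L), c(100L, 300L), c("+", "+")) # overlap
    expect_equal(length(unique(inferDirectons(gov, 0L)$directon_id)), 1L)
})

test_that("directon inference matches the brute-force enumerator", {
    set.seed(55)
    for (rep in 1:200) {
        n <- sample(5:60, 1L)
        g <- rndGenome(n, circular = runif(1) < 0.5)
        d <- inferDirectons(g, maxGap = 150L)
        expect_identical(directonPartitionKey(d), bruteDirectons(g, 150L))
    }
})

test_that("directon inference mirrors when the genome is mirrored", {
    set.seed(66)
    for (rep in 1:20) {
        n <- sample(5:40, 1L)
        g <- rndGenome(n)
        L <- replicons(g)$length
        gg <- genes(g)
        mirrored <- data.frame(
            gene_id = gg$gene_id, replicon_id = gg$replicon_id,
            start = L - gg$end + 1L, end = L - gg$start + 1L,
            strand = ifelse(gg$strand == "+", "-", "+"),
            feature_kind = gg$feature_kind, product = gg$product,
            protein_seq = gg$protein_seq, wraps = FALSE,
            stringsAsFactors = FALSE)
        gm <- GenomeAnnotation(genomeId(g), replicons(g), mirrored)
        d <- inferDirectons(g, 150L)
        dm <- inferDirectons(gm, 150L)
        ## mirroring reverses ordinals; partitions must correspond
        n <- nrow(gg)
        remap <- split((n - 1L) - d$ordinal, d$directon_id)
        expect_identical(
            sort(unname(vapply(remap, function(x)
                paste(sort(x), collapse = ","), character(1))),
                method = "radix"),
            sort(unname(vapply(split(dm$ordinal, dm$directon_id),
                               function(x) paste(sort(x), collapse = ","),
                               character(1))), method = "radix"))
    }
})

test_that("degenerate gap bounds give whole-strand runs or singletons", {
    set.seed(77)
    g <- rndGenome(30)
    dInf <- inferDirectons(g, maxGap = Inf)
    runs <- rle(genes(g)$strand)
    expect_equal(length(unique(dInf$directon_id)), length(runs$lengths))
    dNeg <- inferDirectons(g, maxGap = -1000L)
    expect_equal(length(unique(dNeg$directon_id)), 30L)
})

test_that("head-to-head detection requires divergent strands and the gap", {
    divergent <- makeGenome(c(1L, 201L), c(100L, 400L), c("-", "+"))
    expect_equal(nrow(detectHeadToHead(divergent, 150L)), 1L)
    convergent <- makeGenome(c(1L, 201L), c(100L, 400L), c("+", "-"))
    expect_equal(nrow(detectHeadToHead(convergent, 150L)), 0L)
    far <- makeGenome(c(1L, 5101L), c(100L, 5400L), c("-", "+"))
    expect_equal(nrow(detectHeadToHead(far, 150L)), 0L)
})

test_that("default neighborhood takes five genes per side", {
    set.seed(88)
    g <- rndGenome(30, gapRange = c(200L, 400L))   # all singletons
    q <- genes(g)$gene_id[15L]
    nbh <- extractNeighborhood(g, q)
    expect_s4_class(nbh, "Neighborhood")
    expect_equal(nrow(neighbors(nbh)), 11L)
    expect_equal(neighbors(nbh)$offset, -5:5)
    expect_equal(queryId(nbh), q)
})

test_that("windows clip at linear ends and wrap on circular replicons", {
    set.seed(99)
    g <- rndGenome(100, gapRange = c(200L, 400L))
    nbh <- extractNeighborhood(g, genes(g)$gene_id[2L])
    expect_equal(neighbors(nbh)$offset, -1:5)
    gc <- rndGenome(20, circular = TRUE, gapRange = c(200L, 400L))
    nbhc <- extractNeighborhood(gc, genes(gc)$gene_id[1L])
    expect_equal(neighbors(nbhc)$offset, -5:5)
    expect_equal(neighbors(nbhc)$ordinal[1:5], 15:19)
})

test_that("a window with k covering the replicon returns every gene", {
    set.seed(111)
    gc <- rndGenome(12, circular = TRUE)
    nbh <- extractNeighborhood(gc, genes(gc)$gene_id[4L],
                               neighborhoodConfig(k = 12L))
    expect_setequal(neighbors(nbh)$gene_id, genes(gc)$gene_id)
    gl <- rndGenome(9, circular = FALSE)
    nbh2 <- extractNeighborhood(gl, genes(gl)$gene_id[4L],
                                neighborhoodConfig(k = 9L))
    expect_setequal(neighbors(nbh2)$gene_id, genes(gl)$gene_id)
})

test_that("the window grows through the query's extended directon", {
    ## 9-gene one-directon operon followed by distant genes
    n <- 12L
    starts <- integer(n); ends <- integer(n)
    pos <- 1L
    for (i in seq_len(n)) {
        starts[i] <- pos; ends[i] <- pos + 99L
        pos <- ends[i] + ifelse(i < 9L, 51L, 501L)
    }
    g <- makeGenome(starts, ends, rep("+", n))
    ## query at ordinal 1 (gene 2): directon covers ordinals 0..8,
    ## offset +7 beyond the default +5 window
    nbh <- extractNeighborhood(g, "g002")
    expect_equal(max(neighbors(nbh)$offset), 7L)
    expect_true(all(c("g008", "g009") %in% neighbors(nbh)$gene_id))
    nbh2 <- extractNeighborhood(g, "g002",
        neighborhoodConfig(extendThroughDirecton = FALSE))
    expect_equal(max(neighbors(nbh2)$offset), 5L)
})

test_that("promoter-sharing filter equals recomputation from first rules", {
    set.seed(123)
    for (rep in 1:25) {
        g <- rndGenome(sample(15:40, 1L), circular = runif(1) < 0.5,
                       gapRange = c(0L, 400L))
        q <- sample(genes(g)$gene_id, 1L)
        nbh <- extractNeighborhood(g, q)
        kept <- neighbors(filterPromoterSharing(nbh))$gene_id

        ## recompute from directons + head-to-head pairs directly
        d <- inferDirectons(g, 150L)
        h2h <- detectHeadToHead(g, 150L)
        qd <- d$directon_id[d$gene_id == q]
        expectedDirectons <- qd
        for (k in seq_len(nrow(h2h))) {
            dl <- d$directon_id[d$ordinal == h2h$left_ordinal[k]]
            dr <- d$directon_id[d$ordinal == h2h$right_ordinal[k]]
            if (qd == dl) expectedDirectons <- c(expectedDirectons, dr)
            if (qd == dr) expectedDirectons <- c(expectedDirectons, dl)
        }
        inWindow <- neighbors(nbh)$gene_id
        expectSet <- union(q, inWindow[
            d$directon_id[match(inWindow, d$gene_id)] %in%
                expectedDirectons])
        expect_setequal(kept, expectSet)
    }
})

test_that("neighborhood TSV export carries the documented columns", {
    set.seed(222)
    g <- rndGenome(20)
    f <- withr::local_tempfile()
    writeNeighborhoodTsv(extractNeighborhood(g, genes(g)$gene_id[10L]), f)
    tab <- utils::read.delim(f)
    expect_equal(names(tab),
                 c("offset", "gene_id", "start", "end", "strand",
                   "feature_kind", "directon_id", "promoter_sharing",
                   "product"))
    expect_equal(nrow(tab), 11L)
})
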