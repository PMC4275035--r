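pttLines <- function(rows, n = length(rows)) {
    c("Toy genome, complete sequence - 1..5000",
      sprintf("%d proteins", n),
      paste(c("Location", "Strand", "Length", "PID", "Gene", "Synonym",
              "Code", "COG", "Product"), collapse = "\t"),
      rows)
}

pttRow <- function(loc, strand, syn, product = "hypothetical") {
    paste(c(loc, strand, "99", "123", "-", syn, "-", "-", product),
          collapse = "\t")
}

test_that("PTT parsing yields ordered CDS records with Synonym ids", {
    f <- withr::local_tempfile(lines = pttLines(c(
        pttRow("1..300", "+", "b0001"),
        pttRow("400..900", "-", "b0002"),
        pttRow("1000..1200", "+", "b0003"))))
    g <- readPtt(f, genomeId = "toy", repliconLength = 5000L)
    expect_s4_class(g, "GenomeAnnotation")
    expect_equal(nrow(genes(g)), 3L)
    expect_equal(genes(g)$gene_id, c("b0001", "b0002", "b0003"))
    expect_equal(genes(g)$start, c(1L, 400L, 1000L))
    expect_equal(genes(g)$strand, c("+", "-", "+"))
    expect_true(all(genes(g)$feature_kind == "CDS"))
})

test_that("malformed PTT rows are rejected with the line number", {
    f <- withr::local_tempfile(lines = pttLines(c(
        pttRow("1..300", "+", "b0001"),
        pttRow("10..5", "-", "b0002"))))
    expect_error(readPtt(f, "toy", 5000L), "line 5")
    f2 <- withr::local_tempfile(lines = pttLines(c(
        pttRow("xx..300", "+", "b0001"))))
    expect_error(readPtt(f2, "toy", 5000L), "malformed Location")
    f3 <- withr::local_tempfile(lines = pttLines(c(
        pttRow("1..300", "+", "dup"),
        pttRow("400..900", "+", "dup"))))
    expect_error(readPtt(f3, "toy", 5000L), "duplicate gene_id")
})

test_that("PTT write-then-read round trip preserves generated cohorts", {
    set.seed(101)
    spec <- simulationSpec(nGenomes = 1L, genesPerGenome = 50L,
                           rngSeed = 101L)
    g <- generateCohort(spec)$genomes[[1L]]
    f <- withr::local_tempfile()
    writePtt(g, f)
    g2 <- readPtt(f, genomeId(g), replicons(g)$length,
                  circular = replicons(g)$circular,
                  repliconId = replicons(g)$replicon_id)
    expect_equal(nrow(genes(g2)), 50L)
    for (col in c("gene_id", "start", "end", "strand", "product"))
        expect_equal(genes(g2)[[col]], genes(g)[[col]])
})

gbToy <- c(
    "LOCUS       chr1             5000 bp    DNA     circular BCT 01-JAN-2000",
    "DEFINITION  toy chr1.",
    "FEATURES             Location/Qualifiers",
    "     source          1..5000",
    "     CDS             10..300",
    "                     /locus_tag=\"c0001\"",
    "                     /product=\"widget synthase\"",
    "                     /translation=\"MKL\"",
    "     CDS             complement(400..900)",
    "                     /locus_tag=\"c0002\"",
    "                     /translation=\"MAACD\"",
    "     tRNA            1000..1080",
    "                     /locus_tag=\"t0001\"",
    "                     /product=\"tRNA-Leu\"",
    "     CDS             join(4800..5000,1..99)",
    "                     /locus_tag=\"c0003\"",
    "                     /translation=\"MWWW\"",
    "//")

test_that("GenBank subset parsing handles kinds, strand, wrap and LOCUS", {
    f <- withr::local_tempfile(lines = gbToy)
    g <- readGenBank(f)
    expect_equal(genomeId(g), "toy")
    expect_true(replicons(g)$circular)
    expect_equal(replicons(g)$length, 5000L)
    gg <- genes(g)
    expect_equal(nrow(gg), 4L)
    expect_setequal(gg$feature_kind, c("CDS", "tRNA"))
    expect_equal(gg$protein_seq[gg$gene_id == "c0001"], "MKL")
    expect_equal(gg$strand[gg$gene_id == "c0002"], "-")
    expect_equal(gg$product[gg$gene_id == "t0001"], "tRNA-Leu")
    wrap <- gg[gg$gene_id == "c0003", ]
    expect_true(wrap$wraps)
    expect_equal(wrap$start, 4800L)
    expect_equal(wrap$end, 99L)
})

test_that("GenBank parsing errors on a LOCUS line without a length", {
    f <- withr::local_tempfile(lines = c("LOCUS       chr1", "//"))
    expect_error(readGenBank(f), "LOCUS")
})

test_that("GenBank write-then-read is lossless for generated annotations", {
    fam <- data.frame(family_id = "TLEU", ancestor_length = 100L,
                      divergence = 0, presence_fraction = 1,
                      kind = "tRNA", product = "tRNA-Leu")
    spec <- simulationSpec(nGenomes = 2L, genesPerGenome = 30L,
                           families = fam, rngSeed = 7L)
    co <- generateCohort(spec)
    for (g in co$genomes) {
        f <- withr::local_tempfile()
        writeGenBank(g, f)
        g2 <- readGenBank(f)
        expect_equal(genomeId(g2), genomeId(g))
        expect_equal(replicons(g2), replicons(g))
        expect_equal(genes(g2), genes(g))
    }
})

test_that("FASTA round trips preserve ids, order and sequence bytes", {
    f <- withr::local_tempfile(lines = c(">a", "MKL", ">b", "MAA"))
    x <- readFastaFile(f)
    expect_equal(length(x), 2L)
    expect_equal(names(x), c("a", "b"))
    fdup <- withr::local_tempfile(lines = c(">a", "MKL", ">a", "MAA"))
    expect_error(readFastaFile(fdup), "duplicate")

    set.seed(22)
    seqs <- vapply(1:1000, function(i) rndProt(sample(20:200, 1L)),
                   character(1))
    names(seqs) <- sprintf("p%04d", 1:1000)
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    writeFastaFile(seqs, f1, width = 60L)
    back <- readFastaFile(f1)
    expect_equal(as.character(back), seqs)
    writeFastaFile(back, f2, width = 60L)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("locateGene matches a linear scan and errors on unknown ids", {
    set.seed(33)
    g <- rndGenome(40)
    expect_equal(locateGene(g, genes(g)$gene_id[1L])$ordinal, 0L)
    expect_error(locateGene(g, "nope"), "unknown gene_id")
    for (k in sample(40, 5)) {
        id <- genes(g)$gene_id[k]
        scan <- which(genes(g)$gene_id == id) - 1L  # single replicon
        expect_equal(locateGene(g, id)$ordinal, scan)
    }
})

test_that("normalization sorts without creating or losing records", {
    set.seed(44)
    g <- rndGenome(30)
    gg <- genes(g)
    shuffled <- gg[sample(nrow(gg)), ]
    g2 <- GenomeAnnotation(genomeId(g), replicons(g), shuffled)
    expect_equal(genes(g2), gg)
})

test_that("RNA features merge from the supplementary TSV", {
    g <- makeGenome(c(100L, 1000L), c(400L, 1600L), c("+", "+"))
    f <- withr::local_tempfile(lines = c(
        "gene_id\treplicon\tstart\tend\tstrand\tkind\tproduct",
        "t001\tT\t500\t580\t+\ttRNA\ttRNA-Gly"))
    g2 <- readRnaFeatures(g, f)
    expect_equal(nrow(genes(g2)), 3L)
    expect_equal(genes(g2)$feature_kind[2L], "tRNA")
    expect_equal(genes(g2)$gene_id[2L], "t001")
})

test_that("protein joining fills CDS sequences and validates coverage", {
    g <- makeGenome(c(100L, 1000L), c(400L, 1600L), c("+", "+"))
    prots <- c(g001 = "MKTAYIAK", g002 = "MNNWVKK")
    g2 <- joinProteins(g, prots)
    expect_equal(genes(g2)$protein_seq, unname(prots))
    expect_error(joinProteins(g, prots["g001"]), "no protein sequence")
    expect_equal(as.character(genomeProteins(g2)), prots)
})
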