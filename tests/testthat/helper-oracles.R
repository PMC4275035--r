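## Independent oracles and fixture builders used across the suite.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rndProt <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

## Build a GenomeAnnotation from coordinate vectors (CDS only unless
## kinds given); protein sequences are dummies unless supplied.
makeGenome <- function(starts, ends, strands, circular = FALSE,
                       repLen = max(ends) + 500L, genomeId = "T",
                       kinds = NULL, products = NULL, seqs = NULL) {
    n <- length(starts)
    if (is.null(kinds)) kinds <- rep("CDS", n)
    if (is.null(products)) products <- rep("", n)
    if (is.null(seqs)) seqs <- ifelse(kinds == "CDS", "MKL", "")
    genes <- data.frame(
        gene_id = sprintf("g%03d", seq_len(n)), replicon_id = genomeId,
        start = as.integer(starts), end = as.integer(ends),
        strand = strands, feature_kind = kinds, product = products,
        protein_seq = seqs, wraps = FALSE, stringsAsFactors = FALSE)
    reps <- data.frame(replicon_id = genomeId, length = as.integer(repLen),
                       circular = circular, stringsAsFactors = FALSE)
    GenomeAnnotation(genomeId, reps, genes)
}

## Random toy genome: n genes, mixed strands, intergenic gaps drawn from
## gapRange, gene lengths 50-500 nt.
rndGenome <- function(n, circular = FALSE, gapRange = c(0L, 400L),
                      genomeId = "T") {
    lens <- sample(50:500, n, replace = TRUE)
    gaps <- sample(gapRange[1L]:gapRange[2L], n, replace = TRUE)
    starts <- integer(n); ends <- integer(n)
    pos <- 1L + gaps[1L]
    for (i in seq_len(n)) {
        starts[i] <- pos
        ends[i] <- pos + lens[i] - 1L
        if (i < n) pos <- ends[i] + gaps[i + 1L] + 1L
    }
    makeGenome(starts, ends, sample(c("+", "-"), n, replace = TRUE),
               circular = circular,
               repLen = ends[n] + sample(gapRange[1L]:gapRange[2L], 1L) + 1L,
               genomeId = genomeId)
}

## Brute-force directon oracle: adjacency recomputed straight from the
## coordinate columns, then each gene greedily expanded both ways;
## the set of distinct expanded runs is the expected partition.
bruteDirectons <- function(genome, maxGap) {
    g <- genes(genome)
    reps <- replicons(genome)
    runs <- list()
    for (r in seq_len(nrow(reps))) {
        rid <- reps$replicon_id[r]
        idx <- which(g$replicon_id == rid)
        gg <- g[idx, , drop = FALSE]
        n <- nrow(gg)
        if (!n) next
        ok <- logical(n)              # ok[i]: gene i links to its successor
        for (i in seq_len(n)) {
            j <- if (i < n) i + 1L else 1L
            if (i == n && (!reps$circular[r] || n == 1L)) { ok[i] <- FALSE; next }
            gap <- if (i < n) gg$start[j] - gg$end[i] - 1L else
                gg$start[1L] + (reps$length[r] - gg$end[n]) - 1L
            ok[i] <- gg$strand[i] == gg$strand[j] && gap <= maxGap
        }
        for (s in seq_len(n)) {
            members <- s
            j <- s
            while (ok[j] && length(members) < n) {       # expand right
                j <- if (j < n) j + 1L else 1L
                if (j %in% members) break
                members <- c(members, j)
            }
            i <- s
            prev <- function(x) if (x > 1L) x - 1L else n
            while (ok[prev(i)] && length(members) < n) { # expand left
                i <- prev(i)
                if (i %in% members) break
                members <- c(i, members)
            }
            runs[[length(runs) + 1L]] <-
                paste(rid, paste(sort(members), collapse = ","))
        }
    }
    sort(unique(runs <- unlist(runs)))
}

directonPartitionKey <- function(directons) {
    sp <- split(directons$ordinal + 1L,
                paste(directons$replicon_id, directons$directon_id))
    reps <- vapply(strsplit(names(sp), " "), `[`, character(1), 1L)
    sort(unique(paste(reps, vapply(sp, function(x)
        paste(sort(x), collapse = ","), character(1)))))
}

## Union-find connected-components oracle.
unionFindClusters <- function(ids, edges) {
    parent <- stats::setNames(ids, ids)
    find <- function(x) {
        while (parent[[x]] != x) {
            parent[[x]] <<- parent[[parent[[x]]]]
            x <- parent[[x]]
        }
        x
    }
    for (k in seq_len(nrow(edges))) {
        ra <- find(edges$id_a[k]); rb <- find(edges$id_b[k])
        if (ra != rb) parent[[ra]] <- rb
    }
    roots <- vapply(ids, find, character(1))
    unname(lapply(split(ids, roots), sort))
}

canonicalPartition <- function(parts) {
    sort(unname(vapply(parts, function(x) paste(sort(x), collapse = ","),
                       character(1))), method = "radix")
}

## Pure-R affine-gap Smith-Waterman score (gap of length L costs
## open + L * ext); independent of the package's C++ kernel.
swScoreOracle <- function(a, b, mat, open = 11, ext = 1) {
    A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
    la <- length(A); lb <- length(B)
    M <- matrix(0, la + 1L, lb + 1L)
    X <- matrix(-Inf, la + 1L, lb + 1L)
    Y <- matrix(-Inf, la + 1L, lb + 1L)
    best <- 0
    for (i in 2:(la + 1L)) {
        for (j in 2:(lb + 1L)) {
            s <- mat[A[i - 1L], B[j - 1L]]
            M[i, j] <- max(0, max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                                  Y[i - 1L, j - 1L]) + s)
            X[i, j] <- max(M[i - 1L, j] - open - ext, X[i - 1L, j] - ext)
            Y[i, j] <- max(M[i, j - 1L] - open - ext, Y[i, j - 1L] - ext)
            best <- max(best, M[i, j])
        }
    }
    best
}

blosum62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
})

## Sliding-window motif oracle built from per-token allowed sets.
motifOracle <- function(seq, pattern, table) {
    s <- strsplit(seq, "")[[1L]]
    toks <- strsplit(pattern, "")[[1L]]
    allowed <- lapply(toks, function(t) {
        if (t == "x") AA
        else if (t %in% names(table)) table[[t]]
        else t
    })
    k <- length(toks)
    if (k > length(s)) return(integer(0))
    which(vapply(seq_len(length(s) - k + 1L), function(i)
        all(mapply(function(ch, al) ch %in% al,
                   s[i:(i + k - 1L)], allowed)), logical(1)))
}

## Small two-family cohort used by several modules.
smallCohortSpec <- function(seed, nGenomes = 10L, genesPerGenome = 40L,
                            partnerFraction = 0.6,
                            sameDirecton = TRUE) {
    ## ancestor lengths are realistic protein sizes chosen with a length
    ## ratio below the default coverage threshold, so the bidirectional
    ## coverage rule structurally precludes direct inter-family edges
    fam <- data.frame(
        family_id = c("QRY", "PTN"), ancestor_length = c(280L, 180L),
        divergence = c(0.2, 0.2),
        presence_fraction = c(1, partnerFraction),
        stringsAsFactors = FALSE)
    ctx <- data.frame(
        query_family = "QRY", partner_family = "PTN",
        same_directon = sameDirecton,
        presence_fraction = partnerFraction, max_offset = 5L,
        stringsAsFactors = FALSE)
    simulationSpec(nGenomes = nGenomes, genesPerGenome = genesPerGenome,
                   families = fam, plantedContexts = ctx, rngSeed = seed)
}

querySeeds <- function(truth, family = "QRY") {
    tf <- truth$geneFamilies
    split(tf$gene_id[tf$family_id == family],
          tf$genome_id[tf$family_id == family])
}
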