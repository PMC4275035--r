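## Gene-neighborhood extraction and directon (putative operon) inference.
## A directon is a maximal run of consecutive same-strand genes in which
## every adjacent intergenic gap is at most maxGap nucleotides; genes in
## one directon are taken to share a putative common promoter.  Divergent
## ("head-to-head") gene pairs on opposite strands within the gap
## threshold mark bidirectional promoter sharing between two directons.

#' Neighborhood extraction parameters
#'
#' @param k genes extracted per side of the query (default 5).
#' @param maxGap maximum intergenic distance, in nucleotides, for two
#'   adjacent same-strand genes to be placed in one directon (default 150;
#'   the comparison is inclusive, and overlapping genes always qualify).
#' @param bidirectionalGap maximum gap for a divergent head-to-head pair
#'   to count as sharing a bidirectional promoter (default 150).
#' @param extendThroughDirecton if TRUE (default) the window grows to
#'   cover the query's entire directon when the directon extends past the
#'   k-gene window.
#' @return a validated list of class \code{NeighborhoodConfig}.
#' @export
neighborhoodConfig <- function(k = 5L, maxGap = 150L,
                               bidirectionalGap = 150L,
                               extendThroughDirecton = TRUE) {
    k <- as.integer(k)
    stopifnot(k >= 1L, maxGap >= 0L || maxGap == -Inf,
              bidirectionalGap >= 0L, is.logical(extendThroughDirecton))
    structure(list(k = k, maxGap = maxGap,
                   bidirectionalGap = bidirectionalGap,
                   extendThroughDirecton = extendThroughDirecton),
              class = "NeighborhoodConfig")
}

#' Intergenic distance between two adjacent genes
#'
#' For \code{b} the immediate successor of \code{a} in genome order the
#' gap is \code{start(b) - end(a) - 1}; negative values indicate
#' overlapping genes.  For the wrap-adjacent pair of a circular replicon
#' (last gene, first gene) the distance is measured through the origin.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param a,b gene ids; \code{b} must immediately follow \code{a} on the
#'   same replicon (or be the first gene when \code{a} is the last gene of
#'   a circular replicon).
#' @return integer gap in nucleotides.
#' @export
intergenicGap <- function(genome, a, b) {
    la <- locateGene(genome, a); lb <- locateGene(genome, b)
    if (la$replicon_id != lb$replicon_id)
        stop("genes ", a, " and ", b, " are on different replicons")
    rg <- .repliconGenes(genome, la$replicon_id)
    rep <- replicons(genome)
    circ <- rep$circular[rep$replicon_id == la$replicon_id]
    n <- nrow(rg)
    if (lb$ordinal == la$ordinal + 1L) {
        return(rg$start[lb$ordinal + 1L] - rg$end[la$ordinal + 1L] - 1L)
    }
    if (circ && la$ordinal == n - 1L && lb$ordinal == 0L) {
        L <- rep$length[rep$replicon_id == la$replicon_id]
        lastEnd <- if (rg$wraps[n]) rg$end[n] else rg$end[n] - L
        return(rg$start[1L] - lastEnd - 1L)
    }
    stop("genes ", a, " and ", b, " are not adjacent (b must follow a)")
}

## Gaps between consecutive genes of one replicon: element i is the gap
## between ordinals i-1 and i (1-based vector); the wrap gap (last gene to
## first, through the origin) is appended for circular replicons.
.adjacentGaps <- function(rg, repLength, circular) {
    n <- nrow(rg)
    gaps <- if (n >= 2L)
        rg$start[-1L] - rg$end[-n] - 1L
    else integer(0)
    if (circular && n >= 2L) {
        lastEnd <- if (rg$wraps[n]) rg$end[n] else rg$end[n] - repLength
        gaps <- c(gaps, rg$start[1L] - lastEnd - 1L)
    }
    gaps
}

#' Infer directons (putative co-transcribed gene blocks)
#'
#' Partitions each replicon's genes into maximal runs of consecutive
#' same-strand genes whose adjacent intergenic gaps are all at most
#' \code{maxGap} (inclusive; overlaps always qualify).  On circular
#' replicons a directon may span the origin, but never contains a gene
#' twice.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param maxGap gap threshold in nucleotides (default 150).
#' @return a data frame with one row per gene: \code{replicon_id},
#'   \code{ordinal} (0-based), \code{gene_id}, \code{strand},
#'   \code{directon_id}.  Directon ids are \code{<replicon>.<index>} in
#'   order of first occurrence.
#' @export
inferDirectons <- function(genome, maxGap = 150L) {
    out <- list()
    reps <- replicons(genome)
    for (r in seq_len(nrow(reps))) {
        rid <- reps$replicon_id[r]
        rg <- .repliconGenes(genome, rid)
        n <- nrow(rg)
        if (!n) next
        gaps <- .adjacentGaps(rg, reps$length[r], reps$circular[r])
        linked <- logical(max(n - 1L, 0L))
        if (n >= 2L)
            linked <- rg$strand[-1L] == rg$strand[-n] & gaps[seq_len(n - 1L)] <= maxGap
        grp <- cumsum(c(TRUE, !linked))   # run index per gene
        wrapLinked <- reps$circular[r] && n >= 2L &&
            rg$strand[n] == rg$strand[1L] && gaps[n] <= maxGap &&
            grp[n] != grp[1L]             # all-one-run already wraps fully
        if (wrapLinked) grp[grp == grp[n]] <- grp[1L]
        ids <- match(grp, unique(grp))
        out[[length(out) + 1L]] <- data.frame(
            replicon_id = rid, ordinal = rg$ordinal, gene_id = rg$gene_id,
            strand = rg$strand, directon_id = sprintf("%s.%d", rid, ids),
            stringsAsFactors = FALSE)
    }
    res <- if (length(out)) do.call(rbind, out) else
        data.frame(replicon_id = character(0), ordinal = integer(0),
                   gene_id = character(0), strand = character(0),
                   directon_id = character(0), stringsAsFactors = FALSE)
    attr(res, "max_gap") <- maxGap
    res
}

#' Detect divergent head-to-head gene pairs
#'
#' Returns adjacent gene pairs (left, right) with the left gene on the
#' \code{-} strand and the right gene on the \code{+} strand (5' ends
#' facing each other) whose intergenic gap is at most
#' \code{bidirectionalGap} -- the arrangement compatible with a shared
#' bidirectional promoter.  Wrap-adjacent pairs of circular replicons are
#' considered.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param bidirectionalGap gap threshold in nucleotides (default 150).
#' @return data frame with columns \code{replicon_id},
#'   \code{left_ordinal}, \code{right_ordinal}, \code{left_gene},
#'   \code{right_gene}, \code{gap}.
#' @export
detectHeadToHead <- function(genome, bidirectionalGap = 150L) {
    out <- list()
    reps <- replicons(genome)
    for (r in seq_len(nrow(reps))) {
        rid <- reps$replicon_id[r]
        rg <- .repliconGenes(genome, rid)
        n <- nrow(rg)
        if (n < 2L) next
        gaps <- .adjacentGaps(rg, reps$length[r], reps$circular[r])
        li <- seq_len(n - 1L)
        keep <- rg$strand[li] == "-" & rg$strand[li + 1L] == "+" &
            gaps[li] <= bidirectionalGap
        left <- li[keep]; right <- li[keep] + 1L; gap <- gaps[li][keep]
        if (reps$circular[r] && length(gaps) == n &&
            rg$strand[n] == "-" && rg$strand[1L] == "+" &&
            gaps[n] <= bidirectionalGap) {
            left <- c(left, n); right <- c(right, 1L)
            gap <- c(gap, gaps[n])
        }
        if (length(left))
            out[[length(out) + 1L]] <- data.frame(
                replicon_id = rid, left_ordinal = left - 1L,
                right_ordinal = right - 1L,
                left_gene = rg$gene_id[left], right_gene = rg$gene_id[right],
                gap = gap, stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else
        data.frame(replicon_id = character(0), left_ordinal = integer(0),
                   right_ordinal = integer(0), left_gene = character(0),
                   right_gene = character(0), gap = integer(0),
                   stringsAsFactors = FALSE)
}

#' Extract the gene neighborhood of a query gene
#'
#' Takes the \code{k} nearest genes on each side of the query (clipped at
#' the ends of linear replicons, wrapped on circular ones).  If the
#' query's directon extends past the window and
#' \code{extendThroughDirecton} is on, the window grows to cover the whole
#' directon.  Each neighbor is tagged with its directon and with a
#' promoter-sharing flag: TRUE when it lies in the query's directon, or in
#' the directon facing the query's across a qualifying head-to-head
#' junction (those neighbors additionally carry \code{head_to_head =
#' TRUE}).
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param geneId query gene id.
#' @param config a \code{\link{neighborhoodConfig}}.
#' @param directons optional precomputed result of
#'   \code{\link{inferDirectons}} at \code{config$maxGap}.
#' @return a \linkS4class{Neighborhood}.
#' @export
extractNeighborhood <- function(genome, geneId,
                                config = neighborhoodConfig(),
                                directons = NULL) {
    loc <- locateGene(genome, geneId)
    rid <- loc$replicon_id
    q <- loc$ordinal                      # 0-based
    rg <- .repliconGenes(genome, rid)
    n <- nrow(rg)
    reps <- replicons(genome)
    circ <- reps$circular[reps$replicon_id == rid]
    if (is.null(directons)) directons <- inferDirectons(genome, config$maxGap)
    dd <- directons[directons$replicon_id == rid, , drop = FALSE]
    dOf <- dd$directon_id[match(seq_len(n) - 1L, dd$ordinal)]

    offs <- seq.int(-config$k, config$k)
    if (config$extendThroughDirecton) {
        qd <- dOf[q + 1L]
        members <- which(dOf == qd) - 1L   # 0-based ordinals, consecutive
                                           # (possibly wrapping)
        rel <- (members - q) %% n
        rel[rel > n / 2] <- rel[rel > n / 2] - n
        if (!circ) rel <- members - q
        offs <- sort(unique(c(offs, rel)))
    }
    if (circ) {
        ## map offsets to ordinals, keeping each gene once (smallest |offset|)
        ord <- (q + offs) %% n
        pref <- order(abs(offs), offs)     # closest-to-query first
        keep <- pref[!duplicated(ord[pref])]
        offs <- sort(offs[keep])
        ord <- (q + offs) %% n
    } else {
        keep <- offs + q >= 0L & offs + q <= n - 1L
        offs <- offs[keep]
        ord <- q + offs
    }

    ## promoter sharing: query's directon, or across a head-to-head junction
    qd <- dOf[q + 1L]
    sharing <- dOf[ord + 1L] == qd
    h2hFlag <- logical(length(ord))
    h2h <- detectHeadToHead(genome, config$bidirectionalGap)
    h2h <- h2h[h2h$replicon_id == rid, , drop = FALSE]
    for (j in seq_len(nrow(h2h))) {
        dl <- dOf[h2h$left_ordinal[j] + 1L]
        dr <- dOf[h2h$right_ordinal[j] + 1L]
        other <- if (qd == dl) dr else if (qd == dr) dl else next
        across <- dOf[ord + 1L] == other
        sharing <- sharing | across
        h2hFlag <- h2hFlag | across
    }

    nb <- data.frame(
        offset = offs, ordinal = ord, gene_id = rg$gene_id[ord + 1L],
        start = rg$start[ord + 1L], end = rg$end[ord + 1L],
        strand = rg$strand[ord + 1L],
        feature_kind = rg$feature_kind[ord + 1L],
        directon_id = dOf[ord + 1L], promoter_sharing = sharing,
        head_to_head = h2hFlag, product = rg$product[ord + 1L],
        stringsAsFactors = FALSE)
    new("Neighborhood", queryId = geneId, genomeId = genomeId(genome),
        repliconId = rid, neighbors = nb)
}

#' Restrict a neighborhood to promoter-sharing genes
#'
#' Retains only neighbors flagged as sharing a putative promoter with the
#' query (same directon, or across a qualifying head-to-head junction),
#' plus the query itself.
#'
#' @param nbh a \linkS4class{Neighborhood}.
#' @return the filtered \linkS4class{Neighborhood}.
#' @export
filterPromoterSharing <- function(nbh) {
    nb <- neighbors(nbh)
    nb <- nb[nb$promoter_sharing | nb$offset == 0L, , drop = FALSE]
    rownames(nb) <- NULL
    methods::initialize(nbh, neighbors = nb)
}

#' Write a neighborhood as TSV
#'
#' @param nbh a \linkS4class{Neighborhood}.
#' @param file output path or connection.
#' @return invisibly, the path.
#' @export
writeNeighborhoodTsv <- function(nbh, file) {
    nb <- neighbors(nbh)
    cols <- c("offset", "gene_id", "start", "end", "strand",
              "feature_kind", "directon_id", "promoter_sharing", "product")
    utils::write.table(nb[, cols], file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
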