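#' @useDynLib geneContext, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.FEATURE_KINDS <- c("CDS", "tRNA", "rRNA", "other_RNA")
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.emptyGeneTable <- function() {
    data.frame(
        gene_id = character(0), replicon_id = character(0),
        start = integer(0), end = integer(0), strand = character(0),
        feature_kind = character(0), product = character(0),
        protein_seq = character(0), wraps = logical(0),
        stringsAsFactors = FALSE
    )
}

#' GenomeAnnotation: ordered, stranded gene coordinates for one genome
#'
#' Container for the gene complement of a (possibly multi-replicon)
#' prokaryotic genome.  Genes are stored as a data frame with one row per
#' gene, sorted by \code{(replicon_id, start)} with ties broken by
#' \code{gene_id}; coordinates are 1-based inclusive as in PTT and GenBank
#' files.  Genes spanning the origin of a circular replicon carry
#' \code{wraps = TRUE} and store the 5'-segment start as their normalized
#' start coordinate.
#'
#' @slot genomeId single genome identifier.
#' @slot replicons data frame with columns \code{replicon_id},
#'   \code{length} (nt) and \code{circular}.
#' @slot genes data frame with columns \code{gene_id}, \code{replicon_id},
#'   \code{start}, \code{end}, \code{strand} (\code{"+"}/\code{"-"}),
#'   \code{feature_kind} (\code{CDS}, \code{tRNA}, \code{rRNA},
#'   \code{other_RNA}), \code{product}, \code{protein_seq} (empty unless
#'   CDS) and \code{wraps}.
#'
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
    representation(genomeId = "character",
                   replicons = "data.frame",
                   genes = "data.frame"),
    prototype(genomeId = NA_character_,
              replicons = data.frame(replicon_id = character(0),
                                     length = integer(0),
                                     circular = logical(0),
                                     stringsAsFactors = FALSE),
              genes = .emptyGeneTable())
)

setValidity("GenomeAnnotation", function(object) {
    msg <- character(0)
    g <- object@genes
    r <- object@replicons
    need <- c("gene_id", "replicon_id", "start", "end", "strand",
              "feature_kind", "product", "protein_seq", "wraps")
    if (!all(need %in% names(g)))
        return(paste("genes table missing columns:",
                     paste(setdiff(need, names(g)), collapse = ", ")))
    if (!all(c("replicon_id", "length", "circular") %in% names(r)))
        return("replicons table must have replicon_id, length, circular")
    if (length(object@genomeId) != 1L)
        msg <- c(msg, "genomeId must be a single string")
    if (anyDuplicated(g$gene_id))
        msg <- c(msg, "gene_id values must be unique")
    if (anyDuplicated(r$replicon_id))
        msg <- c(msg, "replicon_id values must be unique")
    if (!all(g$replicon_id %in% r$replicon_id))
        msg <- c(msg, "every gene's replicon_id must appear in replicons")
    if (!all(g$strand %in% c("+", "-")))
        msg <- c(msg, "strand must be '+' or '-'")
    if (!all(g$feature_kind %in% .FEATURE_KINDS))
        msg <- c(msg, "invalid feature_kind")
    if (any(g$start < 1L))
        msg <- c(msg, "start coordinates must be >= 1")
    if (any(!g$wraps & g$start > g$end))
        msg <- c(msg, "start must be <= end for non-wrapping genes")
    isCDS <- g$feature_kind == "CDS"
    if (any(nzchar(g$protein_seq) != isCDS))
        msg <- c(msg, "protein_seq must be non-empty iff feature_kind is CDS")
    ord <- order(g$replicon_id, g$start, g$gene_id, method = "radix")
    if (!identical(ord, seq_len(nrow(g))))
        msg <- c(msg, "genes must be sorted by (replicon_id, start, gene_id)")
    if (length(msg)) msg else TRUE
})

#' Neighborhood: a query-centered gene window
#'
#' The result of \code{\link{extractNeighborhood}}: the query gene plus its
#' flanking genes with signed offsets, each tagged with the directon
#' (putative co-transcribed block) it belongs to and whether it putatively
#' shares a promoter with the query.
#'
#' @slot queryId gene identifier of the query.
#' @slot genomeId genome the window was extracted from.
#' @slot repliconId replicon carrying the query.
#' @slot neighbors data frame with columns \code{offset} (0 is the query),
#'   \code{ordinal} (0-based replicon-local gene index), \code{gene_id},
#'   \code{start}, \code{end}, \code{strand}, \code{feature_kind},
#'   \code{directon_id}, \code{promoter_sharing}, \code{head_to_head},
#'   \code{product}.
#'
#' @exportClass Neighborhood
setClass("Neighborhood",
    representation(queryId = "character", genomeId = "character",
                   repliconId = "character", neighbors = "data.frame"))

setValidity("Neighborhood", function(object) {
    nb <- object@neighbors
    need <- c("offset", "ordinal", "gene_id", "start", "end", "strand",
              "feature_kind", "directon_id", "promoter_sharing",
              "head_to_head", "product")
    if (!all(need %in% names(nb)))
        return(paste("neighbors table missing columns:",
                     paste(setdiff(need, names(nb)), collapse = ", ")))
    msg <- character(0)
    if (is.unsorted(nb$offset, strictly = TRUE))
        msg <- c(msg, "offsets must be strictly increasing")
    if (sum(nb$offset == 0L) != 1L)
        msg <- c(msg, "exactly one neighbor must have offset 0 (the query)")
    else if (nb$gene_id[nb$offset == 0L] != object@queryId)
        msg <- c(msg, "offset-0 row must be the query gene")
    if (length(msg)) msg else TRUE
})

#' ClusterSet: a single-linkage partition of protein identifiers
#'
#' Clusters are disjoint sets of protein ids covering the clustered input.
#' Cluster ids are deterministic: clusters are numbered \code{C1, C2, ...}
#' by decreasing size, ties broken by the lexicographically smallest member.
#'
#' @slot clusters named list of character vectors (members, sorted).
#' @slot labels named character vector of annotation labels, one per
#'   cluster (may be empty before \code{\link{annotateClusters}}).
#'
#' @exportClass ClusterSet
setClass("ClusterSet",
    representation(clusters = "list", labels = "character"))

setValidity("ClusterSet", function(object) {
    msg <- character(0)
    members <- unlist(object@clusters, use.names = FALSE)
    if (anyDuplicated(members))
        msg <- c(msg, "clusters must be disjoint")
    if (is.null(names(object@clusters)) ||
        anyDuplicated(names(object@clusters)))
        msg <- c(msg, "clusters must have unique names")
    if (length(object@labels) &&
        !all(names(object@labels) %in% names(object@clusters)))
        msg <- c(msg, "labels must be named by cluster id")
    if (length(msg)) msg else TRUE
})

#' Pssm: position-specific scoring matrix over the 20 standard residues
#'
#' Log-odds profile built from a master-slave alignment on query
#' coordinates.  Scores are \code{log2((c + alpha*b) / ((N + alpha) * b))}
#' with observed count \code{c}, column depth \code{N}, background
#' frequency \code{b} and pseudocount weight \code{alpha}; zero-depth
#' columns score 0 for every residue (pure-background limit).
#'
#' @slot scores numeric matrix, 20 rows (residues) by query-length columns,
#'   in log2 (bit) units.
#' @slot background named numeric vector of 20 residue frequencies
#'   summing to 1.
#' @slot alpha pseudocount weight used to build the profile.
#'
#' @exportClass Pssm
setClass("Pssm",
    representation(scores = "matrix", background = "numeric",
                   alpha = "numeric"))

setValidity("Pssm", function(object) {
    msg <- character(0)
    if (!identical(rownames(object@scores), .AA20))
        msg <- c(msg, "score matrix rows must be the 20 standard residues")
    if (any(!is.finite(object@scores)))
        msg <- c(msg, "scores must be finite")
    if (!isTRUE(all.equal(sum(object@background), 1, tolerance = 1e-6)))
        msg <- c(msg, "background frequencies must sum to 1")
    if (length(object@alpha) != 1L || object@alpha <= 0)
        msg <- c(msg, "alpha must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' IterativeSearchResult: trace of a reciprocally validated profile search
#'
#' @slot acceptedByIteration list of character vectors, the cumulative
#'   accepted id set after each iteration (monotonically non-decreasing).
#' @slot rejected data frame with columns \code{target_id}, \code{reason}
#'   (\code{above-threshold} or \code{reciprocal-failure}) and
#'   \code{iteration}.
#' @slot converged TRUE if a fixed point was reached before \code{maxIter}.
#' @slot nIterations number of search iterations performed.
#' @slot firstCorruptionIteration first iteration at which a candidate
#'   failed reciprocal validation (NA if none did).
#'
#' @exportClass IterativeSearchResult
setClass("IterativeSearchResult",
    representation(acceptedByIteration = "list", rejected = "data.frame",
                   converged = "logical", nIterations = "integer",
                   firstCorruptionIteration = "integer"))

setValidity("IterativeSearchResult", function(object) {
    msg <- character(0)
    acc <- object@acceptedByIteration
    if (length(acc) > 1L) {
        for (i in seq_len(length(acc) - 1L)) {
            if (!all(acc[[i]] %in% acc[[i + 1L]])) {
                msg <- c(msg, "accepted sets must be non-decreasing")
                break
            }
        }
    }
    final <- if (length(acc)) acc[[length(acc)]] else character(0)
    rej <- object@rejected$target_id[
        object@rejected$reason == "reciprocal-failure"]
    if (length(intersect(final, rej)))
        msg <- c(msg, "accepted and reciprocal-rejected sets must be disjoint")
    if (length(msg)) msg else TRUE
})
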