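## Protein family clustering: BLOSUM62 local alignment over all pairs,
## identity/coverage thresholding, single-linkage (connected components),
## and cluster annotation by shared domain architecture.

#' Clustering thresholds
#'
#' @param minIdentity minimum fraction of identical residue pairs over
#'   aligned (non-gap) columns (default 0.30).
#' @param minCoverage minimum aligned-span fraction, required of BOTH
#'   sequences (default 0.70).
#' @return a validated list of class \code{ClusterThresholds}.
#' @export
clusterThresholds <- function(minIdentity = 0.30, minCoverage = 0.70) {
    stopifnot(minIdentity >= 0, minIdentity <= 1,
              minCoverage >= 0, minCoverage <= 1)
    structure(list(minIdentity = minIdentity, minCoverage = minCoverage),
              class = "ClusterThresholds")
}

.alignScoring <- function(substitutionMatrix = "BLOSUM62",
                          gapOpening = 11, gapExtension = 1) {
    if (is.character(substitutionMatrix)) {
        e <- new.env()
        utils::data(list = substitutionMatrix,
                    package = "Biostrings", envir = e)
        substitutionMatrix <- get(substitutionMatrix, envir = e)
    }
    list(matrix = substitutionMatrix, gapOpening = gapOpening,
         gapExtension = gapExtension)
}

#' Align two proteins and report identity, coverage and score
#'
#' Best local (Smith-Waterman) alignment under an affine gap model: a gap
#' of length L costs \code{gapOpening + L * gapExtension}.  Identity is
#' computed over aligned columns excluding gap columns; coverage is the
#' aligned span divided by the full sequence length, reported for each
#' sequence.  When no residue pair scores positively the empty local
#' alignment is reported (score, identity and coverages all 0).
#'
#' @param a,b protein sequences (character or \code{AAString}) over the 20
#'   standard residues plus X.
#' @param substitutionMatrix matrix or the name of a matrix shipped with
#'   Biostrings (default \code{"BLOSUM62"}).
#' @param gapOpening,gapExtension affine gap penalties (defaults 11, 1).
#' @return list with \code{identity}, \code{coverage_a}, \code{coverage_b},
#'   \code{score}.
#' @export
alignPair <- function(a, b, substitutionMatrix = "BLOSUM62",
                      gapOpening = 11, gapExtension = 1) {
    a <- as.character(a); b <- as.character(b)
    if (!nzchar(a) || !nzchar(b))
        stop("alignPair: empty sequence")
    sc <- .alignScoring(substitutionMatrix, gapOpening, gapExtension)
    .alignPairEncoded(.encodeForMatrix(a, sc$matrix),
                      .encodeForMatrix(b, sc$matrix), sc)
}

.encodeForMatrix <- function(seq, mat) {
    alpha <- rownames(mat)
    codes <- match(strsplit(toupper(seq), "")[[1L]], alpha)
    if (anyNA(codes)) {
        xi <- match("X", alpha)
        if (is.na(xi)) stop("residue outside the scoring alphabet")
        codes[is.na(codes)] <- xi
    }
    codes - 1L
}

.alignPairEncoded <- function(ea, eb, sc) {
    ## canonical argument order so ties between co-optimal alignments
    ## resolve identically whichever way a pair is presented
    ka <- paste(ea, collapse = ","); kb <- paste(eb, collapse = ",")
    if (ka > kb) {
        sw <- .alignPairEncoded(eb, ea, sc)
        return(list(identity = sw$identity, coverage_a = sw$coverage_b,
                    coverage_b = sw$coverage_a, score = sw$score))
    }
    al <- .pairLocalAlign(ea, eb, sc$matrix, sc$gapOpening,
                          sc$gapExtension)
    if (al$score <= 0)
        return(list(identity = 0, coverage_a = 0, coverage_b = 0,
                    score = 0))
    list(identity = if (al$ncols > 0L) al$nmatch / al$ncols else 0,
         coverage_a = (al$qend - al$qstart + 1L) / length(ea),
         coverage_b = (al$tend - al$tstart + 1L) / length(eb),
         score = al$score)
}

#' Build the thresholded similarity graph over a sequence set
#'
#' Aligns all pairs and keeps an (undirected) edge where identity and
#' bidirectional coverage both meet their thresholds.  Pairs whose length
#' ratio is below \code{minCoverage} are skipped without alignment: even
#' a full-length overlap of the shorter sequence could not cover the
#' longer one, so no such pair can form an edge.
#'
#' @param sequences named character vector or \code{AAStringSet}.
#' @param thresholds a \code{\link{clusterThresholds}}.
#' @param ... scoring arguments passed on to \code{\link{alignPair}}.
#' @return data frame of passing edges with columns \code{id_a},
#'   \code{id_b}, \code{identity}, \code{coverage_a}, \code{coverage_b},
#'   \code{score}.
#' @export
buildSimilarityGraph <- function(sequences,
                                 thresholds = clusterThresholds(), ...) {
    if (methods::is(sequences, "XStringSet"))
        sequences <- as.character(sequences)
    if (!length(sequences)) stop("buildSimilarityGraph: no sequences")
    ids <- names(sequences)
    sc <- .alignScoring(...)
    enc <- lapply(sequences, .encodeForMatrix, mat = sc$matrix)
    len <- lengths(enc)
    out <- list()
    for (j in seq_along(enc)[-1L]) {
        for (i in seq_len(j - 1L)) {
            if (min(len[i], len[j]) / max(len[i], len[j]) <
                thresholds$minCoverage) next
            sim <- .alignPairEncoded(enc[[i]], enc[[j]], sc)
            if (sim$identity >= thresholds$minIdentity &&
                min(sim$coverage_a, sim$coverage_b) >=
                thresholds$minCoverage)
                out[[length(out) + 1L]] <- data.frame(
                    id_a = ids[i], id_b = ids[j],
                    identity = sim$identity,
                    coverage_a = sim$coverage_a,
                    coverage_b = sim$coverage_b,
                    score = sim$score, stringsAsFactors = FALSE)
        }
    }
    if (length(out)) do.call(rbind, out) else
        data.frame(id_a = character(0), id_b = character(0),
                   identity = numeric(0), coverage_a = numeric(0),
                   coverage_b = numeric(0), score = numeric(0),
                   stringsAsFactors = FALSE)
}

#' Single-linkage clustering of protein ids
#'
#' Clusters are the connected components of the similarity graph: one
#' qualifying link suffices to merge two clusters, so a-b and b-c place a
#' and c together even without an a-c edge.  Cluster ids are assigned
#' deterministically: decreasing size, ties broken by the
#' lexicographically smallest member id.
#'
#' @param ids character vector of all protein ids (singletons allowed).
#' @param edges data frame with columns \code{id_a}, \code{id_b} (as from
#'   \code{\link{buildSimilarityGraph}}).
#' @return a \linkS4class{ClusterSet}.
#' @export
clusterSingleLinkage <- function(ids, edges) {
    ids <- as.character(ids)
    bad <- setdiff(c(edges$id_a, edges$id_b), ids)
    if (length(bad))
        stop("edges reference unknown ids: ",
             paste(utils::head(bad, 5), collapse = ", "))
    g <- igraph::graph_from_data_frame(
        edges[, c("id_a", "id_b"), drop = FALSE],
        directed = FALSE, vertices = data.frame(name = ids))
    comp <- igraph::components(g)$membership
    parts <- split(names(comp), comp)
    parts <- lapply(parts, function(p) sort(p))
    anchor <- vapply(parts, `[`, character(1), 1L)
    ord <- order(-lengths(parts), anchor, method = "radix")
    parts <- parts[ord]
    names(parts) <- sprintf("C%d", seq_along(parts))
    new("ClusterSet", clusters = parts,
        labels = stats::setNames(character(0), character(0)))
}

#' Annotate clusters by shared domain architecture
#'
#' Each cluster is labeled with the most frequent architecture string
#' (\code{"Dom1+Dom2+..."} syntax) among its annotated members; ties break
#' lexicographically; clusters with no annotated member are labeled
#' \code{"unannotated"}.
#'
#' @param clusterSet a \linkS4class{ClusterSet}.
#' @param architectures named character vector (or the result of
#'   \code{\link{readArchitectures}}) mapping protein id to architecture.
#' @return the \linkS4class{ClusterSet} with labels filled in.
#' @export
annotateClusters <- function(clusterSet, architectures) {
    labs <- vapply(clusters(clusterSet), function(members) {
        arch <- architectures[intersect(members, names(architectures))]
        arch <- arch[!is.na(arch) & nzchar(arch)]
        if (!length(arch)) return("unannotated")
        tab <- table(arch)
        best <- names(tab)[tab == max(tab)]
        sort(best)[1L]
    }, character(1))
    methods::initialize(clusterSet, labels = labs)
}

#' Read a protein domain-architecture table
#'
#' @param file TSV with columns \code{protein_id}, \code{architecture}.
#' @return named character vector.
#' @export
readArchitectures <- function(file) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (!all(c("protein_id", "architecture") %in% names(tab)))
        stop("architecture TSV must have columns protein_id, architecture")
    stats::setNames(tab$architecture, tab$protein_id)
}

#' Write a ClusterSet as TSV
#'
#' @param clusterSet a \linkS4class{ClusterSet}.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeClustersTsv <- function(clusterSet, file) {
    cl <- clusters(clusterSet)
    labs <- clusterLabels(clusterSet)
    tab <- data.frame(
        cluster_id = names(cl), size = lengths(cl),
        label = if (length(labs)) unname(labs[names(cl)]) else "",
        members = vapply(cl, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE)
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
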