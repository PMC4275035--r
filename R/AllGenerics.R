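#' Accessors for geneContext classes
#'
#' @param x a \code{GenomeAnnotation}, \code{Neighborhood},
#'   \code{ClusterSet}, \code{Pssm} or \code{IterativeSearchResult}.
#' @return the slot contents documented for each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("replicons", function(x) standardGeneric("replicons"))
#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("neighbors", function(x) standardGeneric("neighbors"))
#' @rdname accessors
#' @export
setGeneric("queryId", function(x) standardGeneric("queryId"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname accessors
#' @export
setGeneric("pssmScores", function(x) standardGeneric("pssmScores"))
#' @rdname accessors
#' @export
setGeneric("acceptedIds", function(x) standardGeneric("acceptedIds"))
#' @rdname accessors
#' @export
setGeneric("rejectedIds", function(x) standardGeneric("rejectedIds"))

#' @rdname accessors
setMethod("genomeId", "GenomeAnnotation", function(x) x@genomeId)
#' @rdname accessors
setMethod("replicons", "GenomeAnnotation", function(x) x@replicons)
#' @rdname accessors
setMethod("genes", "GenomeAnnotation", function(x) x@genes)
#' @rdname accessors
setMethod("genomeId", "Neighborhood", function(x) x@genomeId)
#' @rdname accessors
setMethod("neighbors", "Neighborhood", function(x) x@neighbors)
#' @rdname accessors
setMethod("queryId", "Neighborhood", function(x) x@queryId)
#' @rdname accessors
setMethod("clusters", "ClusterSet", function(x) x@clusters)
#' @rdname accessors
setMethod("clusterLabels", "ClusterSet", function(x) x@labels)

#' @rdname accessors
#' @aliases membership,ClusterSet-method
#' @details \code{membership} returns a named character vector mapping each
#'   protein id to its cluster id.
setMethod("membership", "ClusterSet", function(x) {
    ids <- unlist(x@clusters, use.names = FALSE)
    cl <- rep(names(x@clusters), lengths(x@clusters))
    stats::setNames(cl, ids)
})

#' @rdname accessors
setMethod("pssmScores", "Pssm", function(x) x@scores)

#' @rdname accessors
#' @details \code{acceptedIds} returns the final accepted id set of an
#'   iterative search; \code{rejectedIds} the ids rejected by reciprocal
#'   validation.
setMethod("acceptedIds", "IterativeSearchResult", function(x) {
    acc <- x@acceptedByIteration
    if (length(acc)) acc[[length(acc)]] else character(0)
})
#' @rdname accessors
setMethod("rejectedIds", "IterativeSearchResult", function(x) {
    unique(x@rejected$target_id[x@rejected$reason == "reciprocal-failure"])
})

setMethod("show", "GenomeAnnotation", function(object) {
    g <- object@genes
    cat("GenomeAnnotation object\n")
    cat("  genome:   ", object@genomeId, "\n", sep = "")
    cat("  replicons:", nrow(object@replicons),
        sprintf("(%s)", paste(utils::head(object@replicons$replicon_id, 3),
                              collapse = ", ")), "\n")
    kinds <- table(factor(g$feature_kind, levels = .FEATURE_KINDS))
    cat("  genes:    ", nrow(g), " (",
        paste(sprintf("%s %d", names(kinds), as.integer(kinds)),
              collapse = ", "), ")\n", sep = "")
})

setMethod("show", "Neighborhood", function(object) {
    nb <- object@neighbors
    cat("Neighborhood of ", object@queryId, " (genome ", object@genomeId,
        ", replicon ", object@repliconId, ")\n", sep = "")
    cat("  ", nrow(nb), " genes, offsets ", min(nb$offset), "..",
        max(nb$offset), "; ", sum(nb$promoter_sharing),
        " share the putative promoter\n", sep = "")
})

setMethod("show", "ClusterSet", function(object) {
    sz <- lengths(object@clusters)
    cat("ClusterSet with ", length(sz), " clusters over ", sum(sz),
        " proteins\n", sep = "")
    if (length(sz))
        cat("  sizes: ", paste(utils::head(sz, 8), collapse = ", "),
            if (length(sz) > 8) ", ..." else "", "\n", sep = "")
})

setMethod("show", "Pssm", function(object) {
    cat("Pssm: ", ncol(object@scores), " positions x 20 residues, alpha = ",
        object@alpha, "\n", sep = "")
})

setMethod("show", "IterativeSearchResult", function(object) {
    cat("IterativeSearchResult: ", object@nIterations, " iterations, ",
        length(acceptedIds(object)), " accepted, ",
        length(rejectedIds(object)), " rejected by reciprocal validation; ",
        if (object@converged) "converged" else "stopped at maxIter",
        "\n", sep = "")
})
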