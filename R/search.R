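## Iterative homology search with reciprocal validation.  The search
## discipline -- inclusion threshold, reciprocal re-search of every new
## hit, permanent exclusion of candidates that fail (the profile
## corruption guard) -- is implemented over a pluggable engine contract;
## a bundled desk-scale engine scores local alignments and converts them
## to expectation values with fixed Karlin-Altschul constants.

.encodeSeq <- function(seq) {
    codes <- match(strsplit(as.character(seq), "")[[1L]], .AA20) - 1L
    codes[is.na(codes)] <- -1L          # X and friends: score 0
    as.integer(codes)
}

#' Bundled desk-scale search engine
#'
#' Returns an engine closure satisfying the engine contract: a function
#' \code{(query, database) -> hits} where \code{query} is a protein
#' sequence or a \linkS4class{Pssm}, \code{database} a named sequence set,
#' and the result a data frame of hits sorted by ascending e-value (ties
#' by target id).  Scores come from local alignment (BLOSUM62, affine
#' gaps 11/1 by default); Pssm queries are aligned with the same gap
#' model, their bit-unit scores doubled onto the half-bit scale of
#' BLOSUM62 so one e-value calibration serves both query kinds.
#' Expectation values use \code{E = K * m * n * exp(-lambda * S)} with
#' \code{m} the query length and \code{n} the total database residue
#' count; the constants are fixed defaults of the gapped BLOSUM62
#' convention, not fitted.
#'
#' @param substitutionMatrix,gapOpening,gapExtension scoring for sequence
#'   queries (and the gap model for Pssm queries).
#' @param lambda,K Karlin-Altschul constants (defaults 0.267, 0.041).
#' @return an engine function for \code{\link{iterativeSearch}} /
#'   \code{\link{reciprocalValidate}}.
#' @export
toyEngine <- function(substitutionMatrix = "BLOSUM62", gapOpening = 11,
                      gapExtension = 1, lambda = 0.267, K = 0.041) {
    sc <- .alignScoring(substitutionMatrix, gapOpening, gapExtension)
    function(query, database) {
        toyEngineSearch(query, database, scoring = sc,
                        lambda = lambda, K = K)
    }
}

#' Search a protein database with a sequence or profile query
#'
#' Workhorse behind \code{\link{toyEngine}}; see there for the scoring
#' and e-value model.
#'
#' @param query protein sequence (character/\code{AAString}) or a
#'   \linkS4class{Pssm}.
#' @param database named character vector or \code{AAStringSet}.
#' @param scoring list with \code{matrix}, \code{gapOpening},
#'   \code{gapExtension} (see \code{\link{toyEngine}}).
#' @param lambda,K Karlin-Altschul constants.
#' @return data frame with columns \code{target_id}, \code{e_value},
#'   \code{bit_score}, \code{qstart}, \code{qend}, \code{tstart},
#'   \code{tend}, sorted by ascending \code{e_value} (ties by target id);
#'   empty for an empty database.
#' @export
toyEngineSearch <- function(query, database, scoring = .alignScoring(),
                            lambda = 0.267, K = 0.041) {
    emptyHits <- data.frame(target_id = character(0), e_value = numeric(0),
                            bit_score = numeric(0), qstart = integer(0),
                            qend = integer(0), tstart = integer(0),
                            tend = integer(0), stringsAsFactors = FALSE)
    if (!length(database)) return(emptyHits)
    if (!methods::is(database, "XStringSet"))
        database <- Biostrings::AAStringSet(database)
    n <- sum(Biostrings::width(database))
    if (methods::is(query, "Pssm")) {
        m <- ncol(pssmScores(query))
        halfBits <- 2 * pssmScores(query)   # half-bit scale, see toyEngine
        res <- lapply(seq_along(database), function(i) {
            al <- .profileLocalAlign(halfBits,
                                     .encodeSeq(database[[i]]),
                                     scoring$gapOpening,
                                     scoring$gapExtension)
            data.frame(target_id = names(database)[i], score = al$score,
                       qstart = al$qstart, qend = al$qend,
                       tstart = al$tstart, tend = al$tend,
                       stringsAsFactors = FALSE)
        })
        res <- do.call(rbind, res)
    } else {
        q <- as.character(query)
        m <- nchar(q)
        eq <- .encodeForMatrix(q, scoring$matrix)
        res <- lapply(seq_along(database), function(i) {
            al <- .pairLocalAlign(
                eq, .encodeForMatrix(as.character(database[[i]]),
                                     scoring$matrix),
                scoring$matrix, scoring$gapOpening, scoring$gapExtension)
            data.frame(target_id = names(database)[i], score = al$score,
                       qstart = al$qstart, qend = al$qend,
                       tstart = al$tstart, tend = al$tend,
                       stringsAsFactors = FALSE)
        })
        res <- do.call(rbind, res)
    }
    res$e_value <- K * m * n * exp(-lambda * res$score)
    res$bit_score <- (lambda * res$score - log(K)) / log(2)
    res <- res[order(res$e_value, res$target_id, method = "radix"), ,
               drop = FALSE]
    rownames(res) <- NULL
    res[, c("target_id", "e_value", "bit_score", "qstart", "qend",
            "tstart", "tend")]
}

#' Master-slave alignment of accepted members onto query coordinates
#'
#' Aligns each member locally to the seed and projects its residues onto
#' the seed's coordinate system, dropping member insertions; unaligned
#' seed positions are gap characters for that member.
#'
#' @param seedId id of the master (seed) sequence in \code{database}.
#' @param memberIds ids of the aligned members (the seed itself included
#'   automatically).
#' @param database named sequence set containing all ids.
#' @param scoring alignment scoring (see \code{\link{toyEngine}}).
#' @return character matrix, members x seed-length, gap = \code{"-"}.
#' @export
masterSlaveAlignment <- function(seedId, memberIds, database,
                                 scoring = .alignScoring()) {
    if (!methods::is(database, "XStringSet"))
        database <- Biostrings::AAStringSet(database)
    seed <- as.character(database[[seedId]])
    L <- nchar(seed)
    memberIds <- union(seedId, memberIds)
    out <- matrix("-", nrow = length(memberIds), ncol = L,
                  dimnames = list(memberIds, NULL))
    out[seedId, ] <- strsplit(seed, "")[[1L]]
    for (id in setdiff(memberIds, seedId)) {
        pa <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(as.character(database[[id]])),
            Biostrings::AAString(seed),
            substitutionMatrix = scoring$matrix,
            gapOpening = scoring$gapOpening,
            gapExtension = scoring$gapExtension, type = "local")
        if (Biostrings::score(pa) <= 0) next
        p <- strsplit(as.character(Biostrings::alignedPattern(pa)),
                      "")[[1L]]
        s <- strsplit(as.character(Biostrings::alignedSubject(pa)),
                      "")[[1L]]
        pos <- Biostrings::start(Biostrings::subject(pa)) - 1L
        for (k in seq_along(s)) {
            if (s[k] != "-") {
                pos <- pos + 1L
                if (p[k] != "-") out[id, pos] <- p[k]
            }                               # member insertions dropped
        }
    }
    out
}

#' Build a position-specific scoring matrix from a master-slave alignment
#'
#' Per position and residue the log-odds score is
#' \code{log2((c + alpha * b) / ((N + alpha) * b))} with observed count
#' \code{c}, column depth \code{N} (gap and X characters excluded),
#' background frequency \code{b} and pseudocount weight \code{alpha}.
#' Zero-depth columns score 0 for every residue.
#'
#' @param alignment character matrix as from
#'   \code{\link{masterSlaveAlignment}} (members x positions).
#' @param alpha pseudocount weight, > 0 (default 1).
#' @param background named residue frequencies (default uniform 1/20).
#' @return a \linkS4class{Pssm}.
#' @export
buildPssm <- function(alignment, alpha = 1,
                      background = stats::setNames(rep(1 / 20, 20), .AA20)) {
    stopifnot(alpha > 0, is.matrix(alignment))
    L <- ncol(alignment)
    scores <- matrix(0, nrow = 20L, ncol = L,
                     dimnames = list(.AA20, NULL))
    for (j in seq_len(L)) {
        col <- alignment[, j]
        col <- col[col %in% .AA20]
        N <- length(col)
        cnt <- tabulate(match(col, .AA20), nbins = 20L)
        scores[, j] <- log2((cnt + alpha * background[.AA20]) /
                            ((N + alpha) * background[.AA20]))
    }
    new("Pssm", scores = scores, background = background[.AA20],
        alpha = alpha)
}

#' Reciprocal validation of a candidate hit
#'
#' Re-searches the database with the candidate's own sequence as query
#' and accepts the candidate iff some already-accepted member (the
#' original seed included) is recovered at an e-value at or below the
#' cut-off (inclusive).
#'
#' @param candidateId id of the candidate in \code{database}.
#' @param acceptedIds ids already accepted (seed included).
#' @param database named sequence set.
#' @param engine an engine function (see \code{\link{toyEngine}}).
#' @param eCut e-value cut-off (default 0.01).
#' @return TRUE to accept, FALSE otherwise.
#' @export
reciprocalValidate <- function(candidateId, acceptedIds, database,
                               engine = toyEngine(), eCut = 0.01) {
    if (!methods::is(database, "XStringSet"))
        database <- Biostrings::AAStringSet(database)
    hits <- engine(database[[candidateId]], database)
    hits <- hits[hits$target_id != candidateId, , drop = FALSE]
    any(hits$target_id %in% acceptedIds & hits$e_value <= eCut)
}

#' Iterative profile search with reciprocal validation
#'
#' Iteration 1 searches with the seed sequence; each later iteration
#' searches with a Pssm built from the master-slave alignment of all
#' accepted members.  A hit at or below the e-value cut-off is admitted
#' only after passing \code{\link{reciprocalValidate}}; a hit that fails
#' is recorded and permanently excluded (the corruption guard), and the
#' first iteration at which any exclusion occurred is reported.  The
#' search stops at a fixed point (no new members accepted; converged) or
#' after \code{maxIter} iterations.
#'
#' @param seedId id of the seed sequence in \code{database}.
#' @param database named character vector or \code{AAStringSet}.
#' @param engine engine function (default \code{\link{toyEngine}()}).
#' @param eCut inclusion e-value cut-off (default 0.01, inclusive).
#' @param maxIter maximum iterations (default 10, must be >= 1).
#' @param alpha pseudocount weight for profile construction.
#' @param scoring scoring used for the master-slave alignment.
#' @return an \linkS4class{IterativeSearchResult}.
#' @export
iterativeSearch <- function(seedId, database, engine = toyEngine(),
                            eCut = 0.01, maxIter = 10L, alpha = 1,
                            scoring = .alignScoring()) {
    if (maxIter < 1L) stop("maxIter must be >= 1")
    if (!methods::is(database, "XStringSet"))
        database <- Biostrings::AAStringSet(database)
    if (!seedId %in% names(database))
        stop("seed ", seedId, " not in database")
    accepted <- seedId
    excluded <- character(0)
    rejected <- data.frame(target_id = character(0), reason = character(0),
                           iteration = integer(0), stringsAsFactors = FALSE)
    acceptedByIteration <- list()
    converged <- FALSE
    firstCorruption <- NA_integer_
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        query <- if (iter == 1L) database[[seedId]] else
            buildPssm(masterSlaveAlignment(seedId, accepted, database,
                                           scoring), alpha = alpha)
        hits <- engine(query, database)
        above <- hits$target_id[hits$e_value > eCut]
        above <- setdiff(above, c(accepted, excluded))
        if (length(above))
            rejected <- rbind(rejected, data.frame(
                target_id = above, reason = "above-threshold",
                iteration = iter, stringsAsFactors = FALSE))
        cand <- hits$target_id[hits$e_value <= eCut]
        cand <- setdiff(cand, c(accepted, excluded))
        newAccepts <- character(0)
        for (id in cand) {
            if (reciprocalValidate(id, accepted, database, engine, eCut)) {
                accepted <- c(accepted, id)
                newAccepts <- c(newAccepts, id)
            } else {
                excluded <- c(excluded, id)
                rejected <- rbind(rejected, data.frame(
                    target_id = id, reason = "reciprocal-failure",
                    iteration = iter, stringsAsFactors = FALSE))
                if (is.na(firstCorruption)) firstCorruption <- iter
            }
        }
        acceptedByIteration[[iter]] <- accepted
        if (!length(newAccepts)) { converged <- TRUE; break }
    }
    new("IterativeSearchResult",
        acceptedByIteration = acceptedByIteration, rejected = rejected,
        converged = converged, nIterations = iter,
        firstCorruptionIteration = firstCorruption)
}

#' Read / write tabular hit files (BLAST outfmt-6-like)
#'
#' Columns: query_id, target_id, e_value, bit_score, qstart, qend,
#' tstart, tend.
#'
#' @param file path.
#' @param hits hit data frame (a \code{query_id} column is added from the
#'   \code{queryId} argument if absent).
#' @param queryId query id to record when writing.
#' @return \code{readHitsTsv}: the hit data frame; \code{writeHitsTsv}:
#'   the path, invisibly.
#' @export
readHitsTsv <- function(file) {
    utils::read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname readHitsTsv
#' @export
writeHitsTsv <- function(hits, file, queryId = "query") {
    if (is.null(hits$query_id))
        hits <- cbind(query_id = queryId, hits)
    utils::write.table(hits, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
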