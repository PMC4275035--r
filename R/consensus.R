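## Alignment consensus annotation with physicochemical residue classes
## and degenerate class-coded motif scanning.  Classes follow the common
## Taylor-style sets: hydroxylic ("o") is exactly {S, T}; tiny ("u") is a
## subset of small ("s"); aliphatic ("l") and aromatic ("a") are subsets
## of hydrophobic ("h"); positively charged ("+") is a subset of charged
## ("c").

.DEFAULT_CLASSES <- list(
    h = c("A", "C", "F", "H", "I", "L", "M", "V", "W", "Y"),  # hydrophobic
    p = c("C", "D", "E", "H", "K", "N", "Q", "R", "S", "T"),  # polar
    s = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),  # small
    u = c("A", "G", "S"),                                 # tiny
    l = c("I", "L", "V"),                                 # aliphatic
    o = c("S", "T"),                                      # hydroxylic
    a = c("F", "H", "W", "Y"),                            # aromatic
    b = c("E", "F", "I", "K", "L", "M", "Q", "R", "W", "Y"),  # big
    c = c("D", "E", "H", "K", "R"),                       # charged
    `+` = c("H", "K", "R")                                # positive
)

## Specificity-first order used to break ties between classes of equal
## size when assigning a column's consensus code.
.CLASS_ORDER <- c("u", "o", "l", "a", "+", "s", "c", "h", "p", "b")

#' Residue class table for consensus annotation
#'
#' @param overrides named list of character vectors replacing individual
#'   default class memberships.
#' @return named list of residue sets, validated: \code{o} must be
#'   exactly Ser/Thr; tiny within small, aliphatic and aromatic within
#'   hydrophobic, positive within charged; all residues standard.
#' @export
residueClassTable <- function(overrides = list()) {
    tab <- utils::modifyList(.DEFAULT_CLASSES, overrides)
    bad <- setdiff(unlist(tab), .AA20)
    if (length(bad))
        stop("non-standard residues in class table: ",
             paste(bad, collapse = ", "))
    if (any(lengths(tab) == 0L)) stop("every class must be non-empty")
    if (!setequal(tab$o, c("S", "T")))
        stop("class 'o' (hydroxylic) must be exactly {S, T}")
    subsets <- list(c("u", "s"), c("l", "h"), c("a", "h"), c("+", "c"))
    for (pr in subsets)
        if (!all(tab[[pr[1L]]] %in% tab[[pr[2L]]]))
            stop("class '", pr[1L], "' must be a subset of '", pr[2L], "'")
    tab
}

#' Read a residue class table from TSV
#'
#' @param file TSV with two columns: class code, residue string (no
#'   header), e.g. \code{"u\tAGS"}.
#' @return a validated class table (see \code{\link{residueClassTable}}).
#' @export
readClassTable <- function(file) {
    tab <- utils::read.delim(file, header = FALSE,
                             stringsAsFactors = FALSE)
    sets <- lapply(tab[[2L]], function(x) strsplit(x, "")[[1L]])
    names(sets) <- tab[[1L]]
    residueClassTable(sets)
}

.alignmentMatrix <- function(alignment) {
    if (methods::is(alignment, "XStringSet"))
        alignment <- stats::setNames(as.character(alignment),
                                     names(alignment))
    w <- unique(nchar(alignment))
    if (length(w) != 1L)
        stop("ragged alignment: sequence lengths differ")
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(m) <- names(alignment)
    m
}

#' Compute a per-column consensus line for a protein alignment
#'
#' For each column (gaps counted in the denominator): if one residue's
#' frequency reaches the threshold the uppercase residue is emitted;
#' otherwise the smallest residue class whose combined member frequency
#' reaches the threshold is emitted as its lowercase code (ties between
#' equal-size classes broken by a fixed specificity order:
#' u, o, l, a, +, s, c, h, p, b); otherwise \code{"."}.
#'
#' @param alignment equal-length gapped sequences (\code{AAStringSet} or
#'   character vector), at least 2.
#' @param threshold required fraction of sequences, in (0.5, 1]
#'   (default 0.8).
#' @param table class table from \code{\link{residueClassTable}}.
#' @return list with \code{consensus} (single string) and \code{support}
#'   (numeric vector of supporting fractions, 0 where \code{"."}).
#' @export
computeConsensus <- function(alignment, threshold = 0.8,
                             table = residueClassTable()) {
    m <- .alignmentMatrix(alignment)
    if (nrow(m) < 2L) stop("need at least 2 sequences")
    stopifnot(threshold > 0.5, threshold <= 1)
    nseq <- nrow(m)
    ord <- c(intersect(.CLASS_ORDER, names(table)),
             sort(setdiff(names(table), .CLASS_ORDER)))
    codes <- character(ncol(m)); support <- numeric(ncol(m))
    for (j in seq_len(ncol(m))) {
        col <- m[, j]
        cnt <- table(col[col %in% .AA20])
        codes[j] <- "."
        if (length(cnt)) {
            top <- max(cnt)
            if (top / nseq >= threshold) {
                codes[j] <- sort(names(cnt)[cnt == top])[1L]
                support[j] <- top / nseq
                next
            }
            sizes <- lengths(table)[ord]
            for (cl in ord[order(sizes, match(ord, ord))]) {
                f <- sum(cnt[names(cnt) %in% table[[cl]]]) / nseq
                if (f >= threshold) {
                    codes[j] <- cl
                    support[j] <- f
                    break
                }
            }
        }
    }
    list(consensus = paste(codes, collapse = ""), support = support)
}

#' Scan a sequence for a degenerate class-coded motif
#'
#' Pattern tokens: an uppercase residue matches exactly, a lowercase
#' class code matches any member of that class, \code{"x"} matches any
#' residue.  All (possibly overlapping) matches are reported.
#'
#' @param sequence ungapped protein string (or \code{AAString}).
#' @param pattern token string such as \code{"DsoW"}, or a character
#'   vector of tokens.
#' @param table class table from \code{\link{residueClassTable}}.
#' @return integer vector of 1-based match start positions.
#' @export
motifScan <- function(sequence, pattern, table = residueClassTable()) {
    seq <- strsplit(toupper(as.character(sequence)), "")[[1L]]
    tok <- if (length(pattern) == 1L) strsplit(pattern, "")[[1L]] else
        pattern
    bad <- !(tok %in% .AA20 | tok %in% names(table) | tok == "x")
    if (any(bad))
        stop("invalid motif token(s): ", paste(tok[bad], collapse = ", "))
    if (length(tok) > length(seq)) return(integer(0))
    ok <- function(ch, t) {
        if (t == "x") return(TRUE)
        if (t %in% .AA20 && t == toupper(t)) return(ch == t)
        ch %in% table[[t]]
    }
    starts <- integer(0)
    for (i in seq_len(length(seq) - length(tok) + 1L)) {
        hit <- TRUE
        for (k in seq_along(tok)) {
            if (!ok(seq[i + k - 1L], tok[k])) { hit <- FALSE; break }
        }
        if (hit) starts <- c(starts, i)
    }
    starts
}

#' Render an alignment with its consensus line
#'
#' Writes fixed-width blocks; each block lists every sequence (name,
#' whitespace, residues) followed by a line named \code{consensus=}.  The
#' output is re-parseable with \code{\link{readAnnotatedAlignment}}.
#'
#' @param alignment equal-length gapped sequences.
#' @param consensus result of \code{\link{computeConsensus}} (or a bare
#'   consensus string of matching width).
#' @param file output path or connection.
#' @param blockWidth residues per block (default 60).
#' @return invisibly, the path.
#' @export
renderAnnotatedAlignment <- function(alignment, consensus, file,
                                     blockWidth = 60L) {
    m <- .alignmentMatrix(alignment)
    cons <- if (is.list(consensus)) consensus$consensus else consensus
    if (nchar(cons) != ncol(m))
        stop("consensus width does not match alignment width")
    ids <- rownames(m)
    if (is.null(ids)) ids <- sprintf("seq%d", seq_len(nrow(m)))
    pad <- max(nchar(c(ids, "consensus="))) + 2L
    con <- file(file, "w"); on.exit(close(con))
    starts <- seq.int(1L, ncol(m), by = blockWidth)
    for (s in starts) {
        e <- min(s + blockWidth - 1L, ncol(m))
        for (i in seq_len(nrow(m)))
            writeLines(sprintf("%-*s%s", pad, ids[i],
                               paste(m[i, s:e], collapse = "")), con)
        writeLines(sprintf("%-*s%s", pad, "consensus=",
                           substr(cons, s, e)), con)
        if (e < ncol(m)) writeLines("", con)
    }
    invisible(file)
}

#' Read an alignment rendered by \code{renderAnnotatedAlignment}
#'
#' @param file path.
#' @return list with \code{alignment} (named character vector) and
#'   \code{consensus} (string).
#' @export
readAnnotatedAlignment <- function(file) {
    lines <- readLines(file)
    lines <- lines[nzchar(lines)]
    seqs <- list(); cons <- character(0)
    for (ln in lines) {
        parts <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)$", ln))[[1L]]
        if (length(parts) != 3L) stop("unparseable line: ", ln)
        if (parts[2L] == "consensus=")
            cons <- c(cons, parts[3L])
        else
            seqs[[parts[2L]]] <- c(seqs[[parts[2L]]], parts[3L])
    }
    list(alignment = vapply(seqs, paste, character(1), collapse = ""),
         consensus = paste(cons, collapse = ""))
}

#' Write a consensus line as TSV
#'
#' @param consensus result of \code{\link{computeConsensus}}.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeConsensusTsv <- function(consensus, file) {
    codes <- strsplit(consensus$consensus, "")[[1L]]
    utils::write.table(
        data.frame(column = seq_along(codes), code = codes,
                   supporting_fraction = consensus$support),
        file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}
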