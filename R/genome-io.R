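## Genome annotation input/output: NCBI PTT protein tables, a GenBank
## flat-file subset (CDS + tRNA/rRNA features with translations), FASTA,
## and a supplementary RNA-feature TSV.  External coordinates are 1-based
## inclusive throughout; internal gene ordinals are replicon-local and
## 0-based.

.GB_RNA_KEYS <- c(tRNA = "tRNA", rRNA = "rRNA", misc_RNA = "other_RNA",
                  ncRNA = "other_RNA", tmRNA = "other_RNA")

## Residues outside the 20 standard letters + X are collapsed to X so that
## downstream scoring (BLOSUM62 over 20+X) is always defined.
.sanitizeProtein <- function(seqs) {
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
    if (any(bad)) {
        warning(sum(bad), " sequence(s) contained non-standard residues; ",
                "mapped to X", call. = FALSE)
        seqs[bad] <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", seqs[bad])
    }
    seqs
}

.sortGenes <- function(genes) {
    genes[order(genes$replicon_id, genes$start, genes$gene_id,
                method = "radix"), , drop = FALSE]
}

#' Construct a GenomeAnnotation
#'
#' Normalizes the gene table (stable sort by replicon, start, gene id) and
#' validates the container invariants.
#'
#' @param genomeId single genome identifier.
#' @param replicons data frame with columns \code{replicon_id},
#'   \code{length}, \code{circular}.
#' @param genes data frame as documented in
#'   \linkS4class{GenomeAnnotation}; a missing \code{wraps} column is
#'   filled with \code{FALSE}.
#' @return a \linkS4class{GenomeAnnotation}.
#' @export
GenomeAnnotation <- function(genomeId, replicons, genes) {
    if (is.null(genes$wraps)) genes$wraps <- FALSE
    if (is.null(genes$product)) genes$product <- ""
    if (is.null(genes$protein_seq)) genes$protein_seq <- ""
    genes$protein_seq <- .sanitizeProtein(toupper(genes$protein_seq))
    genes <- .sortGenes(genes)
    rownames(genes) <- NULL
    replicons$length <- as.integer(replicons$length)
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
    new("GenomeAnnotation", genomeId = as.character(genomeId),
        replicons = replicons, genes = genes)
}

#' Read an NCBI PTT protein table
#'
#' Parses the tab-delimited PTT dialect: free-text header lines, a column
#' header starting with \code{Location}, then one row per protein-coding
#' gene with columns Location (\code{start..end}), Strand, Length, PID,
#' Gene, Synonym, Code, COG, Product.  Gene ids are taken from the Synonym
#' column, falling back to PID where Synonym is \code{-} or empty.
#' Protein sequences are left empty; join them from a FASTA with
#' \code{\link{joinProteins}}.  PTT files carry no RNA genes; add those
#' with \code{\link{readRnaFeatures}} if needed.
#'
#' @param file path to the PTT file (or a connection).
#' @param genomeId genome identifier to record.
#' @param repliconLength replicon length in nucleotides.
#' @param circular is the replicon circular?  When TRUE, a row whose start
#'   exceeds its end is interpreted as spanning the origin (wrap flag set);
#'   when FALSE such a row is a parse error.
#' @param repliconId replicon identifier (defaults to \code{genomeId}).
#' @return a \linkS4class{GenomeAnnotation}.
#' @export
readPtt <- function(file, genomeId, repliconLength, circular = FALSE,
                    repliconId = genomeId) {
    lines <- readLines(file)
    hdr <- grep("^Location\t", lines)
    if (!length(hdr))
        stop("PTT parse error: no 'Location' header row found")
    hdr <- hdr[1L]
    rows <- lines[seq.int(hdr + 1L, length.out = length(lines) - hdr)]
    rows <- rows[nzchar(rows)]
    n <- length(rows)
    gene_id <- character(n); start <- integer(n); end <- integer(n)
    strand <- character(n); product <- character(n); wraps <- logical(n)
    for (i in seq_len(n)) {
        lineno <- hdr + i
        f <- strsplit(rows[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 9L)
            stop("PTT parse error at line ", lineno, ": expected 9 columns")
        loc <- regmatches(f[1L],
                          regexec("^([0-9]+)\\.\\.([0-9]+)$", f[1L]))[[1L]]
        if (length(loc) != 3L)
            stop("PTT parse error at line ", lineno,
                 ": malformed Location '", f[1L], "'")
        s <- as.integer(loc[2L]); e <- as.integer(loc[3L])
        if (s > e) {
            if (!circular)
                stop("PTT parse error at line ", lineno,
                     ": start ", s, " > end ", e, " on a linear replicon")
            wraps[i] <- TRUE
        }
        if (!f[2L] %in% c("+", "-"))
            stop("PTT parse error at line ", lineno,
                 ": bad strand '", f[2L], "'")
        id <- f[6L]
        if (!nzchar(id) || id == "-") id <- f[4L]
        gene_id[i] <- id; start[i] <- s; end[i] <- e
        strand[i] <- f[2L]
        product[i] <- if (length(f) >= 9L) f[9L] else ""
    }
    if (anyDuplicated(gene_id))
        stop("duplicate gene_id in PTT: ",
             paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
    genes <- data.frame(
        gene_id = gene_id, replicon_id = rep(repliconId, n),
        start = start, end = end, strand = strand,
        feature_kind = rep("CDS", n), product = product,
        ## placeholder until joinProteins(); validity requires non-empty
        protein_seq = rep("X", n), wraps = wraps,
        stringsAsFactors = FALSE)
    reps <- data.frame(replicon_id = repliconId,
                       length = as.integer(repliconLength),
                       circular = circular, stringsAsFactors = FALSE)
    GenomeAnnotation(genomeId, reps, genes)
}

#' Write the CDS complement of a genome as a PTT table
#'
#' One PTT file describes one replicon; RNA features are skipped (the
#' format cannot carry them).
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param file output path.
#' @param repliconId which replicon to write (default: the first).
#' @return invisibly, the path.
#' @export
writePtt <- function(genome, file, repliconId = replicons(genome)$replicon_id[1L]) {
    rep <- replicons(genome)
    rep <- rep[rep$replicon_id == repliconId, , drop = FALSE]
    if (!nrow(rep)) stop("unknown replicon: ", repliconId)
    g <- genes(genome)
    g <- g[g$replicon_id == repliconId & g$feature_kind == "CDS", ,
           drop = FALSE]
    ntlen <- ifelse(g$wraps, rep$length - g$start + 1L + g$end,
                    g$end - g$start + 1L)
    aalen <- pmax(ntlen %/% 3L - 1L, 1L)
    con <- file(file, "w"); on.exit(close(con))
    writeLines(c(
        sprintf("%s %s, complete sequence - 1..%d", genomeId(genome),
                repliconId, rep$length),
        sprintf("%d proteins", nrow(g)),
        paste(c("Location", "Strand", "Length", "PID", "Gene", "Synonym",
                "Code", "COG", "Product"), collapse = "\t")), con)
    if (nrow(g))
        writeLines(sprintf("%d..%d\t%s\t%d\t%s\t-\t%s\t-\t-\t%s",
                           g$start, g$end, g$strand, aalen, g$gene_id,
                           g$gene_id, g$product), con)
    invisible(file)
}

#' Read a protein FASTA into a named sequence set
#'
#' Identifiers are the header up to the first whitespace and must be
#' unique.  Order is preserved.
#'
#' @param file path to a FASTA file.
#' @return an \code{\link[Biostrings]{AAStringSet}}.
#' @export
readFastaFile <- function(file) {
    x <- Biostrings::readAAStringSet(file)
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        stop("duplicate FASTA ids: ",
             paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
    x
}

#' Write sequences as FASTA
#'
#' @param x an \code{AAStringSet} or named character vector.
#' @param file output path.
#' @param width line width for wrapping (default 60).
#' @return invisibly, the path.
#' @export
writeFastaFile <- function(x, file, width = 60L) {
    if (!methods::is(x, "XStringSet")) x <- Biostrings::AAStringSet(x)
    Biostrings::writeXStringSet(x, file, width = width)
    invisible(file)
}

## ---- GenBank flat-file subset ----------------------------------------

.parseGbLocation <- function(loc) {
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    wraps <- FALSE
    if (grepl("^join\\(", loc)) {
        parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1L]]
        m1 <- regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", parts[1L])[[1L]]
        m2 <- regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$",
                      parts[length(parts)])[[1L]]
        s <- as.integer(regmatches(parts[1L], list(m1))[[1L]][2L])
        e <- as.integer(regmatches(parts[length(parts)],
                                   list(m2))[[1L]][3L])
        wraps <- TRUE   # join() across segments: treated as origin-spanning
        return(list(start = s, end = e, strand = strand, wraps = wraps))
    }
    m <- regmatches(loc, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", loc))[[1L]]
    if (length(m) != 3L) stop("unsupported GenBank location: ", loc)
    list(start = as.integer(m[2L]), end = as.integer(m[3L]),
         strand = strand, wraps = wraps)
}

#' Read a GenBank flat file (annotation subset)
#'
#' Parses LOCUS records with CDS, tRNA, rRNA and other RNA features
#' (misc_RNA, ncRNA, tmRNA map to \code{other_RNA}).  CDS translations are
#' taken from the \code{/translation} qualifier; gene ids from
#' \code{/locus_tag}.  The circular flag is read from the LOCUS line;
#' \code{join()} locations spanning the origin set the wrap flag.
#' Multiple LOCUS records become multiple replicons of one genome.
#'
#' @param file path to the GenBank flat file.
#' @param genomeId genome identifier; default: first DEFINITION word, or
#'   the first LOCUS name.
#' @return a \linkS4class{GenomeAnnotation}.
#' @export
readGenBank <- function(file, genomeId = NULL) {
    lines <- readLines(file)
    reps <- list(); feats <- list(); defName <- NULL
    i <- 1L; n <- length(lines); curRep <- NULL
    flushFeature <- function(ft) {
        if (is.null(ft)) return()
        kind <- if (ft$key == "CDS") "CDS"
                else .GB_RNA_KEYS[[ft$key]]
        loc <- .parseGbLocation(ft$loc)
        feats[[length(feats) + 1L]] <<- data.frame(
            gene_id = ft$locus_tag, replicon_id = curRep,
            start = loc$start, end = loc$end, strand = loc$strand,
            feature_kind = kind, product = ft$product,
            protein_seq = ft$translation, wraps = loc$wraps,
            stringsAsFactors = FALSE)
    }
    while (i <= n) {
        line <- lines[i]
        if (startsWith(line, "LOCUS")) {
            f <- strsplit(trimws(line), "\\s+")[[1L]]
            bp <- which(f == "bp")
            if (length(bp) != 1L || bp < 3L)
                stop("GenBank parse error: LOCUS line lacks a length in bp")
            curRep <- f[2L]
            reps[[length(reps) + 1L]] <- data.frame(
                replicon_id = curRep, length = as.integer(f[bp - 1L]),
                circular = "circular" %in% f, stringsAsFactors = FALSE)
        } else if (startsWith(line, "DEFINITION") && is.null(defName)) {
            defName <- strsplit(trimws(sub("^DEFINITION\\s*", "", line)),
                                "[ .]")[[1L]][1L]
        } else if (startsWith(line, "FEATURES")) {
            i <- i + 1L
            ft <- NULL
            while (i <= n && !startsWith(lines[i], "ORIGIN") &&
                   !startsWith(lines[i], "//") &&
                   !startsWith(lines[i], "LOCUS")) {
                fl <- lines[i]
                if (grepl("^ {5}\\S", fl)) {          # new feature
                    flushFeature(ft); ft <- NULL
                    f <- strsplit(trimws(fl), "\\s+")[[1L]]
                    key <- f[1L]
                    if (key == "CDS" || key %in% names(.GB_RNA_KEYS)) {
                        ft <- list(key = key, loc = f[2L], locus_tag = "",
                                   product = "", translation = "")
                        while (i + 1L <= n &&
                               grepl("^ {21}[^/]", lines[i + 1L])) {
                            i <- i + 1L   # continuation of the location
                            ft$loc <- paste0(ft$loc, trimws(lines[i]))
                        }
                    }
                } else if (!is.null(ft) && grepl("^ {21}/", fl)) {
                    q <- trimws(fl)
                    while (i + 1L <= n &&
                           grepl("^ {21}[^/]", lines[i + 1L]) &&
                           !grepl("^ {5}\\S", lines[i + 1L])) {
                        i <- i + 1L
                        sep <- if (startsWith(q, "/translation=")) "" else " "
                        q <- paste(q, trimws(lines[i]), sep = sep)
                    }
                    kv <- regmatches(q, regexec(
                        "^/([A-Za-z_]+)=\"?([^\"]*)\"?$", q))[[1L]]
                    if (length(kv) == 3L) {
                        if (kv[2L] == "locus_tag") ft$locus_tag <- kv[3L]
                        if (kv[2L] == "product") ft$product <- kv[3L]
                        if (kv[2L] == "translation")
                            ft$translation <- gsub("\\s", "", kv[3L])
                    }
                }
                i <- i + 1L
            }
            flushFeature(ft); ft <- NULL
            next
        }
        i <- i + 1L
    }
    if (!length(reps)) stop("GenBank parse error: no LOCUS record found")
    repdf <- do.call(rbind, reps)
    genes <- if (length(feats)) do.call(rbind, feats) else .emptyGeneTable()
    noid <- !nzchar(genes$gene_id)
    if (any(noid))
        genes$gene_id[noid] <- sprintf("feature_%04d", which(noid))
    if (is.null(genomeId))
        genomeId <- if (!is.null(defName)) defName else repdf$replicon_id[1L]
    GenomeAnnotation(genomeId, repdf, genes)
}

.gbWrap <- function(tag, value, con) {
    # qualifier text wrapped at column 79, continuation indent 21
    text <- sprintf("/%s=\"%s\"", tag, value)
    avail <- 58L
    while (nchar(text) > avail) {
        writeLines(paste0(strrep(" ", 21L), substr(text, 1L, avail)), con)
        text <- substr(text, avail + 1L, nchar(text))
    }
    writeLines(paste0(strrep(" ", 21L), text), con)
}

#' Write a genome as a GenBank flat file (annotation subset)
#'
#' Emits one LOCUS record per replicon with source, CDS and RNA features;
#' CDS carry \code{/translation}.  No ORIGIN sequence block is written.
#' The output is re-readable by \code{\link{readGenBank}} with all fields
#' preserved.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeGenBank <- function(genome, file) {
    con <- file(file, "w"); on.exit(close(con))
    g <- genes(genome)
    for (r in seq_len(nrow(replicons(genome)))) {
        rep <- replicons(genome)[r, ]
        writeLines(sprintf(
            "LOCUS       %-16s %d bp    DNA     %s BCT 01-JAN-2000",
            rep$replicon_id, rep$length,
            if (rep$circular) "circular" else "linear  "), con)
        writeLines(sprintf("DEFINITION  %s %s.", genomeId(genome),
                           rep$replicon_id), con)
        writeLines("FEATURES             Location/Qualifiers", con)
        writeLines(sprintf("     source          1..%d", rep$length), con)
        gr <- g[g$replicon_id == rep$replicon_id, , drop = FALSE]
        for (k in seq_len(nrow(gr))) {
            gn <- gr[k, ]
            key <- switch(gn$feature_kind, CDS = "CDS", tRNA = "tRNA",
                          rRNA = "rRNA", other_RNA = "misc_RNA")
            loc <- if (gn$wraps)
                sprintf("join(%d..%d,1..%d)", gn$start, rep$length, gn$end)
            else sprintf("%d..%d", gn$start, gn$end)
            if (gn$strand == "-") loc <- sprintf("complement(%s)", loc)
            writeLines(sprintf("     %-15s %s", key, loc), con)
            .gbWrap("locus_tag", gn$gene_id, con)
            if (nzchar(gn$product)) .gbWrap("product", gn$product, con)
            if (gn$feature_kind == "CDS")
                .gbWrap("translation", gn$protein_seq, con)
        }
        writeLines("//", con)
    }
    invisible(file)
}

#' Add RNA features from a supplementary TSV
#'
#' PTT files cannot carry RNA genes; this reads a tab-separated table with
#' columns \code{gene_id}, \code{replicon}, \code{start}, \code{end},
#' \code{strand}, \code{kind}, \code{product} and merges the features into
#' an existing annotation.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param file path to the RNA-feature TSV (header required).
#' @return the augmented \linkS4class{GenomeAnnotation}.
#' @export
readRnaFeatures <- function(genome, file) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("gene_id", "replicon", "start", "end", "strand", "kind",
              "product")
    if (!all(need %in% names(tab)))
        stop("RNA-feature TSV must have columns: ",
             paste(need, collapse = ", "))
    if (!all(tab$kind %in% c("tRNA", "rRNA", "other_RNA")))
        stop("RNA-feature kind must be tRNA, rRNA or other_RNA")
    add <- data.frame(
        gene_id = tab$gene_id, replicon_id = tab$replicon,
        start = as.integer(tab$start), end = as.integer(tab$end),
        strand = tab$strand, feature_kind = tab$kind,
        product = tab$product, protein_seq = "", wraps = FALSE,
        stringsAsFactors = FALSE)
    GenomeAnnotation(genomeId(genome), replicons(genome),
                     rbind(genes(genome), add))
}

#' Attach protein sequences to CDS records
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param proteins an \code{AAStringSet} or named character vector keyed by
#'   gene id.
#' @param strict error if a CDS has no sequence in \code{proteins}
#'   (default TRUE).
#' @return the updated \linkS4class{GenomeAnnotation}.
#' @export
joinProteins <- function(genome, proteins, strict = TRUE) {
    seqs <- if (methods::is(proteins, "XStringSet"))
        as.character(proteins) else proteins
    g <- genes(genome)
    isCDS <- g$feature_kind == "CDS"
    hit <- g$gene_id[isCDS] %in% names(seqs)
    if (strict && !all(hit))
        stop("no protein sequence for CDS: ",
             paste(utils::head(g$gene_id[isCDS][!hit], 5), collapse = ", "))
    idx <- which(isCDS)[hit]
    g$protein_seq[idx] <- unname(seqs[g$gene_id[idx]])
    GenomeAnnotation(genomeId(genome), replicons(genome), g)
}

#' Extract the protein complement of a genome
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @return an \code{AAStringSet} of all CDS products, named by gene id.
#' @export
genomeProteins <- function(genome) {
    g <- genes(genome)
    g <- g[g$feature_kind == "CDS", , drop = FALSE]
    Biostrings::AAStringSet(stats::setNames(g$protein_seq, g$gene_id))
}

#' Locate a gene within its replicon
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param geneId gene identifier.
#' @return a list with \code{replicon_id} and \code{ordinal}, the 0-based
#'   index of the gene in its replicon's ordered gene list.
#' @export
locateGene <- function(genome, geneId) {
    g <- genes(genome)
    row <- which(g$gene_id == geneId)
    if (!length(row)) stop("unknown gene_id: ", geneId)
    rep <- g$replicon_id[row]
    list(replicon_id = rep,
         ordinal = sum(g$replicon_id[seq_len(row - 1L)] == rep))
}

## Replicon-local view with 0-based ordinals; internal.
.repliconGenes <- function(genome, repliconId) {
    g <- genes(genome)
    g <- g[g$replicon_id == repliconId, , drop = FALSE]
    g$ordinal <- seq_len(nrow(g)) - 1L
    rownames(g) <- NULL
    g
}
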