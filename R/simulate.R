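## Synthetic prokaryotic cohort generator: toy genomes laid out as
## successive transcription units (geometric sizes, per-unit strand,
## short intra-unit and long inter-unit gaps), with planted diverged
## protein families and planted query/partner contextual associations,
## plus full ground truth for parameter-recovery tests.

#' Cohort simulation parameters
#'
#' The gap-range defaults are disjoint across the 150-nt directon
#' boundary, so the generator's unit layout is exactly recoverable by
#' \code{\link{inferDirectons}} at \code{maxGap = 150}.
#'
#' @param nGenomes number of genomes.
#' @param genesPerGenome single count or \code{c(min, max)} range.
#' @param circular replicon circularity flag (default TRUE).
#' @param operonSizeP geometric parameter for transcription-unit size
#'   (unit size = 1 + Geom(p); default 0.5, mean 2 genes).
#' @param intraOperonGap nucleotide gap range within a unit
#'   (default \code{c(0, 150)}).
#' @param interUnitGap gap range between units (default
#'   \code{c(151, 1000)}).
#' @param proteinLength background protein length range (default
#'   \code{c(80, 400)}).
#' @param families data frame: \code{family_id}, \code{ancestor_length},
#'   \code{divergence} (per-site substitution probability in [0,1)),
#'   \code{presence_fraction}, optional \code{kind} (\code{"CDS"}
#'   default, or \code{"tRNA"}/\code{"rRNA"}) and \code{product}.
#' @param plantedContexts data frame (possibly empty):
#'   \code{query_family}, \code{partner_family}, \code{same_directon}
#'   (logical), \code{presence_fraction}, \code{max_offset}.
#' @param rngSeed integer seed; all randomness flows through it.
#' @return a validated list of class \code{SimulationSpec}.
#' @export
simulationSpec <- function(nGenomes = 10L, genesPerGenome = 60L,
                           circular = TRUE, operonSizeP = 0.5,
                           intraOperonGap = c(0L, 150L),
                           interUnitGap = c(151L, 1000L),
                           proteinLength = c(80L, 400L),
                           families = NULL, plantedContexts = NULL,
                           rngSeed = 1L) {
    if (is.null(families))
        families <- data.frame(family_id = character(0),
                               ancestor_length = integer(0),
                               divergence = numeric(0),
                               presence_fraction = numeric(0),
                               stringsAsFactors = FALSE)
    if (is.null(families$kind))
        families$kind <- rep("CDS", nrow(families))
    if (is.null(families$product))
        families$product <- ifelse(families$kind == "CDS", "",
                                   paste0(families$kind, "-",
                                          families$family_id))
    if (is.null(plantedContexts))
        plantedContexts <- data.frame(query_family = character(0),
                                      partner_family = character(0),
                                      same_directon = logical(0),
                                      presence_fraction = numeric(0),
                                      max_offset = integer(0),
                                      stringsAsFactors = FALSE)
    stopifnot(nGenomes >= 1L, operonSizeP > 0, operonSizeP <= 1,
              all(families$divergence >= 0), all(families$divergence < 1),
              all(families$presence_fraction >= 0),
              all(families$presence_fraction <= 1),
              all(plantedContexts$presence_fraction >= 0),
              all(plantedContexts$presence_fraction <= 1),
              all(plantedContexts$query_family %in% families$family_id),
              all(plantedContexts$partner_family %in% families$family_id))
    if (length(genesPerGenome) == 1L)
        genesPerGenome <- rep(genesPerGenome, 2L)
    structure(list(nGenomes = as.integer(nGenomes),
                   genesPerGenome = as.integer(genesPerGenome),
                   circular = circular, operonSizeP = operonSizeP,
                   intraOperonGap = as.integer(intraOperonGap),
                   interUnitGap = as.integer(interUnitGap),
                   proteinLength = as.integer(proteinLength),
                   families = families,
                   plantedContexts = plantedContexts,
                   rngSeed = as.integer(rngSeed)),
              class = "SimulationSpec")
}

#' Random protein sequence at uniform background composition
#'
#' @param length sequence length.
#' @return character protein sequence.
#' @export
randomProtein <- function(length) {
    paste(sample(.AA20, length, replace = TRUE), collapse = "")
}

#' Derive a diverged family member from an ancestor sequence
#'
#' Each site is substituted independently with probability \code{d}; the
#' replacement is drawn uniformly from the 19 alternative residues, so
#' expected pairwise identity to the ancestor is \code{1 - d} (and
#' between two members \code{(1-d)^2 + d^2/19 + 2 d (1-d)/19}... computed
#' exactly in the tests).  Length is preserved.
#'
#' @param ancestor protein sequence.
#' @param d per-site substitution probability in [0, 1).
#' @return derived protein sequence.
#' @export
evolveFamily <- function(ancestor, d) {
    stopifnot(d >= 0, d < 1)
    res <- strsplit(as.character(ancestor), "")[[1L]]
    hit <- stats::runif(length(res)) < d
    if (any(hit))
        res[hit] <- vapply(res[hit], function(aa)
            sample(setdiff(.AA20, aa), 1L), character(1))
    paste(res, collapse = "")
}

## exact per-genome counts: round(fraction * n), drawn as a random subset
.drawGenomes <- function(frac, n) {
    k <- round(frac * n)
    if (k == 0L) integer(0) else sort(sample.int(n, k))
}

#' Generate a synthetic annotated genome cohort with ground truth
#'
#' Genomes are laid out as successive transcription units; gene content
#' is background (independent random proteins at uniform composition,
#' pairwise identity at chance level) except where family members and
#' planted contexts are inserted.  Presence fractions are honored as
#' exact genome counts (\code{round(fraction * nGenomes)}, random
#' subset).  A same-directon context places the partner adjacent to the
#' query inside one unit; an any-neighbor context places it within
#' \code{max_offset} gene positions.  Output is byte-deterministic under
#' \code{rngSeed}.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @return list with \code{genomes} (named list of
#'   \linkS4class{GenomeAnnotation}), \code{proteins} (cohort
#'   \code{AAStringSet}), \code{ancestors} (named character), and
#'   \code{truth}: \code{geneFamilies} (genome_id, gene_id, family_id),
#'   \code{units} (genome_id, gene_id, unit), \code{plantedAssociations}
#'   (query_family, partner_family, genome_id, same_directon),
#'   \code{architectures} (named character: member id -> family id).
#' @export
generateCohort <- function(spec) {
    stopifnot(inherits(spec, "SimulationSpec"))
    old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$rngSeed)

    fam <- spec$families
    ctx <- spec$plantedContexts
    nG <- spec$nGenomes
    ancestors <- stats::setNames(
        vapply(fam$ancestor_length, randomProtein, character(1)),
        fam$family_id)

    ## which genomes carry each context / each family (exact counts)
    ctxGenomes <- lapply(seq_len(nrow(ctx)), function(i)
        .drawGenomes(ctx$presence_fraction[i], nG))
    famGenomes <- lapply(seq_len(nrow(fam)), function(i)
        .drawGenomes(fam$presence_fraction[i], nG))
    names(famGenomes) <- fam$family_id
    ## genomes already covered by a context count toward family presence
    for (i in seq_len(nrow(ctx))) {
        for (f in c(ctx$query_family[i], ctx$partner_family[i])) {
            need <- length(famGenomes[[f]])
            covered <- union(famGenomes[[f]], ctxGenomes[[i]])
            famGenomes[[f]] <- if (length(covered) > need)
                sort(c(ctxGenomes[[i]],
                       utils::head(setdiff(famGenomes[[f]],
                                           ctxGenomes[[i]]),
                                   max(need - length(ctxGenomes[[i]]), 0L))))
            else sort(covered)
        }
    }

    genomes <- list(); prots <- character(0)
    gfRows <- list(); unitRows <- list(); assocRows <- list()
    for (gi in seq_len(nG)) {
        gid <- sprintf("G%02d", gi)
        n <- if (spec$genesPerGenome[1L] == spec$genesPerGenome[2L])
            spec$genesPerGenome[1L] else
            sample(spec$genesPerGenome[1L]:spec$genesPerGenome[2L], 1L)
        ## unit layout
        sizes <- integer(0)
        while (sum(sizes) < n)
            sizes <- c(sizes, 1L + stats::rgeom(1L, spec$operonSizeP))
        extra <- sum(sizes) - n
        sizes[length(sizes)] <- sizes[length(sizes)] - extra
        sizes <- sizes[sizes > 0L]
        unit <- rep(seq_along(sizes), sizes)
        strandPerUnit <- sample(c("+", "-"), length(sizes), replace = TRUE)
        strand <- strandPerUnit[unit]

        ## slot assignment: family_id per slot, NA = background
        slotFam <- rep(NA_character_, n)
        placeAt <- function(slot, famId) slotFam[slot] <<- famId
        queryShot <- list()   # family -> slot, for context reuse
        for (ci in seq_len(nrow(ctx))) {
            if (!gi %in% ctxGenomes[[ci]]) next
            qf <- ctx$query_family[ci]; pf <- ctx$partner_family[ci]
            qslot <- queryShot[[qf]]
            if (ctx$same_directon[ci]) {
                if (is.null(qslot)) {
                    ## adjacent free pair inside one unit
                    cand <- which(seq_len(n - 1L) > 0 &
                                  unit[-n] == unit[-1L] &
                                  is.na(slotFam[-n]) & is.na(slotFam[-1L]))
                    if (!length(cand))
                        stop("spec infeasible: no unit can host a ",
                             "same-directon context in ", gid)
                    s <- sample(cand, 1L)
                    placeAt(s, qf); placeAt(s + 1L, pf)
                    queryShot[[qf]] <- s
                } else {
                    nbr <- c(qslot - 1L, qslot + 1L)
                    nbr <- nbr[nbr >= 1L & nbr <= n &
                               unit[nbr] == unit[qslot] &
                               is.na(slotFam[nbr])]
                    if (!length(nbr))
                        stop("spec infeasible: query unit full in ", gid)
                    placeAt(nbr[1L], pf)
                }
            } else {
                if (is.null(qslot)) {
                    free <- which(is.na(slotFam))
                    qslot <- sample(free, 1L)
                    placeAt(qslot, qf)
                    queryShot[[qf]] <- qslot
                }
                win <- setdiff(
                    max(1L, qslot - ctx$max_offset[ci]):
                    min(n, qslot + ctx$max_offset[ci]), qslot)
                win <- win[is.na(slotFam[win])]
                if (!length(win))
                    stop("spec infeasible: window full in ", gid)
                placeAt(sample(rep(win, 2L), 1L), pf)
            }
            assocRows[[length(assocRows) + 1L]] <- data.frame(
                query_family = qf, partner_family = pf, genome_id = gid,
                same_directon = ctx$same_directon[ci],
                stringsAsFactors = FALSE)
        }
        for (fi in seq_len(nrow(fam))) {
            f <- fam$family_id[fi]
            if (!gi %in% famGenomes[[f]]) next
            if (f %in% slotFam) next     # already placed by a context
            free <- which(is.na(slotFam))
            if (!length(free))
                stop("spec infeasible: more planted genes than slots")
            placeAt(sample(rep(free, 2L), 1L), f)
        }

        ## sequences, kinds, coordinates
        geneId <- sprintf("%s_g%03d", gid, seq_len(n))
        kind <- rep("CDS", n); product <- rep("hypothetical protein", n)
        seqs <- character(n)
        for (s in seq_len(n)) {
            if (is.na(slotFam[s])) {
                len <- sample(spec$proteinLength[1L]:
                              spec$proteinLength[2L], 1L)
                seqs[s] <- randomProtein(len)
            } else {
                fi <- match(slotFam[s], fam$family_id)
                kind[s] <- fam$kind[fi]
                if (kind[s] == "CDS") {
                    seqs[s] <- evolveFamily(ancestors[[slotFam[s]]],
                                            fam$divergence[fi])
                    product[s] <- sprintf("%s family protein", slotFam[s])
                } else {
                    seqs[s] <- ""
                    product[s] <- fam$product[fi]
                }
            }
        }
        ntLen <- ifelse(kind == "CDS", 3L * (nchar(seqs) + 1L),
                        sample(70:100, n, replace = TRUE))
        gaps <- integer(n)   # gap preceding each gene
        gaps[1L] <- sample(spec$interUnitGap[1L]:spec$interUnitGap[2L], 1L)
        if (n > 1L) {
            intra <- sample(spec$intraOperonGap[1L]:spec$intraOperonGap[2L],
                            n - 1L, replace = TRUE)
            inter <- sample(spec$interUnitGap[1L]:spec$interUnitGap[2L],
                            n - 1L, replace = TRUE)
            sameUnit <- unit[-1L] == unit[-n]
            gaps[-1L] <- ifelse(sameUnit, intra, inter)
        }
        start <- cumsum(gaps) + cumsum(c(0L, ntLen[-n])) + 1L
        end <- start + ntLen - 1L
        repLen <- end[n] +
            sample(spec$interUnitGap[1L]:spec$interUnitGap[2L], 1L)

        genes <- data.frame(
            gene_id = geneId, replicon_id = gid, start = start, end = end,
            strand = strand, feature_kind = kind, product = product,
            protein_seq = seqs, wraps = FALSE, stringsAsFactors = FALSE)
        reps <- data.frame(replicon_id = gid, length = repLen,
                           circular = spec$circular,
                           stringsAsFactors = FALSE)
        genomes[[gid]] <- GenomeAnnotation(gid, reps, genes)
        prots <- c(prots, stats::setNames(seqs[kind == "CDS"],
                                          geneId[kind == "CDS"]))
        gfRows[[gi]] <- data.frame(
            genome_id = gid, gene_id = geneId,
            family_id = ifelse(is.na(slotFam), "background", slotFam),
            stringsAsFactors = FALSE)
        unitRows[[gi]] <- data.frame(genome_id = gid, gene_id = geneId,
                                     unit = unit, stringsAsFactors = FALSE)
    }
    geneFamilies <- do.call(rbind, gfRows)
    arch <- geneFamilies$family_id[geneFamilies$family_id != "background"]
    names(arch) <- geneFamilies$gene_id[
        geneFamilies$family_id != "background"]
    cdsIds <- names(prots)
    arch <- arch[names(arch) %in% cdsIds]
    list(genomes = genomes,
         proteins = Biostrings::AAStringSet(prots),
         ancestors = ancestors,
         truth = list(
             geneFamilies = geneFamilies,
             units = do.call(rbind, unitRows),
             plantedAssociations = if (length(assocRows))
                 do.call(rbind, assocRows) else
                 data.frame(query_family = character(0),
                            partner_family = character(0),
                            genome_id = character(0),
                            same_directon = logical(0),
                            stringsAsFactors = FALSE),
             architectures = arch))
}

#' Write a generated cohort to disk
#'
#' Emits one PTT per genome, the cohort protein FASTA, ground-truth TSVs
#' (\code{gene_families.tsv}, \code{planted_contexts.tsv},
#' \code{architectures.tsv}), an RNA-feature TSV per genome carrying RNA
#' genes, and (optionally) GenBank files.
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param dir output directory (created if missing).
#' @param genbank also write one GenBank file per genome (default: only
#'   when RNA features are present).
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir, genbank = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    anyRna <- any(vapply(cohort$genomes, function(g)
        any(genes(g)$feature_kind != "CDS"), logical(1)))
    if (is.null(genbank)) genbank <- anyRna
    for (gid in names(cohort$genomes)) {
        g <- cohort$genomes[[gid]]
        writePtt(g, file.path(dir, paste0(gid, ".ptt")))
        rna <- genes(g)[genes(g)$feature_kind != "CDS", , drop = FALSE]
        if (nrow(rna))
            utils::write.table(
                data.frame(gene_id = rna$gene_id,
                           replicon = rna$replicon_id, start = rna$start,
                           end = rna$end, strand = rna$strand,
                           kind = rna$feature_kind, product = rna$product),
                file.path(dir, paste0(gid, ".rna.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
        if (genbank) writeGenBank(g, file.path(dir, paste0(gid, ".gbk")))
    }
    writeFastaFile(cohort$proteins, file.path(dir, "proteins.faa"))
    utils::write.table(cohort$truth$geneFamilies,
                       file.path(dir, "gene_families.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$truth$plantedAssociations,
                       file.path(dir, "planted_contexts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(protein_id = names(cohort$truth$architectures),
                   architecture = unname(cohort$truth$architectures)),
        file.path(dir, "architectures.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(dir)
}

#' Compare pipeline output against planted ground truth
#'
#' @param truth the \code{truth} element of a
#'   \code{\link{generateCohort}} result.
#' @param associations association table from
#'   \code{\link{scoreAssociations}} (partner keys are family labels when
#'   clusters were annotated with the generator's architectures).
#' @param clusterSet optional \linkS4class{ClusterSet} over the cohort
#'   proteins, compared against the planted family partition (background
#'   proteins count as singleton families).
#' @return list: \code{perAssociation} data frame (planted association,
#'   detected flag, observed and planted genome counts, count error),
#'   \code{precision}, \code{recall}, and -- when \code{clusterSet} is
#'   given -- \code{partitionExact} and \code{randIndex}.
#' @export
recoveryReport <- function(truth, associations, clusterSet = NULL) {
    planted <- truth$plantedAssociations
    agg <- if (nrow(planted))
        stats::aggregate(genome_id ~ query_family + partner_family +
                             same_directon, data = planted,
                         FUN = function(x) length(unique(x)))
    else data.frame(query_family = character(0),
                    partner_family = character(0),
                    same_directon = logical(0), genome_id = integer(0))
    names(agg)[names(agg) == "genome_id"] <- "n_planted"
    obsCol <- ifelse(agg$same_directon, "n_genomes_same_directon",
                     "n_genomes_neighborhood")
    hit <- match(agg$partner_family, associations$partner_key)
    observed <- vapply(seq_along(hit), function(i)
        if (is.na(hit[i])) 0L else
            as.integer(associations[[obsCol[i]]][hit[i]]),
        integer(1))
    per <- data.frame(agg, detected = !is.na(hit), n_observed = observed,
                      count_error = observed - agg$n_planted,
                      stringsAsFactors = FALSE)
    recall <- if (nrow(per)) mean(per$detected) else NA_real_
    precision <- if (nrow(associations))
        mean(associations$partner_key %in% agg$partner_family)
    else NA_real_
    out <- list(perAssociation = per, precision = precision,
                recall = recall)
    if (!is.null(clusterSet)) {
        memb <- membership(clusterSet)
        fam <- truth$geneFamilies
        fam <- fam[fam$gene_id %in% names(memb), , drop = FALSE]
        planted <- ifelse(fam$family_id == "background",
                          paste0("bg_", fam$gene_id), fam$family_id)
        pred <- unname(memb[fam$gene_id])
        out$randIndex <- randIndex(planted, pred)
        predParts <- split(fam$gene_id, pred)
        trueParts <- split(fam$gene_id, planted)
        canon <- function(p) sort(unname(vapply(p, function(x)
            paste(sort(x), collapse = ","), character(1))))
        out$partitionExact <- identical(canon(predParts),
                                        canon(trueParts))
    }
    out
}

#' Pairwise Rand index between two partitions
#'
#' @param a,b label vectors over the same elements.
#' @return Rand index in [0, 1]; 1 for identical partitions.
#' @export
randIndex <- function(a, b) {
    stopifnot(length(a) == length(b))
    n <- length(a)
    if (n < 2L) return(1)
    tab <- table(a, b)
    sumIJ <- sum(choose(tab, 2))
    sumA <- sum(choose(rowSums(tab), 2))
    sumB <- sum(choose(colSums(tab), 2))
    total <- choose(n, 2)
    (total + 2 * sumIJ - sumA - sumB) / total
}
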