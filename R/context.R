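## Cross-genome conserved-context detection ("guilt by association"):
## partner families recurring in the neighborhoods of a query family
## across genomes, with an empirical permutation p-value obtained by
## shuffling gene identities over the fixed coordinate/strand template of
## each replicon.

#' Context-analysis parameters
#'
#' @param minGenomes minimum number of distinct genomes in which a partner
#'   must occur in the query's neighborhood to be reported (default 3).
#' @param nPermutations permutations for the empirical null (default 1000).
#' @param rngSeed seed for the permutation generator.
#' @param countMode statistic used by \code{\link{permutationNull}}:
#'   \code{"same_directon"} (promoter-sharing neighbors only, default) or
#'   \code{"any_neighbor"}.  \code{\link{scoreAssociations}} always
#'   reports both counts.
#' @return a validated list of class \code{ContextConfig}.
#' @export
contextConfig <- function(minGenomes = 3L, nPermutations = 1000L,
                          rngSeed = 1L,
                          countMode = c("same_directon", "any_neighbor")) {
    countMode <- match.arg(countMode)
    stopifnot(minGenomes >= 1L, nPermutations >= 0L)
    structure(list(minGenomes = as.integer(minGenomes),
                   nPermutations = as.integer(nPermutations),
                   rngSeed = as.integer(rngSeed), countMode = countMode),
              class = "ContextConfig")
}

## Normalize free-text RNA product names so isoacceptor variants aggregate
## ("tRNA-Leu-1", "tRNA-Leu 2" -> "trna-leu").
.normalizeRnaProduct <- function(x) {
    x <- tolower(trimws(x))
    sub("[-_ ][0-9]+$", "", x)
}

.rnaKey <- function(kind, product) {
    paste0(kind, ":", .normalizeRnaProduct(product))
}

## Partner key for a CDS: its cluster's architecture label when one is
## assigned (and informative), else the cluster id.  Keys must be unique
## per family, so "unannotated" falls back to the cluster id.
.clusterKeys <- function(clusterSet) {
    ids <- names(clusters(clusterSet))
    labs <- clusterLabels(clusterSet)
    key <- ids
    if (length(labs)) {
        lab <- unname(labs[ids])
        usable <- !is.na(lab) & nzchar(lab) & lab != "unannotated"
        shared <- lab %in% lab[duplicated(lab)]   # same label, two clusters
        ok <- usable & !shared
        key[ok] <- lab[ok]
    }
    stats::setNames(key, ids)
}

#' Resolve query seeds from a cluster label
#'
#' @param clusterSet an annotated \linkS4class{ClusterSet}.
#' @param label cluster label (or cluster id) naming the query family.
#' @param genomes named list of \linkS4class{GenomeAnnotation}.
#' @return named list (one element per genome that carries the family) of
#'   seed gene ids, suitable for \code{\link{collectNeighborhoods}}.
#' @export
queryFromCluster <- function(clusterSet, label, genomes) {
    cl <- clusters(clusterSet)
    labs <- clusterLabels(clusterSet)
    hit <- names(cl)[names(cl) == label]
    if (!length(hit) && length(labs))
        hit <- names(labs)[labs == label]
    if (!length(hit))
        stop("no cluster with id or label: ", label)
    members <- unlist(cl[hit], use.names = FALSE)
    seeds <- lapply(genomes, function(g)
        intersect(genes(g)$gene_id, members))
    seeds[lengths(seeds) > 0L]
}

#' Extract neighborhoods of a query family across genomes
#'
#' @param genomes named list of \linkS4class{GenomeAnnotation} (names are
#'   genome ids; unnamed lists are named from \code{genomeId}).
#' @param seeds named list of per-genome query gene-id vectors; genomes
#'   absent from \code{seeds} contribute no neighborhood.
#' @param nconfig a \code{\link{neighborhoodConfig}}.
#' @return list of \linkS4class{Neighborhood} objects, one per seed.
#' @export
collectNeighborhoods <- function(genomes, seeds,
                                 nconfig = neighborhoodConfig()) {
    if (is.null(names(genomes)))
        names(genomes) <- vapply(genomes, genomeId, character(1))
    out <- list()
    for (gid in names(seeds)) {
        if (!gid %in% names(genomes))
            stop("seeds name a genome not supplied: ", gid)
        genome <- genomes[[gid]]
        directons <- inferDirectons(genome, nconfig$maxGap)
        for (s in seeds[[gid]]) {
            if (!s %in% genes(genome)$gene_id)
                stop("seed gene ", s, " not found in genome ", gid)
            out[[length(out) + 1L]] <-
                extractNeighborhood(genome, s, nconfig, directons)
        }
    }
    out
}

## Partner keys for every neighbor row of one neighborhood (query row
## excluded); errors if a CDS neighbor is not in the cluster set.
.neighborKeys <- function(nbh, memb, keys) {
    nb <- neighbors(nbh)
    nb <- nb[nb$offset != 0L, , drop = FALSE]
    if (!nrow(nb)) return(nb[, c("gene_id", "promoter_sharing")][0, ])
    isCDS <- nb$feature_kind == "CDS"
    key <- character(nrow(nb))
    if (any(isCDS)) {
        cid <- memb[nb$gene_id[isCDS]]
        if (anyNA(cid))
            stop("CDS neighbor not present in ClusterSet: ",
                 paste(nb$gene_id[isCDS][is.na(cid)], collapse = ", "))
        key[isCDS] <- keys[cid]
    }
    key[!isCDS] <- .rnaKey(nb$feature_kind[!isCDS], nb$product[!isCDS])
    data.frame(partner_key = key, promoter_sharing = nb$promoter_sharing,
               stringsAsFactors = FALSE)
}

#' Score cross-genome partner associations of a query family
#'
#' For every partner family (cluster of CDS neighbors, or RNA feature key
#' \code{kind:product}) found in the collected neighborhoods, counts the
#' distinct genomes in which it occurs anywhere in the window
#' (\code{n_genomes_neighborhood}) and restricted to promoter-sharing
#' neighbors (\code{n_genomes_same_directon}).  A genome contributes at
#' most one count per partner however many copies it carries.  The query
#' family's own key is excluded.
#'
#' @param neighborhoods list of \linkS4class{Neighborhood} from
#'   \code{\link{collectNeighborhoods}}.
#' @param clusterSet \linkS4class{ClusterSet} covering every CDS neighbor.
#' @param config a \code{\link{contextConfig}}.
#' @param taxonGroups optional named vector mapping genome id to a taxon
#'   group; when given, counts collapse to one per group.
#' @return data frame sorted by \code{n_genomes_same_directon} then
#'   \code{n_genomes_neighborhood} (descending): \code{partner_key},
#'   \code{n_genomes_neighborhood}, \code{n_genomes_same_directon},
#'   \code{genome_ids} (comma-separated), \code{p_empirical} (NA until
#'   \code{\link{permutationNull}} is run).
#' @export
scoreAssociations <- function(neighborhoods, clusterSet,
                              config = contextConfig(),
                              taxonGroups = NULL) {
    memb <- membership(clusterSet)
    keys <- .clusterKeys(clusterSet)
    rows <- list()
    queryKeys <- character(0)
    for (nbh in neighborhoods) {
        gid <- genomeId(nbh)
        qid <- queryId(nbh)
        if (qid %in% names(memb))
            queryKeys <- union(queryKeys, keys[[memb[[qid]]]])
        nk <- .neighborKeys(nbh, memb, keys)
        if (nrow(nk))
            rows[[length(rows) + 1L]] <- data.frame(
                genome = gid, nk, stringsAsFactors = FALSE)
    }
    empty <- data.frame(partner_key = character(0),
                        n_genomes_neighborhood = integer(0),
                        n_genomes_same_directon = integer(0),
                        genome_ids = character(0),
                        p_empirical = numeric(0), stringsAsFactors = FALSE)
    if (!length(rows)) return(empty)
    tab <- do.call(rbind, rows)
    tab <- tab[!tab$partner_key %in% queryKeys, , drop = FALSE]
    if (!nrow(tab)) return(empty)
    unit <- if (is.null(taxonGroups)) tab$genome else
        unname(taxonGroups[tab$genome])
    byKey <- split(seq_len(nrow(tab)), tab$partner_key)
    res <- lapply(names(byKey), function(k) {
        i <- byKey[[k]]
        data.frame(partner_key = k,
                   n_genomes_neighborhood = length(unique(unit[i])),
                   n_genomes_same_directon =
                       length(unique(unit[i][tab$promoter_sharing[i]])),
                   genome_ids = paste(sort(unique(tab$genome[i])),
                                      collapse = ","),
                   p_empirical = NA_real_, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res <- res[res$n_genomes_neighborhood >= config$minGenomes, ,
               drop = FALSE]
    res <- res[order(-res$n_genomes_same_directon,
                     -res$n_genomes_neighborhood, res$partner_key,
                     method = "radix"), , drop = FALSE]
    rownames(res) <- NULL
    res
}

## ---- permutation null -------------------------------------------------
## Shuffling gene identities leaves coordinates, strands -- hence
## directons, windows and promoter-sharing relations between POSITIONS --
## unchanged.  We therefore precompute, per replicon position, the window
## position set and its promoter-sharing subset once, and per permutation
## only re-draw which positions carry query and partner genes.  This is
## exactly equivalent to re-extracting every neighborhood per permutation.

.contextTemplate <- function(genome, nconfig) {
    directons <- inferDirectons(genome, nconfig$maxGap)
    reps <- replicons(genome)
    out <- list()
    for (r in seq_len(nrow(reps))) {
        rid <- reps$replicon_id[r]
        rg <- .repliconGenes(genome, rid)
        n <- nrow(rg)
        if (!n) next
        win <- vector("list", n); share <- vector("list", n)
        for (p in seq_len(n)) {
            nbh <- extractNeighborhood(genome, rg$gene_id[p], nconfig,
                                       directons)
            nb <- neighbors(nbh)
            nb <- nb[nb$offset != 0L, , drop = FALSE]
            win[[p]] <- nb$ordinal
            share[[p]] <- nb$ordinal[nb$promoter_sharing]
        }
        out[[rid]] <- list(ids = rg$gene_id, win = win, share = share)
    }
    out
}

## Count = does this genome link any query position to a partner position?
.genomeHit <- function(tmpl, assign, querySet, partnerSet, mode) {
    for (rid in names(tmpl)) {
        tp <- tmpl[[rid]]
        lab <- assign[[rid]]
        qpos <- which(lab %in% querySet)
        if (!length(qpos)) next
        ppos <- which(lab %in% partnerSet) - 1L   # 0-based ordinals
        if (!length(ppos)) next
        for (q in qpos) {
            ws <- if (mode == "same_directon") tp$share[[q]] else tp$win[[q]]
            if (any(ppos %in% ws)) return(TRUE)
        }
    }
    FALSE
}

#' Resolve the member gene ids of a partner key in one genome
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param partnerKey a cluster label/id or an RNA key \code{kind:product}.
#' @param clusterSet the \linkS4class{ClusterSet} used for scoring.
#' @return character vector of gene ids (possibly empty).
#' @export
partnerMembers <- function(genome, partnerKey, clusterSet) {
    g <- genes(genome)
    if (grepl("^(tRNA|rRNA|other_RNA):", partnerKey)) {
        rna <- g$feature_kind != "CDS"
        return(g$gene_id[rna][.rnaKey(g$feature_kind[rna],
                                      g$product[rna]) == partnerKey])
    }
    keys <- .clusterKeys(clusterSet)
    cid <- names(keys)[keys == partnerKey]
    members <- unlist(clusters(clusterSet)[cid], use.names = FALSE)
    intersect(g$gene_id, members)
}

#' Empirical permutation p-value for a partner association
#'
#' For each permutation, gene identities are shuffled within every
#' replicon while coordinates and strands stay fixed as a template;
#' neighborhoods are (implicitly) re-extracted and the partner's genome
#' count recomputed.  The p-value uses the add-one convention
#' \code{p = (1 + #(perm >= observed)) / (1 + nPermutations)} and is
#' deterministic under \code{config$rngSeed}.
#'
#' @param genomes named list of \linkS4class{GenomeAnnotation}.
#' @param seeds named per-genome list of query gene ids (as for
#'   \code{\link{collectNeighborhoods}}).
#' @param partnerKey the partner family key being tested.
#' @param clusterSet \linkS4class{ClusterSet} for resolving CDS partners.
#' @param nconfig a \code{\link{neighborhoodConfig}}.
#' @param config a \code{\link{contextConfig}} (seed, permutation count,
#'   count mode).
#' @return list with \code{observed} (genome count), \code{p_empirical}.
#' @export
permutationNull <- function(genomes, seeds, partnerKey, clusterSet,
                            nconfig = neighborhoodConfig(),
                            config = contextConfig()) {
    if (is.null(names(genomes)))
        names(genomes) <- vapply(genomes, genomeId, character(1))
    stopifnot(config$nPermutations >= 1L)
    use <- names(genomes)[names(genomes) %in% names(seeds)]
    tmpl <- lapply(genomes[use], .contextTemplate, nconfig = nconfig)
    partners <- lapply(genomes[use], partnerMembers,
                       partnerKey = partnerKey, clusterSet = clusterSet)
    identityAssign <- lapply(tmpl, function(tg) lapply(tg, `[[`, "ids"))
    observed <- sum(vapply(use, function(g)
        .genomeHit(tmpl[[g]], identityAssign[[g]], seeds[[g]],
                   partners[[g]], config$countMode), logical(1)))
    old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(config$rngSeed)
    hits <- integer(config$nPermutations)
    for (b in seq_len(config$nPermutations)) {
        cnt <- 0L
        for (g in use) {
            shuffled <- lapply(identityAssign[[g]], sample)
            if (.genomeHit(tmpl[[g]], shuffled, seeds[[g]],
                           partners[[g]], config$countMode))
                cnt <- cnt + 1L
        }
        hits[b] <- cnt
    }
    p <- (1 + sum(hits >= observed)) / (1 + config$nPermutations)
    list(observed = observed, p_empirical = p)
}

#' Write association results as TSV
#'
#' @param associations data frame from \code{\link{scoreAssociations}}.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeAssociationsTsv <- function(associations, file) {
    utils::write.table(associations, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
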