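## End-to-end orchestration: read annotations -> neighborhoods ->
## neighbor-protein clustering -> cross-genome associations with
## permutation p-values, with a JSON run manifest so that a fixed config
## and seed reproduce byte-identical outputs.

#' Pipeline configuration
#'
#' Captures every stage parameter in one object.  The defaults are the
#' pipeline's standard settings: 5 neighbors per side, a 150-nt
#' intergenic gap bound for directons, and a 0.01 inclusion e-value for
#' the search stage; all are surfaced in the run manifest.
#'
#' @param genomes named list of \linkS4class{GenomeAnnotation}, or a list
#'   of per-genome input descriptors (lists with \code{path},
#'   \code{format} = \code{"ptt"}/\code{"genbank"}, and for PTT:
#'   \code{genome_id}, \code{replicon_length}, \code{circular}, optional
#'   \code{proteins} FASTA and \code{rna_tsv}).
#' @param query named list of per-genome seed gene ids, or a single
#'   cluster label to resolve after clustering.
#' @param nconfig a \code{\link{neighborhoodConfig}}.
#' @param thresholds a \code{\link{clusterThresholds}}.
#' @param context a \code{\link{contextConfig}}.
#' @param architectures named character vector (or TSV path) of domain
#'   architectures for cluster labeling; optional.
#' @param eCut inclusion e-value recorded for search stages (default
#'   0.01).
#' @param outDir output directory.
#' @param rngSeed global seed; propagated to the permutation stage.
#' @return a list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(genomes, query,
                           nconfig = neighborhoodConfig(),
                           thresholds = clusterThresholds(),
                           context = contextConfig(),
                           architectures = NULL, eCut = 0.01,
                           outDir = "geneContext_out", rngSeed = 1L) {
    structure(list(genomes = genomes, query = query, nconfig = nconfig,
                   thresholds = thresholds, context = context,
                   architectures = architectures, eCut = eCut,
                   outDir = outDir, rngSeed = as.integer(rngSeed)),
              class = "PipelineConfig")
}

.loadGenomeInput <- function(desc) {
    if (methods::is(desc, "GenomeAnnotation")) return(desc)
    g <- switch(desc$format,
        ptt = readPtt(desc$path, genomeId = desc$genome_id,
                      repliconLength = desc$replicon_length,
                      circular = isTRUE(desc$circular)),
        genbank = readGenBank(desc$path),
        stop("unknown genome format: ", desc$format))
    if (!is.null(desc$rna_tsv)) g <- readRnaFeatures(g, desc$rna_tsv)
    if (!is.null(desc$proteins))
        g <- joinProteins(g, readFastaFile(desc$proteins))
    g
}

#' Run the full genomic-context pipeline
#'
#' Executes read, neighborhood extraction, promoter-sharing tagging,
#' neighbor-protein clustering, cluster annotation, association scoring
#' and permutation testing, writing \code{neighborhoods.tsv},
#' \code{clusters.tsv}, \code{associations.tsv} and a JSON run manifest
#' to the configured output directory.  Outputs are deterministic for
#' fixed inputs and seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param verbose print per-stage record counts (default TRUE, to
#'   standard error).
#' @return invisibly, a list with the in-memory stage results
#'   (\code{genomes}, \code{neighborhoods}, \code{clusters},
#'   \code{associations}, \code{outDir}).
#' @export
runContextPipeline <- function(config, verbose = TRUE) {
    stopifnot(inherits(config, "PipelineConfig"))
    note <- function(...) if (verbose) message("[geneContext] ", ...)
    if (!length(config$genomes))
        stop("configuration error: empty genome list")
    genomes <- lapply(config$genomes, .loadGenomeInput)
    if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
        names(genomes) <- vapply(genomes, genomeId, character(1))
    note("genomes read: ", length(genomes), " (",
         sum(vapply(genomes, function(g) nrow(genes(g)), integer(1))),
         " genes)")

    arch <- config$architectures
    if (is.character(arch) && length(arch) == 1L && file.exists(arch))
        arch <- readArchitectures(arch)
    allProteins <- do.call(c, unname(lapply(genomes, genomeProteins)))

    seeds <- config$query
    fullClusters <- NULL
    if (is.character(seeds) && length(seeds) == 1L) {
        ## query named by family label: cluster the full CDS complement
        ## to resolve the seeds, and reuse that cluster set downstream
        edges <- buildSimilarityGraph(allProteins, config$thresholds)
        fullClusters <- clusterSingleLinkage(names(allProteins), edges)
        if (!is.null(arch))
            fullClusters <- annotateClusters(fullClusters, arch)
        seeds <- queryFromCluster(fullClusters, config$query, genomes)
    }
    if (!length(seeds))
        stop("data error: query family resolves to no seeds")
    neighborhoods <- collectNeighborhoods(genomes, seeds, config$nconfig)
    note("neighborhoods: ", length(neighborhoods))

    if (is.null(fullClusters)) {
        ## cluster the proteins of all neighbor genes (queries included)
        nbIds <- unique(unlist(lapply(neighborhoods, function(nbh) {
            nb <- neighbors(nbh)
            nb$gene_id[nb$feature_kind == "CDS"]
        })))
        seqs <- allProteins[names(allProteins) %in% nbIds]
        edges <- buildSimilarityGraph(seqs, config$thresholds)
        clusterSet <- clusterSingleLinkage(names(seqs), edges)
        if (!is.null(arch))
            clusterSet <- annotateClusters(clusterSet, arch)
    } else {
        clusterSet <- fullClusters   # edges already computed above
    }
    note("similarity edges: ", nrow(edges))
    note("clusters: ", length(clusters(clusterSet)))

    associations <- scoreAssociations(neighborhoods, clusterSet,
                                      config$context)
    if (nrow(associations) && config$context$nPermutations > 0L) {
        for (i in seq_len(nrow(associations))) {
            associations$p_empirical[i] <- permutationNull(
                genomes, seeds, associations$partner_key[i], clusterSet,
                config$nconfig, config$context)$p_empirical
        }
    }
    note("associations reported: ", nrow(associations))

    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    nbTab <- do.call(rbind, lapply(neighborhoods, function(nbh) {
        cbind(genome_id = genomeId(nbh), query_id = queryId(nbh),
              neighbors(nbh))
    }))
    utils::write.table(nbTab, file.path(config$outDir,
                                        "neighborhoods.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeClustersTsv(clusterSet, file.path(config$outDir, "clusters.tsv"))
    writeAssociationsTsv(associations,
                         file.path(config$outDir, "associations.tsv"))
    manifest <- list(
        package = "geneContext",
        version = as.character(utils::packageVersion("geneContext")),
        rngSeed = config$rngSeed,
        parameters = list(
            k = config$nconfig$k, maxGap = config$nconfig$maxGap,
            bidirectionalGap = config$nconfig$bidirectionalGap,
            extendThroughDirecton = config$nconfig$extendThroughDirecton,
            minIdentity = config$thresholds$minIdentity,
            minCoverage = config$thresholds$minCoverage,
            minGenomes = config$context$minGenomes,
            nPermutations = config$context$nPermutations,
            countMode = config$context$countMode,
            eCut = config$eCut),
        counts = list(genomes = length(genomes),
                      neighborhoods = length(neighborhoods),
                      edges = nrow(edges),
                      clusters = length(clusters(clusterSet)),
                      associations = nrow(associations)))
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(genomes = genomes, neighborhoods = neighborhoods,
                   clusters = clusterSet, associations = associations,
                   outDir = config$outDir))
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors \code{\link{pipelineConfig}}: top-level keys
#' \code{genomes} (list of input descriptors), \code{query} (label or
#' mapping genome -> seed ids), and optional \code{neighborhood},
#' \code{clustering}, \code{context}, \code{architectures},
#' \code{out_dir}, \code{rng_seed}.
#'
#' @param path YAML file.
#' @return a \code{\link{pipelineConfig}}.
#' @export
loadPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    nb <- do.call(neighborhoodConfig, as.list(y$neighborhood %||% list()))
    th <- do.call(clusterThresholds, as.list(y$clustering %||% list()))
    cx <- do.call(contextConfig, as.list(y$context %||% list()))
    pipelineConfig(genomes = y$genomes, query = y$query, nconfig = nb,
                   thresholds = th, context = cx,
                   architectures = y$architectures,
                   eCut = y$e_cut %||% 0.01,
                   outDir = y$out_dir %||% "geneContext_out",
                   rngSeed = y$rng_seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
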