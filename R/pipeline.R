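# End-to-end orchestration: ingest -> similarity network -> communities ->
# community gene sets -> enrichment -> variant mapping, with a run report
# mirroring the headline quantities of the analysis and deterministic
# artifact exports.

.default_pipeline_config <- function() {
  list(
    simulate = FALSE,
    synthetic = list(),          # overrides for syntheticConfig()
    gdaTable = NULL,             # paths, used when simulate = FALSE
    gdaColumnMap = NULL,
    termList = NULL,             # NULL = bundled brain disease terms
    minScore = 0,
    resolution = 1,
    seed = 42L,
    gmt = NULL,
    variantTable = NULL,
    variantColumnMap = NULL,
    gqMin = 99,
    mafMax = 0.01,
    parentRefMin = 0.95,
    parentAltMax = 0.01,
    fdrThreshold = 0.05,
    minPathwaySize = 3,
    maxPathwaySize = 2000,
    correctionScope = "source",
    minVariantCount = 2,
    geneScores = NULL,           # named vector or 2-column TSV path
    quiet = FALSE)
}

.stage <- function(name, quiet, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  if (!quiet)
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full disease-similarity pipeline
#'
#' Executes ingest, similarity-network construction, Leiden community
#' detection, community gene-set decomposition, pathway
#' over-representation, and variant mapping from a single configuration,
#' and assembles a run report carrying the analysis' headline quantities
#' (term/edge/community counts, modularity, per-community gene counts and
#' exclusive proportions, filtered-variant counts, consequence shares,
#' per-community variant shares, top recurrent genes). The report's
#' modularity is recomputed independently at assembly time and must agree
#' with the optimiser's to 1e-12. The report contains no timestamps, so
#' reruns with an identical configuration are byte-identical.
#'
#' @param config a named list of configuration keys, or the path of a YAML
#'   file holding one. Keys (all optional): \code{simulate} (logical; use
#'   the synthetic generators), \code{synthetic} (list of
#'   [syntheticConfig()] overrides), \code{gdaTable}, \code{gdaColumnMap},
#'   \code{termList} (term TSV path; default: bundled brain disease
#'   terms), \code{minScore}, \code{resolution}, \code{seed}, \code{gmt},
#'   \code{variantTable}, \code{variantColumnMap}, \code{gqMin},
#'   \code{mafMax}, \code{parentRefMin}, \code{parentAltMax},
#'   \code{fdrThreshold}, \code{minPathwaySize}, \code{maxPathwaySize},
#'   \code{correctionScope}, \code{minVariantCount}, \code{geneScores},
#'   \code{quiet}. Unknown keys are an error.
#' @param outDir optional directory; when given, all artifact files (edge
#'   list, GraphML, partition, gene sets, enrichment, variant summaries,
#'   report JSON) are written there.
#' @return invisibly, a list with \code{report} plus the intermediate
#'   objects (\code{map}, \code{network}, \code{partition},
#'   \code{geneSets}, \code{enrichment}, \code{variants}, \code{truth}).
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- .default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("invalid config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  quiet <- isTRUE(cfg$quiet)
  truth <- NULL
  collection <- NULL
  variantRecords <- NULL
  inputHashes <- list()

  if (isTRUE(cfg$simulate)) {
    sim <- .stage("simulate", quiet, {
      scfg <- do.call(syntheticConfig,
                      utils::modifyList(list(seed = cfg$seed), cfg$synthetic))
      gda <- simulateGdaTable(scfg)
      pw <- simulatePathways(scfg, gda$truth)
      vt <- simulateVariantTable(scfg, gda$truth)
      list(records = gda$records, truth = gda$truth,
           collection = pw$collection, plantedTerms = pw$plantedTerms,
           variants = vt)
    })
    records <- sim$records
    truth <- sim$truth
    truth$plantedTerms <- sim$plantedTerms
    collection <- sim$collection
    variantRecords <- sim$variants
    terms <- NULL
  } else {
    if (is.null(cfg$gdaTable))
      stop("stage 'ingest' failed: no gene-disease association table configured",
           call. = FALSE)
    inputHashes$gdaTable <- unname(tools::md5sum(cfg$gdaTable))
    records <- .stage("ingest", quiet,
                      readGdaTable(cfg$gdaTable, columnMap = cfg$gdaColumnMap))
    terms <- if (is.null(cfg$termList)) brainDiseaseTerms()
             else .read_tsv(cfg$termList)
    records <- selectDiseaseTerms(records, terms)
    if (!is.null(cfg$gmt)) {
      inputHashes$gmt <- unname(tools::md5sum(cfg$gmt))
      collection <- readGmt(cfg$gmt)
    }
    if (!is.null(cfg$variantTable)) {
      inputHashes$variantTable <- unname(tools::md5sum(cfg$variantTable))
      variantRecords <- readVariantTable(cfg$variantTable,
                                         columnMap = cfg$variantColumnMap)
    }
  }

  map <- .stage("gene map", quiet,
                buildDiseaseGeneMap(records, terms = terms,
                                    minScore = cfg$minScore))
  net <- .stage("network", quiet, buildSimilarityNetwork(map))
  partition <- .stage("communities", quiet,
                      leidenCommunities(net, resolution = cfg$resolution,
                                        seed = cfg$seed))
  sets <- .stage("gene sets", quiet, communityGeneSets(map, partition))

  background <- sort(unique(records$geneSymbol))
  enrichment <- NULL
  if (!is.null(collection)) {
    enrichment <- .stage("enrichment", quiet, {
      res <- lapply(names(exclusiveGenes(sets)), function(c) {
        q <- exclusiveGenes(sets)[[c]]
        if (!length(q)) return(NULL)
        r <- enrichGeneSets(q, collection, background,
                            minSize = cfg$minPathwaySize,
                            maxSize = cfg$maxPathwaySize,
                            fdrThreshold = cfg$fdrThreshold,
                            correctionScope = cfg$correctionScope)
        if (nrow(r)) cbind(community = c, r) else NULL
      })
      do.call(rbind, res)
    })
  }

  variants <- NULL
  if (!is.null(variantRecords)) {
    variants <- .stage("variants", quiet, {
      filtered <- filterDenovoLof(variantRecords, gqMin = cfg$gqMin,
                                  mafMax = cfg$mafMax,
                                  parentRefMin = cfg$parentRefMin,
                                  parentAltMax = cfg$parentAltMax)
      scoreMap <- cfg$geneScores
      if (is.character(scoreMap) && length(scoreMap) == 1 &&
          file.exists(scoreMap)) {
        st <- .read_tsv(scoreMap)
        scoreMap <- stats::setNames(st[[2]], st[[1]])
      }
      ranked <- annotateGeneScores(
        rankGenesByVariantCount(filtered, minCount = cfg$minVariantCount),
        if (is.null(scoreMap)) character(0) else scoreMap)
      list(filtered = filtered,
           filterReport = loadReport(filtered),
           summary = mapVariantsToCommunities(filtered, sets),
           ranked = ranked)
    })
  }

  report <- .stage("report", quiet,
                   .assemble_report(cfg, map, net, partition, sets,
                                    enrichment, variants, truth, inputHashes))

  if (!is.null(outDir)) {
    .stage("export", quiet,
           .write_artifacts(outDir, map, net, partition, sets, enrichment,
                            variants, report))
  }
  invisible(list(report = report, map = map, network = net,
                 partition = partition, geneSets = sets,
                 enrichment = enrichment, variants = variants,
                 truth = truth))
}

.assemble_report <- function(cfg, map, net, partition, sets, enrichment,
                             variants, truth, inputHashes) {
  qCheck <- networkModularity(net, partition, cfg$resolution)
  if (abs(qCheck - modularityScore(partition)) > 1e-12)
    stop("report cross-check failed: recomputed modularity differs")
  labels <- communityLabels(partition)
  comms <- lapply(names(unionGenes(sets)), function(c) {
    list(community = c,
         nDiseases = sum(labels == as.integer(c)),
         nGenes = length(unionGenes(sets)[[c]]),
         nExclusive = length(exclusiveGenes(sets)[[c]]),
         exclusiveProportion =
           round(exclusiveProportion(sets)[[c]], 2))
  })
  rep <- list(
    nDiseaseTerms = length(geneSets(map)),
    nNetworkNodes = length(networkNodes(net)),
    nEdges = nrow(networkEdges(net)),
    modularity = modularityScore(partition),
    nCommunities = nCommunities(partition),
    communities = comms,
    provenance = list(seed = cfg$seed, resolution = cfg$resolution,
                      minScore = cfg$minScore,
                      package = "disnet",
                      version = as.character(utils::packageVersion("disnet")),
                      inputHashes = inputHashes))
  if (!is.null(truth)) {
    rep$planted <- list(
      ari = adjustedRand(labels, truth$plantedPartition[names(labels)]))
  }
  if (!is.null(enrichment)) {
    sig <- enrichment[enrichment$significant, , drop = FALSE]
    rep$enrichment <- list(
      nTested = nrow(enrichment),
      nSignificant = nrow(sig),
      topTerms = utils::head(sig[order(sig$fdr), c("community", "termId",
                                                   "fdr")], 5))
  }
  if (!is.null(variants)) {
    fr <- variants$filterReport
    rep$variants <- list(
      nInput = fr$nInput,
      nFiltered = nrow(variants$filtered),
      nGenes = length(unique(variants$filtered$geneSymbol)),
      consequencePercent =
        as.list(round(variants$summary$consequenceBreakdown, 2)),
      communityPercent = stats::setNames(
        as.list(round(variants$summary$communitySummary$proportion, 2)),
        variants$summary$communitySummary$community),
      unassigned = variants$summary$unassignedCount,
      sharedAllCommunitiesGenes = variants$summary$sharedAllCommunitiesGenes,
      topGenes = variants$ranked)
  } else {
    rep$variants <- NULL
  }
  rep
}

.write_artifacts <- function(outDir, map, net, partition, sets, enrichment,
                             variants, report) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeDiseaseGeneMap(map, file.path(outDir, "disease_gene_map.tsv"))
  writeEdgeList(net, file.path(outDir, "edges.tsv"))
  exportGraphML(net, partition, file.path(outDir, "network.graphml"))
  writePartition(partition, file.path(outDir, "partition.tsv"))
  writeCommunityGeneSets(sets, file.path(outDir, "community_genes.tsv"))
  if (!is.null(enrichment))
    writeEnrichment(enrichment, file.path(outDir, "enrichment.tsv"))
  if (!is.null(variants)) {
    .write_tsv(variants$summary$communitySummary,
               file.path(outDir, "variant_communities.tsv"))
    .write_tsv(variants$ranked, file.path(outDir, "ranked_genes.tsv"))
  }
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(outDir)
}

#' Export the network (with communities) as GraphML
#'
#' Writes a Cytoscape-importable GraphML file with a \code{weight} edge
#' attribute (Jaccard similarity) and \code{community} and \code{degree}
#' node attributes.
#'
#' @param net a [DiseaseNetwork-class].
#' @param partition optional [CommunityPartition-class] covering the
#'   network's nodes.
#' @param path output path.
#' @return the path, invisibly.
#' @export
exportGraphML <- function(net, partition = NULL, path) {
  e <- networkEdges(net)
  g <- igraph::graph_from_data_frame(
    e[, c("diseaseA", "diseaseB")], directed = FALSE,
    vertices = data.frame(name = networkNodes(net), stringsAsFactors = FALSE))
  igraph::E(g)$weight <- e$jaccard
  igraph::V(g)$degree <- unname(nodeDegree(net)[igraph::V(g)$name])
  if (!is.null(partition)) {
    labels <- communityLabels(partition)
    if (!all(networkNodes(net) %in% names(labels)))
      stop("partition does not cover the network", call. = FALSE)
    igraph::V(g)$community <- as.integer(labels[igraph::V(g)$name])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
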