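# Synthetic data with planted ground truth: gene-disease association
# tables with planted community structure, pathway collections with
# planted enriched terms, and variant tables with planted recurrently
# mutated ("hot") genes. All generators are pure functions of the config
# (seed included); each generator derives its own sub-seed from the config
# seed so outputs do not depend on call order.

#' Synthetic study configuration
#'
#' Builds and validates the configuration driving the synthetic
#' generators. The defaults emulate the statistical shape the analysis
#' assumes at desk size: 3 disease communities of 8 terms, community core
#' pools of 300 genes, a shared pool of 100, a decoy pool of 500; each
#' disease samples 100 genes, 80\% from its community core, 10\% shared,
#' 10\% noise, giving clear within- vs between-community Jaccard contrast.
#' The consequence mix matches the reported class shares for rare de novo
#' LoF SNVs (stop gain 43.32\%, frameshift deletion 36.51\%, frameshift
#' insertion 17.71\%, remainder stop loss).
#'
#' @param seed integer master seed.
#' @param nCommunities planted communities; default 3.
#' @param diseasesPerCommunity disease terms per community; default 8.
#' @param corePoolSize genes in each community's core pool; default 300.
#' @param sharedPoolSize genes shared across communities; default 100.
#' @param decoyPoolSize global noise gene pool; default 500.
#' @param genesPerDisease genes sampled per disease; default 100.
#' @param coreFraction,sharedFraction,noiseFraction sampling fractions
#'   (must sum to 1); defaults 0.8 / 0.1 / 0.1.
#' @param nPlantedPathways pathways planted in community core pools;
#'   default 3 (one per community).
#' @param decoyPathways pathways drawn uniformly from all genes; default
#'   20.
#' @param pathwaySize genes per pathway; default 30.
#' @param plantedCoreFraction fraction of a planted pathway drawn from its
#'   community's used core genes (at least 0.7); default 0.8.
#' @param nVariants total variants generated; default 500.
#' @param hotGenes named integer vector: planted recurrently mutated genes
#'   and their exact variant counts; default one SHANK3-like gene with 5.
#' @param consequenceProbs named probabilities over consequence classes
#'   (must sum to 1).
#' @param contaminationFraction probability that a variant row violates
#'   one filter criterion (for filter testing); default 0.
#' @param communityVariantWeights relative weight of each community when
#'   assigning non-hot variants to genes; default equal.
#' @return a validated config (named list, class \code{"synthetic_config"}).
#' @export
syntheticConfig <- function(seed = 42L,
                            nCommunities = 3L,
                            diseasesPerCommunity = 8L,
                            corePoolSize = 300L,
                            sharedPoolSize = 100L,
                            decoyPoolSize = 500L,
                            genesPerDisease = 100L,
                            coreFraction = 0.8,
                            sharedFraction = 0.1,
                            noiseFraction = 0.1,
                            nPlantedPathways = 3L,
                            decoyPathways = 20L,
                            pathwaySize = 30L,
                            plantedCoreFraction = 0.8,
                            nVariants = 500L,
                            hotGenes = c(HOTGENE1 = 5L),
                            consequenceProbs = c("stop gain" = 0.4332,
                                                 "frameshift deletion" = 0.3651,
                                                 "frameshift insertion" = 0.1771,
                                                 "stop loss" = 0.0246),
                            contaminationFraction = 0,
                            communityVariantWeights = NULL) {
  cfg <- list(seed = as.integer(seed), nCommunities = as.integer(nCommunities),
              diseasesPerCommunity = as.integer(diseasesPerCommunity),
              corePoolSize = as.integer(corePoolSize),
              sharedPoolSize = as.integer(sharedPoolSize),
              decoyPoolSize = as.integer(decoyPoolSize),
              genesPerDisease = as.integer(genesPerDisease),
              coreFraction = coreFraction, sharedFraction = sharedFraction,
              noiseFraction = noiseFraction,
              nPlantedPathways = as.integer(nPlantedPathways),
              decoyPathways = as.integer(decoyPathways),
              pathwaySize = as.integer(pathwaySize),
              plantedCoreFraction = plantedCoreFraction,
              nVariants = as.integer(nVariants), hotGenes = hotGenes,
              consequenceProbs = consequenceProbs,
              contaminationFraction = contaminationFraction,
              communityVariantWeights = communityVariantWeights)
  with(cfg, {
    stopifnot(nCommunities >= 1, diseasesPerCommunity >= 1,
              corePoolSize >= 1, sharedPoolSize >= 0, decoyPoolSize >= 0,
              genesPerDisease >= 1,
              coreFraction >= 0, sharedFraction >= 0, noiseFraction >= 0,
              abs(coreFraction + sharedFraction + noiseFraction - 1) < 1e-9,
              nPlantedPathways >= 0, decoyPathways >= 0, pathwaySize >= 1,
              plantedCoreFraction >= 0.7, plantedCoreFraction <= 1,
              nVariants >= 0,
              abs(sum(consequenceProbs) - 1) < 1e-9,
              all(consequenceProbs >= 0),
              contaminationFraction >= 0, contaminationFraction < 1)
    if (length(hotGenes)) {
      stopifnot(!is.null(names(hotGenes)), all(hotGenes >= 1))
      if (sum(hotGenes) > nVariants)
        stop("hot-gene counts exceed nVariants", call. = FALSE)
    }
    if (!all(names(consequenceProbs) %in% .consequence_levels))
      stop("unknown consequence class in consequenceProbs", call. = FALSE)
  })
  nCore <- round(cfg$genesPerDisease * cfg$coreFraction)
  nShared <- round(cfg$genesPerDisease * cfg$sharedFraction)
  nNoise <- cfg$genesPerDisease - nCore - nShared
  if (nCore > cfg$corePoolSize || nShared > cfg$sharedPoolSize ||
      nNoise > cfg$decoyPoolSize)
    stop("gene pool smaller than the per-disease sample drawn from it",
         call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

# Gene pools are a pure function of the config dimensions (no RNG). Hot
# genes replace the head of community core pools, round-robin, so they are
# part of the planted structure.
.synthetic_pools <- function(config) {
  core <- lapply(seq_len(config$nCommunities), function(c)
    sprintf("C%dCORE%04d", c, seq_len(config$corePoolSize)))
  if (length(config$hotGenes)) {
    hg <- toupper(names(config$hotGenes))
    for (i in seq_along(hg)) {
      c <- ((i - 1) %% config$nCommunities) + 1
      slot <- (i - 1) %/% config$nCommunities + 1
      core[[c]][slot] <- hg[i]
    }
  }
  list(core = core,
       shared = if (config$sharedPoolSize)
         sprintf("SHARED%04d", seq_len(config$sharedPoolSize)) else character(0),
       decoy = if (config$decoyPoolSize)
         sprintf("DECOY%04d", seq_len(config$decoyPoolSize)) else character(0))
}

.hot_gene_community <- function(config) {
  if (!length(config$hotGenes)) return(integer(0))
  stats::setNames(((seq_along(config$hotGenes) - 1) %% config$nCommunities) + 1,
                  toupper(names(config$hotGenes)))
}

#' Generate a synthetic gene-disease association table
#'
#' Each disease draws \code{genesPerDisease} genes: \code{coreFraction}
#' from its community's core pool, \code{sharedFraction} from the shared
#' pool, \code{noiseFraction} from the decoy pool. Planted hot genes are
#' guaranteed to occur in their community (added to its first disease if
#' unsampled). Deterministic for a fixed config.
#'
#' @param config a [syntheticConfig()].
#' @return list with \code{records} (association data.frame in the
#'   canonical dialect) and \code{truth} (planted partition, pools,
#'   per-disease gene sets, hot genes).
#' @export
simulateGdaTable <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  pools <- .synthetic_pools(config)
  nCore <- round(config$genesPerDisease * config$coreFraction)
  nShared <- round(config$genesPerDisease * config$sharedFraction)
  nNoise <- config$genesPerDisease - nCore - nShared
  hotComm <- .hot_gene_community(config)
  diseaseGenes <- list()
  plantedPartition <- integer(0)
  withr::with_seed(config$seed, {
    for (c in seq_len(config$nCommunities)) {
      for (d in seq_len(config$diseasesPerCommunity)) {
        id <- sprintf("SIM:C%d_D%02d", c, d)
        genes <- c(sample(pools$core[[c]], nCore),
                   if (nShared) sample(pools$shared, nShared),
                   if (nNoise) sample(pools$decoy, nNoise))
        diseaseGenes[[id]] <- sort(unique(genes))
        plantedPartition[id] <- c
      }
    }
    # guarantee each hot gene occurs in its community
    for (h in names(hotComm)) {
      c <- hotComm[[h]]
      ids <- names(plantedPartition)[plantedPartition == c]
      if (!any(vapply(diseaseGenes[ids], function(g) h %in% g, logical(1)))) {
        diseaseGenes[[ids[1]]] <- sort(c(diseaseGenes[[ids[1]]], h))
      }
    }
    universe <- sort(unique(unlist(diseaseGenes, use.names = FALSE)))
    records <- do.call(rbind, lapply(names(diseaseGenes), function(id) {
      g <- diseaseGenes[[id]]
      data.frame(geneId = match(g, universe), geneSymbol = g,
                 diseaseId = id,
                 diseaseName = paste("Synthetic disease", id),
                 score = round(stats::runif(length(g), 0.01, 1), 3),
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(records) <- NULL
  list(records = records,
       truth = list(plantedPartition = plantedPartition,
                    diseaseGenes = diseaseGenes,
                    corePools = pools$core, sharedPool = pools$shared,
                    decoyPool = pools$decoy,
                    hotGenes = config$hotGenes,
                    hotGeneCommunity = hotComm))
}

#' Generate a synthetic pathway collection with planted enrichment
#'
#' Plants \code{nPlantedPathways} pathways, each drawing at least 70\% of
#' its genes from one community's used core genes (core-pool genes that
#' actually occur in that community's diseases) and the rest from the
#' whole gene universe; decoy pathways are drawn uniformly from the
#' universe. Deterministic for a fixed config.
#'
#' @param config a [syntheticConfig()].
#' @param truth the \code{truth} component of [simulateGdaTable()].
#' @return list with \code{collection} (a [PathwayCollection-class]) and
#'   \code{plantedTerms} (data.frame: termId, community).
#' @export
simulatePathways <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  universe <- sort(unique(unlist(truth$diseaseGenes, use.names = FALSE)))
  usedCore <- lapply(seq_len(config$nCommunities), function(c) {
    members <- names(truth$plantedPartition)[truth$plantedPartition == c]
    intersect(truth$corePools[[c]],
              unique(unlist(truth$diseaseGenes[members], use.names = FALSE)))
  })
  nCore <- ceiling(config$pathwaySize * config$plantedCoreFraction)
  nRest <- config$pathwaySize - nCore
  ids <- character(0); nms <- character(0); genes <- list()
  planted <- data.frame(termId = character(0), community = integer(0),
                        stringsAsFactors = FALSE)
  withr::with_seed(config$seed + 1L, {
    if (config$nPlantedPathways > 0) {
      for (i in seq_len(config$nPlantedPathways)) {
        c <- ((i - 1) %% config$nCommunities) + 1
        g <- unique(c(sample(usedCore[[c]], min(nCore, length(usedCore[[c]]))),
                      if (nRest) sample(universe, nRest)))
        id <- sprintf("SIM:PW%03d", i)
        ids <- c(ids, id)
        nms <- c(nms, sprintf("Planted pathway %d (community %d)", i, c))
        genes <- c(genes, list(g))
        planted <- rbind(planted, data.frame(termId = id, community = c,
                                             stringsAsFactors = FALSE))
      }
    }
    if (config$decoyPathways > 0) {
      for (i in seq_len(config$decoyPathways)) {
        ids <- c(ids, sprintf("SIM:DECOY%03d", i))
        nms <- c(nms, sprintf("Decoy pathway %d", i))
        genes <- c(genes,
                   list(sample(universe, min(config$pathwaySize,
                                             length(universe)))))
      }
    }
  })
  collection <- new("PathwayCollection", ids = ids, termNames = nms,
                    sources = rep("SIM", length(ids)),
                    genes = lapply(genes, sort))
  list(collection = collection, plantedTerms = planted)
}

#' Generate a synthetic de novo variant table
#'
#' Hot genes receive exactly their configured variant counts; remaining
#' variants pick a community (by \code{communityVariantWeights}, default
#' equal) and then a gene uniformly from that community's generated genes.
#' Clean rows have GQ 99, MAF uniform below 0.009 (strictly under the 1\%
#' rarity threshold), parental fractions consistent with a true de novo
#' event, and a consequence class drawn from \code{consequenceProbs}. With
#' \code{contaminationFraction > 0}, each non-hot row independently
#' violates one filter criterion (low GQ, common MAF, non-LoF consequence,
#' inherited flag, or parental support) with that probability.
#' Deterministic for a fixed config.
#'
#' @param config a [syntheticConfig()].
#' @param truth the \code{truth} component of [simulateGdaTable()].
#' @return data.frame of variant records in the canonical dialect.
#' @export
simulateVariantTable <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  commGenes <- lapply(seq_len(config$nCommunities), function(c) {
    members <- names(truth$plantedPartition)[truth$plantedPartition == c]
    sort(unique(unlist(truth$diseaseGenes[members], use.names = FALSE)))
  })
  weights <- config$communityVariantWeights
  if (is.null(weights)) weights <- rep(1, config$nCommunities)
  stopifnot(length(weights) == config$nCommunities, all(weights >= 0),
            sum(weights) > 0)
  nHot <- if (length(config$hotGenes)) sum(config$hotGenes) else 0L
  nRest <- config$nVariants - nHot
  classes <- names(config$consequenceProbs)
  .emit <- function(class) {
    switch(class,
           "stop gain" = c("stop_gained", "C", "T"),
           "stop loss" = c("stop_lost", "T", "C"),
           "frameshift deletion" = c("frameshift_variant", "AT", "A"),
           "frameshift insertion" = c("frameshift_variant", "A", "AT"),
           c("missense_variant", "G", "A"))
  }
  violations <- c("gq", "maf", "consequence", "denovo", "parental")
  withr::with_seed(config$seed + 2L, {
    gene <- c(rep(toupper(names(config$hotGenes)), times = config$hotGenes),
              if (nRest > 0) vapply(sample(seq_len(config$nCommunities), nRest,
                                           replace = TRUE,
                                           prob = weights / sum(weights)),
                                    function(c) sample(commGenes[[c]], 1),
                                    character(1)))
    n <- length(gene)
    cls <- sample(classes, n, replace = TRUE, prob = config$consequenceProbs)
    emitted <- t(vapply(cls, .emit, character(3)))
    df <- data.frame(
      sampleId = sprintf("SIMSAMPLE%04d", seq_len(n)),
      geneSymbol = gene,
      consequence = emitted[, 1],
      maf = stats::runif(n, 0, 0.009),
      genotypeQuality = rep(99, n),
      parentRefFraction = stats::runif(n, 0.96, 1),
      parentAltFraction = stats::runif(n, 0, 0.009),
      deNovo = rep(TRUE, n),
      ref = emitted[, 2],
      alt = emitted[, 3],
      stringsAsFactors = FALSE)
    if (config$contaminationFraction > 0 && n > nHot) {
      hit <- which(stats::runif(n) < config$contaminationFraction)
      hit <- hit[hit > nHot]  # hot-gene rows keep their planted counts
      if (length(hit)) {
        kind <- sample(violations, length(hit), replace = TRUE)
        df$genotypeQuality[hit[kind == "gq"]] <- 50
        df$maf[hit[kind == "maf"]] <- 0.05
        df$consequence[hit[kind == "consequence"]] <- "missense_variant"
        df$deNovo[hit[kind == "denovo"]] <- FALSE
        df$parentAltFraction[hit[kind == "parental"]] <- 0.5
      }
    }
  })
  rownames(df) <- NULL
  df
}

#' Write synthetic tables in the canonical TSV dialects
#'
#' Convenience writers so generated tables exercise the same readers as
#' real data.
#'
#' @param records data.frame (association or variant dialect).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGdaTable <- function(records, path) .write_tsv(records, path)

#' @rdname writeGdaTable
#' @export
writeVariantTable <- function(records, path) .write_tsv(records, path)
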