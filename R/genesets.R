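# Community gene-set decomposition: per-community unions over member
# diseases, cross-community overlaps, and community-exclusive genes with
# exclusivity proportions.

#' Union of gene sets per community
#'
#' For each community, the union of the gene sets of its member diseases.
#'
#' @param map a [DiseaseGeneMap-class].
#' @param partition a [CommunityPartition-class] (or named integer vector)
#'   whose nodes are all present in the map.
#' @return named list of sorted gene vectors, keyed by community label.
#' @export
communityGeneUnion <- function(map, partition) {
  labels <- if (is(partition, "CommunityPartition"))
    communityLabels(partition) else partition
  missing <- setdiff(names(labels), names(geneSets(map)))
  if (length(missing))
    stop("diseases in partition missing from gene map: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  sets <- geneSets(map)
  out <- lapply(split(names(labels), labels), function(ds)
    sort(unique(unlist(sets[ds], use.names = FALSE))))
  out[order(as.integer(names(out)))]
}

#' Community gene-set decomposition
#'
#' Derives, from per-community gene-set unions, the community-exclusive
#' genes (present in exactly one community's union), all pairwise
#' cross-community overlaps, and the exclusive-gene proportion
#' \code{100 * |exclusive| / |union|} per community. Reports use two
#' decimal places; stored proportions keep full precision.
#'
#' @param x either a named list of per-community gene unions (at least two
#'   communities) or a [DiseaseGeneMap-class] (then \code{partition} is
#'   required and unions are computed with [communityGeneUnion()]).
#' @param partition a [CommunityPartition-class]; only used when \code{x}
#'   is a [DiseaseGeneMap-class].
#' @return a [CommunityGeneSets-class]. Communities with an empty union
#'   get proportion \code{NaN} and are listed in the report attribute.
#' @export
communityGeneSets <- function(x, partition = NULL) {
  unions <- if (is(x, "DiseaseGeneMap")) {
    if (is.null(partition))
      stop("partition required with a DiseaseGeneMap", call. = FALSE)
    communityGeneUnion(x, partition)
  } else x
  stopifnot(is.list(unions), !is.null(names(unions)))
  if (length(unions) < 2)
    stop("need at least 2 communities", call. = FALSE)
  unions <- lapply(unions, function(g) sort(unique(g)))
  counts <- table(unlist(unions, use.names = FALSE))
  uniqueGenes <- names(counts)[counts == 1]
  exclusives <- lapply(unions, function(g) g[g %in% uniqueGenes])
  overlaps <- list()
  nms <- names(unions)
  for (i in seq_len(length(unions) - 1)) {
    for (j in seq(i + 1, length(unions))) {
      overlaps[[paste(nms[i], nms[j], sep = "|")]] <-
        intersect(unions[[i]], unions[[j]])
    }
  }
  prop <- 100 * lengths(exclusives) / lengths(unions)
  names(prop) <- nms
  obj <- new("CommunityGeneSets", unionGenes = unions,
             exclusiveGenes = exclusives, overlap = overlaps,
             exclusiveProportion = prop)
  empty <- nms[lengths(unions) == 0]
  attr(obj, "disnetReport") <- list(emptyUnions = empty)
  obj
}

#' Export community gene sets as TSV
#'
#' Writes a long table \code{gene}, \code{community}, \code{exclusive}
#' (TRUE/FALSE) plus a summary table of per-community counts and
#' exclusive proportions (two decimal places, matching the reporting
#' convention).
#'
#' @param sets a [CommunityGeneSets-class].
#' @param path output path for the gene table; the summary goes to
#'   \code{paste0(path, ".summary.tsv")}.
#' @return the path, invisibly.
#' @export
writeCommunityGeneSets <- function(sets, path) {
  u <- unionGenes(sets)
  x <- exclusiveGenes(sets)
  rows <- lapply(names(u), function(c) {
    if (!length(u[[c]])) return(NULL)
    data.frame(gene = u[[c]], community = c,
               exclusive = u[[c]] %in% x[[c]], stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
  summary <- data.frame(
    community = names(u),
    n_genes = lengths(u),
    n_exclusive = lengths(x),
    exclusive_proportion = sprintf("%.2f", exclusiveProportion(sets)),
    stringsAsFactors = FALSE)
  .write_tsv(summary, paste0(path, ".summary.tsv"))
  invisible(path)
}
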