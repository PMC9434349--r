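#' @import methods
NULL

#' Disease-to-gene-set map
#'
#' Container for the per-disease gene sets \eqn{G_d} derived from a
#' gene-disease association table, together with an index of the disease
#' terms themselves (name, ICD codes, diagnostic category, display merge
#' group).
#'
#' @slot geneSets named list; one character vector of uppercase gene symbols
#'   per disease identifier. A set may be empty only if the input table had
#'   no records for that term.
#' @slot termIndex data.frame with columns \code{diseaseId},
#'   \code{diseaseName}, \code{icdCodes}, \code{dsm5Category},
#'   \code{mergeGroup}; one row per disease term, \code{diseaseId} unique.
#'
#' @seealso [buildDiseaseGeneMap()], [buildSimilarityNetwork()]
#' @export
setClass("DiseaseGeneMap",
  representation(geneSets = "list", termIndex = "data.frame"))

setValidity("DiseaseGeneMap", function(object) {
  gs <- object@geneSets
  ti <- object@termIndex
  msgs <- character(0)
  if (is.null(names(gs)) || any(names(gs) == ""))
    msgs <- c(msgs, "geneSets must be a named list keyed by diseaseId")
  if (!all(c("diseaseId", "diseaseName") %in% names(ti)))
    msgs <- c(msgs, "termIndex must have diseaseId and diseaseName columns")
  else {
    if (anyDuplicated(ti$diseaseId))
      msgs <- c(msgs, "diseaseId not unique in termIndex")
    if (!all(names(gs) %in% ti$diseaseId))
      msgs <- c(msgs, "every disease in geneSets must appear in termIndex")
  }
  if (!all(vapply(gs, is.character, logical(1))))
    msgs <- c(msgs, "gene sets must be character vectors")
  else if (any(vapply(gs, anyDuplicated, integer(1)) > 0))
    msgs <- c(msgs, "gene sets must not contain duplicates")
  if (length(msgs)) msgs else TRUE
})

#' Weighted disease-disease similarity network
#'
#' Undirected weighted graph whose nodes are disease terms and whose edge
#' weights are Jaccard similarities between the diseases' gene sets. Pairs
#' sharing no gene have no edge. Node degree (unweighted connection count)
#' and strength (sum of incident Jaccard weights) are stored alongside.
#'
#' @slot nodes character; disease identifiers, sorted.
#' @slot edges data.frame with columns \code{diseaseA}, \code{diseaseB}
#'   (with \code{diseaseA < diseaseB}), \code{jaccard}, \code{sharedGenes},
#'   \code{unionGenes}; one row per unordered pair, no self-loops.
#' @slot degree named numeric; connections per node.
#' @slot strength named numeric; summed incident edge weight per node.
#'
#' @seealso [buildSimilarityNetwork()], [leidenCommunities()]
#' @export
setClass("DiseaseNetwork",
  representation(nodes = "character", edges = "data.frame",
                 degree = "numeric", strength = "numeric"))

setValidity("DiseaseNetwork", function(object) {
  e <- object@edges
  msgs <- character(0)
  need <- c("diseaseA", "diseaseB", "jaccard", "sharedGenes", "unionGenes")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (!all(e$diseaseA %in% object@nodes) || !all(e$diseaseB %in% object@nodes))
      msgs <- c(msgs, "edges reference unknown nodes")
    if (any(e$diseaseA >= e$diseaseB))
      msgs <- c(msgs, "edges must satisfy diseaseA < diseaseB (no self-loops)")
    if (anyDuplicated(paste(e$diseaseA, e$diseaseB)))
      msgs <- c(msgs, "duplicate edges")
    if (any(e$jaccard != e$sharedGenes / e$unionGenes))
      msgs <- c(msgs, "jaccard must equal sharedGenes / unionGenes exactly")
    if (any(e$jaccard <= 0) || any(e$jaccard > 1))
      msgs <- c(msgs, "jaccard weights must lie in (0, 1]")
  }
  deg <- object@degree
  str <- object@strength
  if (!identical(sort(names(deg)), sort(object@nodes)) ||
      !identical(sort(names(str)), sort(object@nodes))) {
    msgs <- c(msgs, "degree/strength must be named by the node set")
  } else {
    dd <- table(factor(c(e$diseaseA, e$diseaseB), levels = object@nodes))
    if (!all(deg[object@nodes] == as.numeric(dd)))
      msgs <- c(msgs, "degree inconsistent with edge list")
    ss <- vapply(object@nodes, function(v)
      sum(e$jaccard[e$diseaseA == v | e$diseaseB == v]), numeric(1))
    if (any(abs(str[object@nodes] - ss) > 1e-9))
      msgs <- c(msgs, "strength inconsistent with edge list")
  }
  if (length(msgs)) msgs else TRUE
})

#' Community partition of a disease network
#'
#' Assignment of every network node to a community, together with the
#' weighted modularity of the assignment, the resolution parameter used, the
#' random seed, and the modularity trace of the optimisation run.
#'
#' @slot membership named integer; community label per node, labels
#'   contiguous from 0 and canonicalised by first appearance over nodes in
#'   sorted order.
#' @slot modularity numeric; weighted modularity Q of the partition.
#' @slot resolution numeric; resolution parameter gamma (> 0).
#' @slot seed integer; RNG seed used by the optimiser (NA for deterministic
#'   constructions such as the exhaustive oracle).
#' @slot nCommunities integer; number of distinct labels.
#' @slot trace numeric; Q after each optimisation phase of the winning run
#'   (non-decreasing).
#'
#' @seealso [leidenCommunities()], [bruteForceBestPartition()]
#' @export
setClass("CommunityPartition",
  representation(membership = "integer", modularity = "numeric",
                 resolution = "numeric", seed = "integer",
                 nCommunities = "integer", trace = "numeric"))

setValidity("CommunityPartition", function(object) {
  m <- object@membership
  msgs <- character(0)
  if (is.null(names(m)) || any(names(m) == ""))
    msgs <- c(msgs, "membership must be named by node id")
  labs <- sort(unique(m))
  if (length(labs) && !identical(labs, seq_along(labs) - 1L))
    msgs <- c(msgs, "community labels must be contiguous integers from 0")
  if (object@nCommunities != length(labs))
    msgs <- c(msgs, "nCommunities must equal the number of distinct labels")
  if (object@modularity < -1 - 1e-9 || object@modularity > 1 + 1e-9)
    msgs <- c(msgs, "modularity outside [-1, 1]")
  if (object@resolution <= 0)
    msgs <- c(msgs, "resolution must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Community gene-set decomposition
#'
#' Per-community gene-set unions, community-exclusive genes, pairwise
#' cross-community overlaps, and exclusive-gene proportions.
#'
#' @slot unionGenes named list; union of member diseases' gene sets per
#'   community label.
#' @slot exclusiveGenes named list; genes found in exactly one community's
#'   union; always a subset of the corresponding union, pairwise disjoint.
#' @slot overlap named list; pairwise intersections keyed
#'   \code{"<c1>|<c2>"} with \code{c1 < c2}.
#' @slot exclusiveProportion named numeric; \code{100 * |exclusive| /
#'   |union|} per community (NaN when a union is empty).
#'
#' @seealso [communityGeneSets()]
#' @export
setClass("CommunityGeneSets",
  representation(unionGenes = "list", exclusiveGenes = "list",
                 overlap = "list", exclusiveProportion = "numeric"))

setValidity("CommunityGeneSets", function(object) {
  u <- object@unionGenes
  x <- object@exclusiveGenes
  msgs <- character(0)
  if (!identical(names(u), names(x)) ||
      !identical(names(u), names(object@exclusiveProportion)))
    msgs <- c(msgs, "unionGenes, exclusiveGenes and exclusiveProportion must share names")
  else {
    for (nm in names(u)) {
      if (!all(x[[nm]] %in% u[[nm]])) {
        msgs <- c(msgs, sprintf("exclusive genes of %s not within its union", nm))
        break
      }
    }
    allx <- unlist(x, use.names = FALSE)
    if (anyDuplicated(allx))
      msgs <- c(msgs, "exclusive sets must be pairwise disjoint")
  }
  if (length(msgs)) msgs else TRUE
})

#' Pathway collection (GMT)
#'
#' A set of named gene sets ("pathways"), each with a source tag such as
#' \code{"GO:MF"} or \code{"REAC"} used to scope multiple-testing
#' correction.
#'
#' @slot ids character; unique term identifiers.
#' @slot termNames character; human-readable term names (same length).
#' @slot sources character; source tag per term.
#' @slot genes list; character vector of uppercase gene symbols per term,
#'   non-empty, no duplicates.
#'
#' @seealso [readGmt()], [enrichGeneSets()]
#' @export
setClass("PathwayCollection",
  representation(ids = "character", termNames = "character",
                 sources = "character", genes = "list"))

setValidity("PathwayCollection", function(object) {
  n <- length(object@ids)
  msgs <- character(0)
  if (length(object@termNames) != n || length(object@sources) != n ||
      length(object@genes) != n)
    msgs <- c(msgs, "ids, termNames, sources and genes must have equal length")
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, "term ids must be unique")
  if (n && any(lengths(object@genes) == 0))
    msgs <- c(msgs, "pathway gene sets must be non-empty")
  if (length(msgs)) msgs else TRUE
})
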