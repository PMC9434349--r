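# Accessor methods and show() methods for the S4 containers.

#' @rdname DiseaseGeneMap-class
#' @export
setMethod("geneSets", "DiseaseGeneMap", function(x) x@geneSets)

#' @rdname DiseaseGeneMap-class
#' @export
setMethod("diseaseTerms", "DiseaseGeneMap", function(x) x@termIndex)

setMethod("show", "DiseaseGeneMap", function(object) {
  sizes <- lengths(object@geneSets)
  cat("DiseaseGeneMap with", length(sizes), "disease terms\n")
  if (length(sizes)) {
    cat("  gene-set sizes: min", min(sizes), "| median", stats::median(sizes),
        "| max", max(sizes), "\n")
    cat("  distinct genes:", length(unique(unlist(object@geneSets, use.names = FALSE))), "\n")
    cat("  empty sets:", sum(sizes == 0), "\n")
  }
  invisible(NULL)
})

#' @rdname DiseaseNetwork-class
#' @export
setMethod("networkNodes", "DiseaseNetwork", function(x) x@nodes)

#' @rdname DiseaseNetwork-class
#' @export
setMethod("networkEdges", "DiseaseNetwork", function(x) x@edges)

#' @rdname DiseaseNetwork-class
#' @export
setMethod("nodeDegree", "DiseaseNetwork", function(x) x@degree)

#' @rdname DiseaseNetwork-class
#' @export
setMethod("nodeStrength", "DiseaseNetwork", function(x) x@strength)

setMethod("show", "DiseaseNetwork", function(object) {
  cat("DiseaseNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  if (nrow(object@edges)) {
    cat("  Jaccard weights: min", signif(min(object@edges$jaccard), 4),
        "| median", signif(stats::median(object@edges$jaccard), 4),
        "| max", signif(max(object@edges$jaccard), 4), "\n")
    cat("  isolated nodes:", sum(object@degree == 0), "\n")
  }
  invisible(NULL)
})

#' @rdname CommunityPartition-class
#' @export
setMethod("communityLabels", "CommunityPartition", function(x) x@membership)

#' @rdname CommunityPartition-class
#' @export
setMethod("modularityScore", "CommunityPartition", function(x) x@modularity)

#' @rdname CommunityPartition-class
#' @export
setMethod("nCommunities", "CommunityPartition", function(x) x@nCommunities)

setMethod("show", "CommunityPartition", function(object) {
  cat("CommunityPartition:", length(object@membership), "nodes in",
      object@nCommunities, "communities\n")
  cat("  Q =", format(object@modularity, digits = 6),
      "at resolution", object@resolution, "\n")
  cat("  sizes:", paste(table(object@membership), collapse = ", "), "\n")
  invisible(NULL)
})

#' @rdname CommunityGeneSets-class
#' @export
setMethod("unionGenes", "CommunityGeneSets", function(x) x@unionGenes)

#' @rdname CommunityGeneSets-class
#' @export
setMethod("exclusiveGenes", "CommunityGeneSets", function(x) x@exclusiveGenes)

#' @rdname CommunityGeneSets-class
#' @export
setMethod("overlapGenes", "CommunityGeneSets", function(x) x@overlap)

#' @rdname CommunityGeneSets-class
#' @export
setMethod("exclusiveProportion", "CommunityGeneSets", function(x) x@exclusiveProportion)

setMethod("show", "CommunityGeneSets", function(object) {
  cat("CommunityGeneSets over", length(object@unionGenes), "communities\n")
  for (nm in names(object@unionGenes)) {
    cat(sprintf("  community %s: %d genes, %d exclusive (%.2f%%)\n", nm,
                length(object@unionGenes[[nm]]),
                length(object@exclusiveGenes[[nm]]),
                object@exclusiveProportion[[nm]]))
  }
  invisible(NULL)
})

#' @rdname PathwayCollection-class
#' @export
setMethod("pathwayIds", "PathwayCollection", function(x) x@ids)

#' @rdname PathwayCollection-class
#' @export
setMethod("pathwaySources", "PathwayCollection", function(x) x@sources)

#' @rdname PathwayCollection-class
#' @export
setMethod("pathwayGenes", "PathwayCollection", function(x) {
  g <- x@genes
  names(g) <- x@ids
  g
})

#' @rdname PathwayCollection-class
#' @export
setMethod("pathwayNames", "PathwayCollection", function(x) {
  n <- x@termNames
  names(n) <- x@ids
  n
})

setMethod("show", "PathwayCollection", function(object) {
  cat("PathwayCollection with", length(object@ids), "terms\n")
  if (length(object@ids)) {
    src <- table(object@sources)
    cat("  sources:", paste(names(src), src, sep = "=", collapse = ", "), "\n")
    cat("  set sizes: min", min(lengths(object@genes)),
        "| max", max(lengths(object@genes)), "\n")
  }
  invisible(NULL)
})
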