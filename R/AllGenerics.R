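# Accessor generics. Slot access stays internal; user code goes through
# these.

#' @rdname DiseaseGeneMap-class
#' @param x a disnet object
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname DiseaseGeneMap-class
#' @export
setGeneric("diseaseTerms", function(x) standardGeneric("diseaseTerms"))

#' @rdname DiseaseNetwork-class
#' @param x a disnet object
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname DiseaseNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname DiseaseNetwork-class
#' @export
setGeneric("nodeDegree", function(x) standardGeneric("nodeDegree"))

#' @rdname DiseaseNetwork-class
#' @export
setGeneric("nodeStrength", function(x) standardGeneric("nodeStrength"))

#' @rdname CommunityPartition-class
#' @param x a disnet object
#' @export
setGeneric("communityLabels", function(x) standardGeneric("communityLabels"))

#' @rdname CommunityPartition-class
#' @export
setGeneric("modularityScore", function(x) standardGeneric("modularityScore"))

#' @rdname CommunityPartition-class
#' @export
setGeneric("nCommunities", function(x) standardGeneric("nCommunities"))

#' @rdname CommunityGeneSets-class
#' @param x a disnet object
#' @export
setGeneric("unionGenes", function(x) standardGeneric("unionGenes"))

#' @rdname CommunityGeneSets-class
#' @export
setGeneric("exclusiveGenes", function(x) standardGeneric("exclusiveGenes"))

#' @rdname CommunityGeneSets-class
#' @export
setGeneric("overlapGenes", function(x) standardGeneric("overlapGenes"))

#' @rdname CommunityGeneSets-class
#' @export
setGeneric("exclusiveProportion", function(x) standardGeneric("exclusiveProportion"))

#' @rdname PathwayCollection-class
#' @param x a disnet object
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' @rdname PathwayCollection-class
#' @export
setGeneric("pathwaySources", function(x) standardGeneric("pathwaySources"))

#' @rdname PathwayCollection-class
#' @export
setGeneric("pathwayGenes", function(x) standardGeneric("pathwayGenes"))

#' @rdname PathwayCollection-class
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))
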