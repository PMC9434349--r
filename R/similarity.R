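# Jaccard similarity between disease gene sets and construction of the
# weighted disease-disease network.

#' Jaccard similarity between two gene sets
#'
#' The fraction of genes shared by two diseases: the number of shared genes
#' divided by the total number of distinct genes implicated in both
#' diseases, \eqn{|A \cap B| / |A \cup B|}.
#'
#' @param setA,setB non-empty character vectors of gene symbols.
#' @return a list with \code{jaccard}, \code{sharedGenes} and
#'   \code{unionGenes}.
#' @examples
#' jaccardIndex(c("A", "B", "C"), c("B", "C", "D"))$jaccard  # 0.5
#' @export
jaccardIndex <- function(setA, setB) {
  a <- unique(setA)
  b <- unique(setB)
  if (!length(a) || !length(b))
    stop("Jaccard similarity is undefined for an empty gene set", call. = FALSE)
  shared <- sum(a %in% b)
  uni <- length(a) + length(b) - shared
  list(jaccard = shared / uni, sharedGenes = shared, unionGenes = uni)
}

#' Build the disease-disease similarity network
#'
#' Computes pairwise Jaccard similarities between the gene sets of a
#' [DiseaseGeneMap-class] and assembles the weighted undirected disease
#' network. Nodes are diseases with non-empty gene sets; an edge exists iff
#' the two diseases share at least one gene (zero-similarity pairs get no
#' edge). Diseases with empty sets are excluded and listed in the report
#' attribute.
#'
#' @param map a [DiseaseGeneMap-class] with at least two non-empty gene
#'   sets.
#' @return a [DiseaseNetwork-class]; \code{attr(x, "disnetReport")} (see
#'   [loadReport()]) lists \code{droppedDiseases}.
#' @export
buildSimilarityNetwork <- function(map) {
  sets <- geneSets(map)
  nonEmpty <- lengths(sets) > 0
  dropped <- names(sets)[!nonEmpty]
  sets <- sets[nonEmpty]
  if (length(sets) < 2)
    stop("need at least 2 diseases with non-empty gene sets", call. = FALSE)
  nodes <- sort(names(sets))
  sets <- sets[nodes]
  n <- length(nodes)
  ea <- character(0); eb <- character(0)
  jj <- numeric(0); sh <- integer(0); un <- integer(0)
  for (i in seq_len(n - 1)) {
    gi <- sets[[i]]
    for (j in seq(i + 1, n)) {
      s <- sum(sets[[j]] %in% gi)
      if (s > 0) {
        u <- length(gi) + length(sets[[j]]) - s
        ea <- c(ea, nodes[i]); eb <- c(eb, nodes[j])
        jj <- c(jj, s / u); sh <- c(sh, s); un <- c(un, u)
      }
    }
  }
  edges <- data.frame(diseaseA = ea, diseaseB = eb, jaccard = jj,
                      sharedGenes = sh, unionGenes = un,
                      stringsAsFactors = FALSE)
  net <- .new_disease_network(nodes, edges)
  attr(net, "disnetReport") <- list(droppedDiseases = dropped)
  net
}

# Construct a DiseaseNetwork from a node vector and an edge data.frame,
# computing degree and strength.
.new_disease_network <- function(nodes, edges) {
  nodes <- sort(nodes)
  if (nrow(edges)) {
    swap <- edges$diseaseA > edges$diseaseB
    tmp <- edges$diseaseA[swap]
    edges$diseaseA[swap] <- edges$diseaseB[swap]
    edges$diseaseB[swap] <- tmp
    edges <- edges[order(edges$diseaseA, edges$diseaseB), , drop = FALSE]
    rownames(edges) <- NULL
  }
  deg <- as.numeric(table(factor(c(edges$diseaseA, edges$diseaseB),
                                 levels = nodes)))
  names(deg) <- nodes
  str <- vapply(nodes, function(v)
    sum(edges$jaccard[edges$diseaseA == v | edges$diseaseB == v]),
    numeric(1))
  new("DiseaseNetwork", nodes = nodes, edges = edges,
      degree = deg, strength = str)
}

#' Read a precomputed disease-disease similarity table
#'
#' Reads a tab-separated table of disease pairs with a Jaccard column (the
#' DisGeNET disease-to-disease dialect; canonical columns \code{diseaseId1},
#' \code{diseaseId2}, \code{jaccard}). Unordered pairs are de-duplicated;
#' self-pairs are dropped and reported; a Jaccard value outside \[0, 1\] is
#' an error.
#'
#' @param path path to the TSV (or TSV.gz) file.
#' @param columnMap optional named character vector renaming foreign headers
#'   to the canonical ones.
#' @return data.frame with columns \code{diseaseA}, \code{diseaseB}
#'   (\code{diseaseA < diseaseB}) and \code{jaccard}; the report counts
#'   \code{nSelfPairsDropped} and \code{nDuplicatesDropped}.
#' @export
readDiseaseSimilarityTable <- function(path, columnMap = NULL) {
  df <- .read_tsv(path)
  df <- .apply_column_map(df, columnMap)
  need <- c("diseaseId1", "diseaseId2", "jaccard")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing required column(s) after mapping: ",
         paste(missing, collapse = ", "), call. = FALSE)
  j <- .parse_numeric(df$jaccard, "jaccard")
  if (any(is.na(j)))
    stop("missing Jaccard value", call. = FALSE)
  if (any(j < 0 | j > 1))
    stop("Jaccard value outside [0, 1]", call. = FALSE)
  a <- pmin(trimws(df$diseaseId1), trimws(df$diseaseId2))
  b <- pmax(trimws(df$diseaseId1), trimws(df$diseaseId2))
  self <- a == b
  nSelf <- sum(self)
  a <- a[!self]; b <- b[!self]; j <- j[!self]
  dup <- duplicated(paste(a, b))
  out <- data.frame(diseaseA = a[!dup], diseaseB = b[!dup],
                    jaccard = j[!dup], stringsAsFactors = FALSE)
  out <- out[order(out$diseaseA, out$diseaseB), , drop = FALSE]
  rownames(out) <- NULL
  .set_report(out, list(nSelfPairsDropped = nSelf,
                        nDuplicatesDropped = sum(dup)))
}

#' Cross-check computed similarities against a loaded table
#'
#' Compares the Jaccard weights of a computed [DiseaseNetwork-class] with a
#' loaded pair table (e.g. the precomputed DisGeNET Jaccard column),
#' reporting pairs whose weights differ by more than \code{tol} and pairs
#' present in only one source.
#'
#' @param net a [DiseaseNetwork-class].
#' @param loaded a data.frame as returned by [readDiseaseSimilarityTable()].
#' @param tol absolute tolerance on the Jaccard weight (default 1e-6).
#' @return a list with data.frame \code{mismatches} (pair, computed,
#'   loaded, difference) and character vectors \code{computedOnly},
#'   \code{loadedOnly} of \code{"a|b"} pair keys.
#' @export
crossCheckSimilarity <- function(net, loaded, tol = 1e-6) {
  e <- networkEdges(net)
  keyC <- paste(e$diseaseA, e$diseaseB, sep = "|")
  keyL <- paste(pmin(loaded$diseaseA, loaded$diseaseB),
                pmax(loaded$diseaseA, loaded$diseaseB), sep = "|")
  common <- intersect(keyC, keyL)
  jc <- e$jaccard[match(common, keyC)]
  jl <- loaded$jaccard[match(common, keyL)]
  diff <- abs(jc - jl)
  bad <- diff > tol
  list(
    mismatches = data.frame(pair = common[bad], computed = jc[bad],
                            loaded = jl[bad], difference = diff[bad],
                            stringsAsFactors = FALSE),
    computedOnly = sort(setdiff(keyC, keyL)),
    loadedOnly = sort(setdiff(keyL, keyC)))
}

#' Strongest connections of a disease
#'
#' Neighbors of a node ranked by descending edge weight, ties broken
#' lexicographically by disease id.
#'
#' @param net a [DiseaseNetwork-class].
#' @param node a disease id present in the network.
#' @param k maximum number of neighbors to return.
#' @return data.frame with columns \code{neighbor} and \code{weight}.
#' @export
topConnections <- function(net, node, k = Inf) {
  if (!node %in% networkNodes(net))
    stop("unknown node: ", node, call. = FALSE)
  e <- networkEdges(net)
  inc <- e$diseaseA == node | e$diseaseB == node
  nb <- ifelse(e$diseaseA[inc] == node, e$diseaseB[inc], e$diseaseA[inc])
  w <- e$jaccard[inc]
  ord <- order(-w, nb)
  n <- min(length(nb), k)
  data.frame(neighbor = nb[ord][seq_len(n)], weight = w[ord][seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Export the network edge list as TSV
#'
#' Columns \code{disease_a}, \code{disease_b}, \code{jaccard},
#' \code{shared_genes}, \code{union_genes} with canonical (min, max) pair
#' ordering.
#'
#' @param net a [DiseaseNetwork-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  e <- networkEdges(net)
  .write_tsv(data.frame(disease_a = e$diseaseA, disease_b = e$diseaseB,
                        jaccard = e$jaccard, shared_genes = e$sharedGenes,
                        union_genes = e$unionGenes, stringsAsFactors = FALSE),
             path)
}
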