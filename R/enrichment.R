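# Over-representation analysis of community-exclusive gene sets: GMT
# ingestion, hypergeometric upper-tail p-values, Benjamini-Hochberg FDR
# control (applied per source tag by default), and the enrichment driver.

#' Read a GMT pathway collection
#'
#' Standard GMT lines: \code{term_id TAB description TAB gene TAB gene ...}.
#' Genes are uppercased and de-duplicated within a line; a line with fewer
#' than three fields is an error naming the line number. The source tag of
#' each term is the prefix of its id before the first colon (e.g.
#' \code{"GO"} for \code{GO:0005102}, \code{"REAC"} for
#' \code{REAC:R-HSA-162582}) unless \code{source} supplies one tag for the
#' whole file.
#'
#' @param path path to the GMT file.
#' @param source optional single source tag overriding prefix inference.
#' @return a [PathwayCollection-class].
#' @export
readGmt <- function(path, source = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("malformed GMT line ", short[1], ": fewer than 3 fields",
         call. = FALSE)
  ids <- vapply(fields, `[`, character(1), 1)
  nms <- vapply(fields, `[`, character(1), 2)
  genes <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  src <- if (is.null(source)) {
    ifelse(grepl(":", ids, fixed = TRUE), sub(":.*$", "", ids), "GMT")
  } else rep(source, length(ids))
  new("PathwayCollection", ids = ids, termNames = nms, sources = src,
      genes = genes)
}

#' Write a pathway collection as GMT
#'
#' @param collection a [PathwayCollection-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGmt <- function(collection, path) {
  lines <- vapply(seq_along(collection@ids), function(i)
    paste(c(collection@ids[i], collection@termNames[i],
            collection@genes[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability \eqn{P(X \ge k)} for \eqn{X \sim
#' \mathrm{Hypergeometric}(N, K, n)}: the chance of drawing at least
#' \code{k} pathway genes when sampling \code{n} query genes from a
#' background of \code{N} genes of which \code{K} belong to the pathway.
#' Evaluated through the log-space distribution function for numerical
#' stability.
#'
#' @param N background (universe) size.
#' @param K pathway size within the background.
#' @param n query size within the background.
#' @param k observed overlap between query and pathway.
#' @return the p-value in \[0, 1\].
#' @examples
#' hypergeomPvalue(10, 5, 4, 4)  # 5/210
#' @export
hypergeomPvalue <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || n > N || K > N || k > K)
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(K, n) <= N)",
         call. = FALSE)
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR-adjusted p-values, order-preserving with the input:
#' \eqn{q_i = \min_{j: p_{(j)} \ge p_{(i)}} p_{(j)} m / \mathrm{rank}(j)},
#' capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order as \code{p}.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis against a pathway collection
#'
#' Tests a query gene set for over-representation in each pathway of a
#' collection with the hypergeometric upper-tail test, relative to a
#' background universe. Pathways are intersected with the background and
#' kept when their effective size lies in \code{[minSize, maxSize]}.
#' Query genes outside the background are dropped and reported. BH
#' adjustment is applied within each source tag by default (GO:MF and
#' Reactome listings are corrected separately), or globally with
#' \code{correctionScope = "global"}.
#'
#' @param query character vector of gene symbols.
#' @param collection a [PathwayCollection-class].
#' @param background character vector: the gene universe.
#' @param minSize,maxSize pathway size bounds after background
#'   intersection; defaults 3 and 2000.
#' @param fdrThreshold significance threshold on the adjusted p-value;
#'   default 0.05.
#' @param correctionScope \code{"source"} (default) or \code{"global"}.
#' @return data.frame with columns \code{source}, \code{termId},
#'   \code{termName}, \code{k}, \code{K}, \code{n}, \code{N},
#'   \code{pValue}, \code{fdr}, \code{significant}, sorted by \code{fdr}
#'   then \code{pValue}; the report lists \code{nQueryOutsideBackground}.
#' @export
enrichGeneSets <- function(query, collection, background,
                           minSize = 3, maxSize = 2000,
                           fdrThreshold = 0.05,
                           correctionScope = c("source", "global")) {
  correctionScope <- match.arg(correctionScope)
  background <- unique(toupper(background))
  query <- unique(toupper(query))
  outside <- setdiff(query, background)
  query <- intersect(query, background)
  if (!length(query))
    stop("query empty after background intersection", call. = FALSE)
  N <- length(background)
  n <- length(query)
  rows <- lapply(seq_along(collection@ids), function(i) {
    pg <- intersect(collection@genes[[i]], background)
    K <- length(pg)
    if (K < minSize || K > maxSize) return(NULL)
    k <- sum(query %in% pg)
    data.frame(source = collection@sources[i], termId = collection@ids[i],
               termName = collection@termNames[i], k = k, K = K, n = n,
               N = N, pValue = hypergeomPvalue(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(source = character(0), termId = character(0),
                      termName = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), pValue = numeric(0),
                      fdr = numeric(0), significant = logical(0))
    return(.set_report(out, list(nQueryOutsideBackground = length(outside))))
  }
  out <- do.call(rbind, rows)
  out$fdr <- if (correctionScope == "source") {
    fdr <- numeric(nrow(out))
    for (s in unique(out$source)) {
      idx <- out$source == s
      fdr[idx] <- bhAdjust(out$pValue[idx])
    }
    fdr
  } else bhAdjust(out$pValue)
  out$significant <- out$fdr < fdrThreshold
  out <- out[order(out$fdr, out$pValue, out$termId), , drop = FALSE]
  rownames(out) <- NULL
  .set_report(out, list(nQueryOutsideBackground = length(outside)))
}

#' Export enrichment results as TSV
#'
#' Mirrors the tabular layout used for reporting enriched terms
#' (\code{source}, \code{term_name}, \code{term_id},
#' \code{adjusted_p_value}) plus the underlying counts and raw p-value.
#'
#' @param results data.frame from [enrichGeneSets()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEnrichment <- function(results, path) {
  .write_tsv(data.frame(
    source = results$source, term_name = results$termName,
    term_id = results$termId, adjusted_p_value = results$fdr,
    p_value = results$pValue, k = results$k, K = results$K,
    n = results$n, N = results$N, significant = results$significant,
    stringsAsFactors = FALSE), path)
}
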