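# Gene-disease association ingest: read association tables (DisGeNET
# dialect), restrict them to a selected disease-term list, and build the
# per-disease gene sets the similarity network is computed from.

.gda_required <- c("geneSymbol", "diseaseId")
.gda_canonical <- c("geneId", "geneSymbol", "diseaseId", "diseaseName", "score")

#' Read a gene-disease association table
#'
#' Reads a tab-separated gene-disease association table in the DisGeNET
#' dialect (canonical columns \code{geneId}, \code{geneSymbol},
#' \code{diseaseId}, \code{diseaseName}, \code{score}). Foreign headers can
#' be renamed via \code{columnMap}. Gene symbols are uppercased; rows with
#' an empty gene symbol or disease id are dropped and counted in the load
#' report. Gzip-compressed input is detected by the \code{.gz} extension.
#'
#' @param path path to a TSV (or TSV.gz) file with a header row.
#' @param columnMap optional named character vector mapping headers found in
#'   the file to the canonical names, e.g.
#'   \code{c(gene = "geneSymbol", cui = "diseaseId")}.
#' @return a data.frame with the canonical columns (one row per kept
#'   association record); the attached report (see [loadReport()]) carries
#'   \code{nInput} and \code{nDropped}.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("geneId\tgeneSymbol\tdiseaseId\tdiseaseName\tscore",
#'              "1\tShank3\tD1\tDisease one\t0.7"), tsv)
#' readGdaTable(tsv)
#' @export
readGdaTable <- function(path, columnMap = NULL) {
  df <- .read_tsv(path)
  df <- .apply_column_map(df, columnMap)
  missing <- setdiff(.gda_required, names(df))
  if (length(missing))
    stop("missing required column(s) after mapping: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"diseaseName" %in% names(df)) df$diseaseName <- df$diseaseId
  if (!"geneId" %in% names(df)) df$geneId <- NA_character_
  if (!"score" %in% names(df)) df$score <- NA_character_
  nInput <- nrow(df)
  out <- data.frame(
    geneId = suppressWarnings(as.integer(df$geneId)),
    geneSymbol = toupper(trimws(df$geneSymbol)),
    diseaseId = trimws(df$diseaseId),
    diseaseName = trimws(df$diseaseName),
    score = .parse_numeric(df$score, "score"),
    stringsAsFactors = FALSE)
  bad_score <- !is.na(out$score) & (out$score < 0 | out$score > 1)
  if (any(bad_score))
    stop("association score outside [0, 1]", call. = FALSE)
  keep <- nzchar(out$geneSymbol) & nzchar(out$diseaseId)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  .set_report(out, list(nInput = nInput, nDropped = sum(!keep)))
}

#' Bundled brain disease-term list
#'
#' Returns the static resource table of the selected brain disease terms:
#' an autism-spectrum-disorder term, co-occurring psychiatric disorder
#' terms, and epilepsy, with their ICD-10/ICD-10-CM codes and DSM-5 disease
#' category. Disease identifiers are package-local placeholders (licensed
#' vocabularies ship no identifiers here); \code{mergeGroup} marks
#' synonymous terms that are kept as separate network nodes but may be
#' merged for display.
#'
#' @return data.frame with columns \code{diseaseId}, \code{diseaseName},
#'   \code{icdCodes}, \code{dsm5Category}, \code{mergeGroup}.
#' @export
brainDiseaseTerms <- function() {
  path <- system.file("extdata", "brain_disease_terms.tsv", package = "disnet",
                      mustWork = TRUE)
  df <- .read_tsv(path)
  df$mergeGroup[df$mergeGroup == ""] <- NA_character_
  df
}

#' Restrict association records to a disease-term list
#'
#' Keeps only records whose \code{diseaseId} appears in the supplied term
#' list. Terms with no matching record are flagged in the report.
#'
#' @param records data.frame of association records ([readGdaTable()]).
#' @param terms either a character vector of disease ids or a data.frame
#'   with a \code{diseaseId} column (e.g. [brainDiseaseTerms()]).
#' @return the filtered records; the report lists \code{unmatchedTerms}.
#' @export
selectDiseaseTerms <- function(records, terms) {
  ids <- if (is.data.frame(terms)) terms$diseaseId else terms
  ids <- unique(as.character(ids))
  if (!length(ids)) stop("empty disease-term list", call. = FALSE)
  keep <- records$diseaseId %in% ids
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  .set_report(out, list(
    nInput = nrow(records), nKept = nrow(out),
    unmatchedTerms = setdiff(ids, unique(records$diseaseId))))
}

#' Build per-disease gene sets from association records
#'
#' Materialises the gene set \eqn{G_d} of each disease: the distinct
#' uppercased gene symbols of its records with association score at least
#' \code{minScore}. With the default \code{minScore = 0} records with a
#' missing score are always kept; with a positive cutoff they are dropped.
#'
#' @param records term-selected association records.
#' @param terms optional term table (data.frame with \code{diseaseId},
#'   \code{diseaseName}, and optionally \code{icdCodes},
#'   \code{dsm5Category}, \code{mergeGroup}). When supplied, every listed
#'   term gets an entry (possibly an empty set); otherwise terms are taken
#'   from the records.
#' @param minScore association-score cutoff in \[0, 1\]; default 0 (no
#'   score filtering).
#' @return a [DiseaseGeneMap-class] object.
#' @export
buildDiseaseGeneMap <- function(records, terms = NULL, minScore = 0) {
  stopifnot(is.numeric(minScore), length(minScore) == 1, minScore >= 0,
            minScore <= 1)
  if (minScore > 0)
    records <- records[!is.na(records$score) & records$score >= minScore, ,
                       drop = FALSE]
  if (is.null(terms)) {
    ids <- sort(unique(records$diseaseId))
    nm <- records$diseaseName[match(ids, records$diseaseId)]
    terms <- data.frame(diseaseId = ids, diseaseName = nm,
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(terms), "diseaseId" %in% names(terms))
    terms <- terms[order(terms$diseaseId), , drop = FALSE]
  }
  for (col in c("diseaseName", "icdCodes", "dsm5Category", "mergeGroup"))
    if (!col %in% names(terms)) terms[[col]] <- NA_character_
  rownames(terms) <- NULL
  sets <- lapply(terms$diseaseId, function(d)
    sort(unique(records$geneSymbol[records$diseaseId == d])))
  names(sets) <- terms$diseaseId
  new("DiseaseGeneMap", geneSets = sets,
      termIndex = terms[, c("diseaseId", "diseaseName", "icdCodes",
                            "dsm5Category", "mergeGroup")])
}

#' Write / read a disease gene map as TSV
#'
#' Long-format serialization with columns \code{diseaseId},
#' \code{diseaseName}, \code{geneSymbol}; diseases with empty gene sets are
#' written with an empty \code{geneSymbol} so round trips are lossless at
#' the set level.
#'
#' @param map a [DiseaseGeneMap-class].
#' @param path output (input) TSV path.
#' @return \code{writeDiseaseGeneMap} returns the path invisibly;
#'   \code{readDiseaseGeneMap} returns a [DiseaseGeneMap-class].
#' @export
writeDiseaseGeneMap <- function(map, path) {
  sets <- geneSets(map)
  ti <- diseaseTerms(map)
  rows <- lapply(names(sets), function(d) {
    g <- sets[[d]]
    data.frame(diseaseId = d,
               diseaseName = ti$diseaseName[match(d, ti$diseaseId)],
               geneSymbol = if (length(g)) g else "",
               stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
}

#' @rdname writeDiseaseGeneMap
#' @export
readDiseaseGeneMap <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("diseaseId", "geneSymbol") %in% names(df)))
  if (!"diseaseName" %in% names(df)) df$diseaseName <- df$diseaseId
  recs <- df[nzchar(df$geneSymbol), , drop = FALSE]
  recs$geneSymbol <- toupper(recs$geneSymbol)
  recs$score <- NA_real_
  ids <- unique(df$diseaseId)
  terms <- data.frame(diseaseId = ids,
                      diseaseName = df$diseaseName[match(ids, df$diseaseId)],
                      stringsAsFactors = FALSE)
  buildDiseaseGeneMap(recs, terms = terms)
}
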