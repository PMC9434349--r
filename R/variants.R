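# Rare de novo loss-of-function variant handling: TSV ingestion,
# quality/rarity/parental filtering, consequence-class normalisation,
# mapping onto community gene sets, recurrent-gene ranking, and gene-score
# annotation.

.variant_required <- c("sampleId", "geneSymbol", "consequence")
.lof_classes <- c("stop gain", "stop loss", "frameshift deletion",
                  "frameshift insertion")
.consequence_levels <- c(.lof_classes, "other")
.valid_gene_scores <- c("1", "1S", "2", "2S", "S")

#' Read a de novo variant table
#'
#' Reads a tab-separated variant table with canonical columns
#' \code{sampleId}, \code{geneSymbol}, \code{consequence} (VEP vocabulary),
#' \code{maf}, \code{genotypeQuality}, \code{parentRefFraction},
#' \code{parentAltFraction}, \code{deNovo}, and optionally \code{ref},
#' \code{alt} (used to split frameshifts into deletions/insertions).
#' Foreign headers (e.g. spreadsheet exports of annotated de novo calls)
#' are renamed via \code{columnMap}. Gene symbols are uppercased; blank
#' optional fields are kept as missing (NA), never coerced to zero. A
#' missing \code{deNovo} column defaults to TRUE (tables of pre-called de
#' novo variants), noted in the report.
#'
#' @param path path to the TSV (or TSV.gz) file.
#' @param columnMap optional named character vector renaming foreign
#'   headers to canonical names.
#' @return data.frame of variant records; report notes
#'   \code{deNovoAssumed} when the column was absent.
#' @export
readVariantTable <- function(path, columnMap = NULL) {
  df <- .read_tsv(path)
  df <- .apply_column_map(df, columnMap)
  missing <- setdiff(.variant_required, names(df))
  if (length(missing))
    stop("missing required column(s) after mapping: ",
         paste(missing, collapse = ", "), call. = FALSE)
  deNovoAssumed <- !"deNovo" %in% names(df)
  out <- data.frame(
    sampleId = trimws(df$sampleId),
    geneSymbol = toupper(trimws(df$geneSymbol)),
    consequence = trimws(df$consequence),
    maf = if ("maf" %in% names(df)) .parse_numeric(df$maf, "maf") else NA_real_,
    genotypeQuality = if ("genotypeQuality" %in% names(df))
      .parse_numeric(df$genotypeQuality, "genotypeQuality") else NA_real_,
    parentRefFraction = if ("parentRefFraction" %in% names(df))
      .parse_numeric(df$parentRefFraction, "parentRefFraction") else NA_real_,
    parentAltFraction = if ("parentAltFraction" %in% names(df))
      .parse_numeric(df$parentAltFraction, "parentAltFraction") else NA_real_,
    deNovo = if (deNovoAssumed) TRUE else .parse_logical(df$deNovo, "deNovo"),
    ref = if ("ref" %in% names(df)) trimws(df$ref) else NA_character_,
    alt = if ("alt" %in% names(df)) trimws(df$alt) else NA_character_,
    stringsAsFactors = FALSE)
  for (col in c("maf", "parentRefFraction", "parentAltFraction")) {
    bad <- !is.na(out[[col]]) & (out[[col]] < 0 | out[[col]] > 1)
    if (any(bad)) stop(col, " outside [0, 1]", call. = FALSE)
  }
  .set_report(out, list(nInput = nrow(out), deNovoAssumed = deNovoAssumed))
}

#' Normalise VEP consequence strings to reporting classes
#'
#' Maps VEP consequence terms onto the classes \code{"stop gain"},
#' \code{"stop loss"}, \code{"frameshift deletion"},
#' \code{"frameshift insertion"} and \code{"other"}.
#' \code{frameshift_variant} is split by ref/alt allele lengths when
#' alleles are available; without allele information it is classed
#' \code{"frameshift deletion"} (the commoner frameshift class) and
#' flagged via the \code{ambiguousFrameshift} attribute. The VEP-to-class
#' map is extensible through \code{classMap}.
#'
#' @param consequence character vector of VEP consequence strings.
#' @param ref,alt optional allele vectors used to split frameshifts.
#' @param classMap named character vector from VEP term to class; defaults
#'   map \code{stop_gained}, \code{stop_lost} and (via alleles)
#'   \code{frameshift_variant}.
#' @return character vector of classes, same length.
#' @export
normalizeConsequence <- function(consequence, ref = NULL, alt = NULL,
                                 classMap = c(stop_gained = "stop gain",
                                              stop_lost = "stop loss")) {
  cons <- tolower(trimws(consequence))
  out <- rep("other", length(cons))
  hit <- cons %in% names(classMap)
  out[hit] <- unname(classMap[cons[hit]])
  fs <- cons == "frameshift_variant"
  ambiguous <- logical(length(cons))
  if (any(fs)) {
    if (is.null(ref)) ref <- rep(NA_character_, length(cons))
    if (is.null(alt)) alt <- rep(NA_character_, length(cons))
    del <- fs & !is.na(ref) & !is.na(alt) & nchar(ref) > nchar(alt)
    ins <- fs & !is.na(ref) & !is.na(alt) & nchar(ref) < nchar(alt)
    rest <- fs & !del & !ins
    out[del] <- "frameshift deletion"
    out[ins] <- "frameshift insertion"
    out[rest] <- "frameshift deletion"
    ambiguous[rest] <- TRUE
  }
  structure(out, ambiguousFrameshift = ambiguous)
}

#' Filter rare de novo loss-of-function variants
#'
#' Applies the quality, rarity and parental-support filters for rare de
#' novo LoF single-nucleotide variants: keeps records that are flagged de
#' novo, whose normalised consequence class is one of \code{lofClasses},
#' with genotype quality at least \code{gqMin} (99), minor allele
#' frequency below \code{mafMax} (1\%), parental reference-call fraction
#' above \code{parentRefMin} (95\%) and parental variant-call fraction
#' below \code{parentAltMax} (1\%). Quality and parental criteria are
#' applied only when the fields are present (upstream datasets are often
#' pre-filtered); a missing MAF passes the rarity filter but is counted in
#' the report.
#'
#' @param records data.frame from [readVariantTable()].
#' @param gqMin genotype-quality threshold; default 99.
#' @param mafMax MAF threshold (exclusive); default 0.01.
#' @param parentRefMin parental reference-call fraction threshold
#'   (exclusive); default 0.95.
#' @param parentAltMax parental variant-call fraction threshold
#'   (exclusive); default 0.01.
#' @param lofClasses consequence classes counted as LoF; default stop
#'   gain/stop loss/frameshift deletion/frameshift insertion.
#' @return the kept records with an added \code{consequenceClass} column;
#'   the report counts removals per criterion
#'   (\code{removedNotDeNovo}, \code{removedNotLof}, \code{removedLowGq},
#'   \code{removedCommon}, \code{removedParentalSupport}; a record may
#'   fail several) and \code{nMissingMafPassed}.
#' @export
filterDenovoLof <- function(records, gqMin = 99, mafMax = 0.01,
                            parentRefMin = 0.95, parentAltMax = 0.01,
                            lofClasses = .lof_classes) {
  if (!length(lofClasses)) stop("empty lofClasses", call. = FALSE)
  stopifnot(gqMin >= 0, mafMax > 0, mafMax <= 1,
            parentRefMin >= 0, parentRefMin <= 1,
            parentAltMax >= 0, parentAltMax <= 1)
  cls <- normalizeConsequence(records$consequence, records$ref, records$alt)
  records$consequenceClass <- as.character(cls)
  passDeNovo <- !is.na(records$deNovo) & records$deNovo
  passLof <- records$consequenceClass %in% lofClasses
  passGq <- is.na(records$genotypeQuality) | records$genotypeQuality >= gqMin
  passMaf <- is.na(records$maf) | records$maf < mafMax
  passParent <- (is.na(records$parentRefFraction) |
                   records$parentRefFraction > parentRefMin) &
                (is.na(records$parentAltFraction) |
                   records$parentAltFraction < parentAltMax)
  keep <- passDeNovo & passLof & passGq & passMaf & passParent
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  .set_report(out, list(
    nInput = nrow(records), nKept = nrow(out),
    removedNotDeNovo = sum(!passDeNovo),
    removedNotLof = sum(!passLof),
    removedLowGq = sum(!passGq),
    removedCommon = sum(!passMaf),
    removedParentalSupport = sum(!passParent),
    nMissingMafPassed = sum(is.na(out$maf)),
    nAmbiguousFrameshift = sum(attr(cls, "ambiguousFrameshift")[keep])))
}

#' Consequence-class proportions
#'
#' Percentage of variant records per normalised consequence class
#' (\code{stop gain}, \code{stop loss}, \code{frameshift deletion},
#' \code{frameshift insertion}, \code{other}).
#'
#' @param records non-empty filtered variant records (with a
#'   \code{consequenceClass} column, else classes are normalised on the
#'   fly).
#' @return named numeric of percentages over all five classes (summing to
#'   100).
#' @export
consequenceProportions <- function(records) {
  if (!nrow(records)) stop("no variant records", call. = FALSE)
  cls <- if ("consequenceClass" %in% names(records)) records$consequenceClass
         else as.character(normalizeConsequence(records$consequence,
                                                records$ref, records$alt))
  tab <- table(factor(cls, levels = .consequence_levels))
  pct <- 100 * as.numeric(tab) / nrow(records)
  names(pct) <- .consequence_levels
  pct
}

#' Map filtered variants onto community gene sets
#'
#' Counts, for each community, the filtered variants whose gene belongs to
#' that community's gene-set union. Counting is overlapping: a gene may be
#' in several communities' unions, so a variant can contribute to several
#' communities and proportions need not sum to 100. The denominator is all
#' filtered variants, including those mapping to no community
#' (\code{unassigned}). Variant genes present in every community's union
#' are reported separately.
#'
#' @param records filtered variant records ([filterDenovoLof()]).
#' @param sets a [CommunityGeneSets-class].
#' @return list with \code{communitySummary} (data.frame: community,
#'   variantCount, proportion), \code{unassignedCount},
#'   \code{consequenceBreakdown} (named percentages) and
#'   \code{sharedAllCommunitiesGenes}.
#' @export
mapVariantsToCommunities <- function(records, sets) {
  u <- unionGenes(sets)
  total <- nrow(records)
  counts <- vapply(u, function(g) sum(records$geneSymbol %in% g), numeric(1))
  inAny <- rep(FALSE, total)
  for (g in u) inAny <- inAny | records$geneSymbol %in% g
  variantGenes <- unique(records$geneSymbol)
  inAll <- variantGenes
  for (g in u) inAll <- inAll[inAll %in% g]
  list(
    communitySummary = data.frame(
      community = names(u),
      variantCount = as.integer(counts),
      proportion = if (total) 100 * counts / total else rep(NaN, length(u)),
      stringsAsFactors = FALSE, row.names = NULL),
    unassignedCount = sum(!inAny),
    consequenceBreakdown = if (total) consequenceProportions(records) else NULL,
    sharedAllCommunitiesGenes = sort(inAll))
}

#' Rank genes by recurrent variant count
#'
#' Genes hit by at least \code{minCount} filtered variants, in descending
#' count order with lexicographic tie-breaking.
#'
#' @param records filtered variant records.
#' @param minCount minimum variant count; default 2 (recurrently hit
#'   genes).
#' @return data.frame with columns \code{gene} and \code{count}.
#' @export
rankGenesByVariantCount <- function(records, minCount = 2) {
  tab <- table(records$geneSymbol)
  tab <- tab[tab >= minCount]
  genes <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, genes)
  data.frame(gene = genes[ord], count = cnt[ord], stringsAsFactors = FALSE)
}

#' Annotate ranked genes with evidence-score labels
#'
#' Joins external gene-score labels (SFARI-style scoring: \code{1},
#' \code{1S}, \code{2}, \code{2S}, \code{S}) onto a ranked gene table.
#' Genes without a label are marked \code{"absent"}. Category-3 labels are
#' rejected (weak candidates are excluded from this scoring by
#' convention), as is any unknown label.
#'
#' @param ranked data.frame from [rankGenesByVariantCount()].
#' @param scoreMap named character vector: gene symbol to score label.
#' @return the ranked table with an added \code{score} column.
#' @export
annotateGeneScores <- function(ranked, scoreMap = character(0)) {
  if (length(scoreMap)) {
    bad <- setdiff(unique(scoreMap), .valid_gene_scores)
    if (length(bad))
      stop("invalid gene-score label(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(.valid_gene_scores, collapse = ", "),
           "; category 3 is excluded)", call. = FALSE)
    names(scoreMap) <- toupper(names(scoreMap))
  }
  score <- unname(scoreMap[ranked$gene])
  score[is.na(score)] <- "absent"
  ranked$score <- score
  ranked
}
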