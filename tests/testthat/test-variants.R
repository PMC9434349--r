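# Variant ingestion, LoF filtering, consequence classes, community
# mapping, gene ranking and score annotation.

test_that("variant tables read with missing fields kept as NA, not zero", {
  df <- data.frame(sampleId = c("S1", "S2", "S3"),
                   geneSymbol = c("Shank3", "chd2", "ASH1L"),
                   consequence = "stop_gained",
                   maf = c("0.001", "", "0.004"),
                   genotypeQuality = c("99", "99", ""),
                   deNovo = "TRUE")
  recs <- readVariantTable(write_fixture(df))
  expect_equal(nrow(recs), 3)
  expect_equal(recs$geneSymbol, c("SHANK3", "CHD2", "ASH1L"))
  expect_true(is.na(recs$maf[2]))
  expect_false(any(recs$maf == 0, na.rm = TRUE))
  expect_true(is.na(recs$genotypeQuality[3]))
})

test_that("variant column_map reproduces the canonical read", {
  df <- data.frame(sampleId = "S1", geneSymbol = "A", consequence = "stop_lost",
                   maf = 0.001, genotypeQuality = 99, deNovo = TRUE)
  canonical <- readVariantTable(write_fixture(df))
  foreign <- df
  names(foreign) <- c("sample", "gene", "effect", "freq", "gq", "is_denovo")
  remapped <- readVariantTable(write_fixture(foreign),
    columnMap = c(sample = "sampleId", gene = "geneSymbol",
                  effect = "consequence", freq = "maf",
                  gq = "genotypeQuality", is_denovo = "deNovo"))
  expect_identical(remapped, canonical, ignore_attr = TRUE)
  expect_error(readVariantTable(write_fixture(data.frame(gene = "A"))),
               "missing required")
})

test_that("consequence classes split frameshifts by allele lengths", {
  cls <- normalizeConsequence(
    c("stop_gained", "stop_lost", "frameshift_variant", "frameshift_variant",
      "missense_variant", "frameshift_variant"),
    ref = c("C", "T", "AT", "A", "G", NA),
    alt = c("T", "C", "A", "AT", "A", NA))
  expect_equal(as.character(cls),
               c("stop gain", "stop loss", "frameshift deletion",
                 "frameshift insertion", "other", "frameshift deletion"))
  expect_equal(attr(cls, "ambiguousFrameshift"),
               c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("the four-row worked fixture keeps exactly the clean LoF record", {
  kept <- filterDenovoLof(four_row_variants())
  expect_equal(nrow(kept), 1)
  expect_equal(kept$geneSymbol, "SHANK3")
  rep <- loadReport(kept)
  expect_equal(rep$removedNotLof, 1)     # the missense record
  expect_equal(rep$removedCommon, 1)     # MAF 2%
  expect_equal(rep$removedLowGq, 1)      # GQ 50
  expect_error(filterDenovoLof(four_row_variants(), lofClasses = character(0)),
               "empty lofClasses")
})

test_that("empty input filters to an empty table with a zeroed report", {
  empty <- four_row_variants()[0, ]
  kept <- filterDenovoLof(empty)
  expect_equal(nrow(kept), 0)
  expect_equal(loadReport(kept)$removedNotDeNovo, 0)
})

test_that("filter matches a row-wise predicate oracle and ignores row order", {
  df <- random_variants(1000, seed = 61)
  kept <- filterDenovoLof(df)
  oracle <- oracle_variant_keep(df)
  expect_equal(nrow(kept), sum(oracle))
  expect_setequal(kept$sampleId, df$sampleId[oracle])
  # order independence
  withr::with_seed(62, perm <- sample(nrow(df)))
  kept2 <- filterDenovoLof(df[perm, ])
  expect_setequal(kept2$sampleId, kept$sampleId)
})

test_that("missing MAF passes the rarity filter and is flagged", {
  df <- four_row_variants()[1, ]
  df$maf <- NA_real_
  kept <- filterDenovoLof(df)
  expect_equal(nrow(kept), 1)
  expect_equal(loadReport(kept)$nMissingMafPassed, 1)
})

test_that("consequence proportions cover the worked case and sum to 100", {
  df <- data.frame(sampleId = sprintf("S%d", 1:4),
                   geneSymbol = "G1",
                   consequence = c("stop_gained", "stop_gained",
                                   "frameshift_variant", "frameshift_variant"),
                   ref = c("C", "C", "AT", "A"), alt = c("T", "T", "A", "AT"),
                   deNovo = TRUE, maf = NA_real_, genotypeQuality = NA_real_,
                   parentRefFraction = NA_real_, parentAltFraction = NA_real_,
                   stringsAsFactors = FALSE)
  pct <- consequenceProportions(df)
  expect_equal(unname(pct["stop gain"]), 50)
  expect_equal(unname(pct["frameshift deletion"]), 25)
  expect_equal(unname(pct["frameshift insertion"]), 25)
  expect_equal(sum(pct), 100)
  expect_equal(unname(consequenceProportions(df[1:2, ])["stop gain"]), 100)
  expect_error(consequenceProportions(df[0, ]), "no variant records")
  # random labels match a counting oracle and round-trip the sum invariant
  rand <- random_variants(300, seed = 63)
  pr <- consequenceProportions(rand)
  expect_equal(sum(round(pr, 2)), 100, tolerance = 0.01)
  expect_equal(unname(pr["other"]),
               100 * mean(rand$consequence %in%
                            c("missense_variant", "synonymous_variant")))
})

test_that("community mapping counts overlapping genes in every community", {
  sets <- communityGeneSets(list(C1 = c("G1", "G2"), C2 = c("G2", "G3")))
  df <- data.frame(sampleId = sprintf("S%d", 1:4),
                   geneSymbol = c("G1", "G2", "G3", "G4"),
                   consequence = "stop_gained", deNovo = TRUE,
                   maf = NA_real_, genotypeQuality = NA_real_,
                   parentRefFraction = NA_real_, parentAltFraction = NA_real_,
                   ref = "C", alt = "T", stringsAsFactors = FALSE)
  summ <- mapVariantsToCommunities(df, sets)
  cs <- summ$communitySummary
  expect_equal(cs$proportion[cs$community == "C1"], 50)
  expect_equal(cs$proportion[cs$community == "C2"], 50)
  expect_equal(summ$unassignedCount, 1)
  expect_gt(sum(cs$proportion), 99.9)  # overlapping counting: sums can pass 100
  expect_equal(summ$sharedAllCommunitiesGenes, "G2")
  # no overlap between unions: proportions sum to at most 100
  sets2 <- communityGeneSets(list(C1 = "G1", C2 = "G3"))
  summ2 <- mapVariantsToCommunities(df, sets2)
  expect_lte(sum(summ2$communitySummary$proportion), 100)
})

test_that("per-community variant shares track planted generator weights", {
  cfg <- syntheticConfig(seed = 71, nVariants = 500, hotGenes = integer(0))
  sim <- simulateGdaTable(cfg)
  vt <- simulateVariantTable(cfg, sim$truth)
  map <- buildDiseaseGeneMap(sim$records)
  part <- stats::setNames(as.integer(sim$truth$plantedPartition) - 1L,
                          names(sim$truth$plantedPartition))
  fakePart <- new("CommunityPartition", membership = part, modularity = 0,
                  resolution = 1, seed = NA_integer_, nCommunities = 3L,
                  trace = 0)
  sets <- communityGeneSets(map, fakePart)
  filtered <- filterDenovoLof(vt)
  summ <- mapVariantsToCommunities(filtered, sets)
  # expectation oracle from truth: a variant drawn for community k lands in
  # community c's union with probability p_kc = share of k's genes also in
  # c's union; equal community weights
  commGenes <- lapply(1:3, function(c) {
    members <- names(sim$truth$plantedPartition)[sim$truth$plantedPartition == c]
    unique(unlist(sim$truth$diseaseGenes[members]))
  })
  for (c in 1:3) {
    expected <- 100 * mean(vapply(1:3, function(k)
      mean(commGenes[[k]] %in% commGenes[[c]]), numeric(1)))
    observed <- summ$communitySummary$proportion[c]
    expect_lt(abs(observed - expected), 3)
  }
})

test_that("gene ranking orders by count with lexicographic ties", {
  df <- data.frame(geneSymbol = c(rep("G1", 3), rep("G2", 2), "G3"),
                   stringsAsFactors = FALSE)
  ranked <- rankGenesByVariantCount(df)
  expect_equal(ranked$gene, c("G1", "G2"))
  expect_equal(ranked$count, c(3L, 2L))
  expect_equal(rankGenesByVariantCount(df, minCount = 1)$gene,
               c("G1", "G2", "G3"))
  tie <- data.frame(geneSymbol = c("B", "B", "A", "A"))
  expect_equal(rankGenesByVariantCount(tie)$gene, c("A", "B"))
  rand <- random_variants(400, seed = 64)
  ranked2 <- rankGenesByVariantCount(rand, minCount = 3)
  oracle <- table(rand$geneSymbol)
  oracle <- sort(oracle[oracle >= 3], decreasing = TRUE)
  expect_setequal(ranked2$gene, names(oracle))
  expect_equal(sort(ranked2$count), sort(as.integer(oracle)))
})

test_that("a planted hot gene with five variants ranks first", {
  cfg <- syntheticConfig(seed = 72, hotGenes = c(SHANK3LIKE = 5L))
  sim <- simulateGdaTable(cfg)
  vt <- simulateVariantTable(cfg, sim$truth)
  filtered <- filterDenovoLof(vt)
  ranked <- rankGenesByVariantCount(filtered)
  expect_equal(ranked$gene[1], "SHANK3LIKE")
  expect_gte(ranked$count[1], 5)
})

test_that("gene-score annotation labels absences and rejects category 3", {
  ranked <- data.frame(gene = c("G1", "G2"), count = c(3L, 2L),
                       stringsAsFactors = FALSE)
  out <- annotateGeneScores(ranked, c(G1 = "1S"))
  expect_equal(out$score, c("1S", "absent"))
  expect_equal(annotateGeneScores(ranked)$score, c("absent", "absent"))
  expect_error(annotateGeneScores(ranked, c(G1 = "3")), "invalid gene-score")
  expect_error(annotateGeneScores(ranked, c(G1 = "3S")), "invalid gene-score")
})
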