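# GMT ingestion, hypergeometric p-values, BH adjustment, and the
# over-representation driver.

test_that("GMT files parse with uppercasing, dedup and source inference", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("GO:0001\tterm one\tshank3\tSCN2A\tshank3",
               "REAC:R-HSA-1\tterm two\tA\tB\tC"), path)
  col <- readGmt(path)
  expect_equal(pathwayIds(col), c("GO:0001", "REAC:R-HSA-1"))
  expect_equal(pathwayGenes(col)[["GO:0001"]], c("SHANK3", "SCN2A"))
  expect_equal(unname(pathwaySources(col)), c("GO", "REAC"))
  writeLines(c("GO:0001\tonly two fields"), path)
  expect_error(readGmt(path), "line 1")
})

test_that("GMT round-trips through write and read", {
  col <- new("PathwayCollection", ids = c("A:1", "B:2"),
             termNames = c("first", "second"), sources = c("A", "B"),
             genes = list(c("G1", "G2"), c("G3", "G4", "G5")))
  path <- tempfile(fileext = ".gmt")
  writeGmt(col, path)
  back <- readGmt(path)
  expect_equal(pathwayIds(back), pathwayIds(col))
  expect_equal(pathwayGenes(back), pathwayGenes(col))
})

test_that("hypergeometric worked value and edge cases", {
  expect_equal(hypergeomPvalue(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeomPvalue(10, 5, 4, 0), 1)
  expect_equal(hypergeomPvalue(20, 20, 7, 7), 1)  # K = N forces k = n
  expect_error(hypergeomPvalue(10, 5, 4, 6), "inconsistent")
  expect_error(hypergeomPvalue(10, 12, 4, 2), "inconsistent")
})

test_that("hypergeometric p-values match combinatorial enumeration (N <= 30)", {
  for (N in c(5, 12, 21, 30)) {
    for (K in seq(0, N, by = 3)) {
      for (n in seq(0, N, by = 3)) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeomPvalue(N, K, n, k), oracle_hyper(N, K, n, k),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("enrichment p-values are monotone non-increasing in the overlap", {
  for (N in c(15, 30)) {
    K <- 6; n <- 8
    p <- vapply(0:min(K, n), function(k) hypergeomPvalue(N, K, n, k),
                numeric(1))
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("BH worked examples and validation", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(0.05, 0.05, 0.05)), rep(0.05, 3))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH agrees with an independent step-up reference on random vectors", {
  withr::with_seed(51, {
    for (i in 1:200) {
      p <- stats::runif(sample(1:40, 1))
      expect_equal(bhAdjust(p), oracle_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("a fully recovered pathway is significant against decoys", {
  pw <- sprintf("P%02d", 1:10)
  decoys <- sprintf("D%02d", 1:20)
  col <- new("PathwayCollection", ids = "SET:1", termNames = "planted",
             sources = "SET", genes = list(pw))
  res <- enrichGeneSets(pw, col, background = c(pw, decoys))
  expect_equal(res$k, 10)
  expect_equal(res$K, 10)
  expect_equal(res$n, 10)
  expect_equal(res$pValue, 1 / choose(30, 10), tolerance = 1e-12)
  expect_true(res$significant)
})

test_that("queries disjoint from every pathway yield nothing significant", {
  col <- new("PathwayCollection", ids = c("S:1", "S:2"),
             termNames = c("a", "b"), sources = c("S", "S"),
             genes = list(sprintf("A%d", 1:5), sprintf("B%d", 1:5)))
  bg <- c(sprintf("A%d", 1:5), sprintf("B%d", 1:5), sprintf("Q%d", 1:10))
  res <- enrichGeneSets(sprintf("Q%d", 1:5), col, bg)
  expect_false(any(res$significant))
  expect_true(all(res$pValue == 1 | res$k == 0))
})

test_that("genes outside the background are dropped and reported", {
  col <- new("PathwayCollection", ids = "S:1", termNames = "a", sources = "S",
             genes = list(c("A1", "A2", "A3")))
  bg <- c("A1", "A2", "A3", "B1", "B2")
  res <- enrichGeneSets(c("A1", "ZZ9"), col, bg)
  expect_equal(loadReport(res)$nQueryOutsideBackground, 1)
  expect_equal(res$n, 1)
  expect_error(enrichGeneSets("ZZ9", col, bg), "query empty")
})

test_that("size bounds and per-source correction scope are honoured", {
  col <- new("PathwayCollection",
             ids = c("GO:1", "GO:2", "REAC:1", "TINY:1"),
             termNames = letters[1:4],
             sources = c("GO", "GO", "REAC", "TINY"),
             genes = list(sprintf("A%d", 1:6), sprintf("G%d", 1:8),
                          sprintf("A%d", 1:6), c("A1", "A2")))
  bg <- unique(c(sprintf("A%d", 1:6), sprintf("G%d", 1:8), sprintf("X%d", 1:20)))
  res <- enrichGeneSets(sprintf("A%d", 1:6), col, bg, minSize = 3)
  expect_false("TINY:1" %in% res$termId)  # below minSize
  # per-source: GO block corrected over 2 tests, REAC over 1
  go <- res[res$source == "GO", ]
  reac <- res[res$source == "REAC", ]
  expect_equal(reac$fdr, reac$pValue)
  expect_equal(go$fdr, oracle_bh(go$pValue), tolerance = 1e-12)
  glob <- enrichGeneSets(sprintf("A%d", 1:6), col, bg, minSize = 3,
                         correctionScope = "global")
  expect_equal(sort(glob$fdr), sort(oracle_bh(glob$pValue)), tolerance = 1e-12)
})

test_that("planted synthetic pathways enrich in their community's exclusive genes", {
  cfg <- syntheticConfig(seed = 8)
  sim <- simulateGdaTable(cfg)
  map <- buildDiseaseGeneMap(sim$records)
  part <- stats::setNames(as.integer(sim$truth$plantedPartition) - 1L,
                          names(sim$truth$plantedPartition))
  fakePart <- new("CommunityPartition", membership = part, modularity = 0,
                  resolution = 1, seed = NA_integer_,
                  nCommunities = 3L, trace = 0)
  sets <- communityGeneSets(map, fakePart)
  pw <- simulatePathways(cfg, sim$truth)
  bg <- unique(sim$records$geneSymbol)
  planted1 <- pw$plantedTerms$termId[pw$plantedTerms$community == 1]
  res <- enrichGeneSets(exclusiveGenes(sets)[["0"]], pw$collection, bg)
  expect_equal(res$termId[1], planted1)
  expect_lt(res$fdr[1], 0.05)
})

test_that("enrichment export mirrors the reporting columns", {
  col <- new("PathwayCollection", ids = "S:1", termNames = "a", sources = "S",
             genes = list(sprintf("A%d", 1:5)))
  res <- enrichGeneSets(sprintf("A%d", 1:4), col,
                        c(sprintf("A%d", 1:5), sprintf("B%d", 1:20)))
  path <- tempfile(fileext = ".tsv")
  writeEnrichment(res, path)
  tab <- utils::read.delim(path)
  expect_equal(names(tab)[1:4],
               c("source", "term_name", "term_id", "adjusted_p_value"))
  expect_equal(tab$adjusted_p_value, res$fdr)
})
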