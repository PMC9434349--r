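# Weighted modularity, the Leiden implementation, and the exhaustive
# oracle.

test_that("modularity closed forms hold", {
  net1 <- single_edge_network()
  nodes <- networkNodes(net1)
  one <- stats::setNames(c(0L, 0L), nodes)
  singletons <- stats::setNames(c(0L, 1L), nodes)
  expect_equal(networkModularity(net1, one), 0, tolerance = 1e-14)
  expect_equal(networkModularity(net1, singletons), -0.5)

  net2 <- two_triangles_network()
  split <- stats::setNames(c(0L, 0L, 0L, 1L, 1L, 1L), networkNodes(net2))
  expect_equal(networkModularity(net2, split), 0.5)
  expect_error(networkModularity(net1, one, resolution = 0), "resolution > 0")
})

test_that("any all-in-one partition has zero modularity at unit resolution", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      net <- random_network(sample(3:12, 1), 0.5, seed = rep * 7 + 1)
      if (is.null(net)) next
      m <- stats::setNames(rep(0L, length(networkNodes(net))),
                           networkNodes(net))
      expect_lt(abs(networkModularity(net, m)), 1e-12)
    }
  })
})

test_that("modularity agrees with igraph's weighted implementation", {
  for (seed in c(5, 17, 29)) {
    net <- random_network(8, 0.6, seed = seed)
    if (is.null(net)) next
    e <- networkEdges(net)
    g <- igraph::graph_from_data_frame(e[, 1:2], directed = FALSE,
      vertices = data.frame(name = networkNodes(net)))
    withr::with_seed(seed, {
      m <- stats::setNames(sample(0:2, length(networkNodes(net)), TRUE),
                           networkNodes(net))
    })
    for (gamma in c(0.5, 1, 2)) {
      expect_equal(
        networkModularity(net, m, resolution = gamma),
        igraph::modularity(g, m[igraph::V(g)$name] + 1, weights = e$jaccard,
                           resolution = gamma),
        tolerance = 1e-12)
    }
  }
})

test_that("exhaustive search recovers the known optima of tiny graphs", {
  bf1 <- bruteForceBestPartition(single_edge_network())
  expect_equal(nCommunities(bf1), 1)
  expect_equal(modularityScore(bf1), 0)

  bf2 <- bruteForceBestPartition(two_triangles_network())
  expect_equal(nCommunities(bf2), 2)
  expect_equal(modularityScore(bf2), 0.5)
  m <- communityLabels(bf2)
  expect_equal(unname(m[1:3]), rep(m[[1]], 3))
  expect_equal(unname(m[4:6]), rep(m[[4]], 3))

  # 4-cycle: enumeration over the 15 partitions of 4 nodes
  cyc <- unit_network(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  bfc <- bruteForceBestPartition(cyc)
  ld <- leidenCommunities(cyc, seed = 3)
  expect_equal(modularityScore(ld), modularityScore(bfc), tolerance = 1e-12)
  expect_error(bruteForceBestPartition(random_network(11, 1, 1)),
               "limited to 10 nodes")
})

test_that("leiden equals the exhaustive oracle on random small graphs", {
  tested <- 0
  for (s in 1:50) {
    net <- random_network(sample(3:8, 1), 0.5, seed = 1000 + s)
    if (is.null(net)) next
    tested <- tested + 1
    bf <- bruteForceBestPartition(net)
    ld <- leidenCommunities(net, seed = s)
    expect_equal(modularityScore(ld), modularityScore(bf), tolerance = 1e-12)
    expect_true(all(diff(ld@trace) >= -1e-12))
  }
  expect_gte(tested, 40)
})

test_that("leiden never scores below the trivial partitions", {
  for (s in 1:10) {
    net <- random_network(sample(4:10, 1), 0.4, seed = 500 + s)
    if (is.null(net)) next
    nodes <- networkNodes(net)
    ld <- leidenCommunities(net, seed = s)
    q_one <- networkModularity(net, stats::setNames(rep(0L, length(nodes)),
                                                    nodes))
    q_singletons <- networkModularity(
      net, stats::setNames(seq_along(nodes) - 1L, nodes))
    expect_gte(modularityScore(ld), q_one - 1e-12)
    expect_gte(modularityScore(ld), q_singletons - 1e-12)
  }
})

test_that("leiden communities are internally connected", {
  for (s in 1:10) {
    net <- random_network(10, 0.3, seed = 700 + s)
    if (is.null(net)) next
    ld <- leidenCommunities(net, seed = s)
    m <- communityLabels(ld)
    e <- networkEdges(net)
    for (c in unique(m)) {
      members <- names(m)[m == c]
      if (length(members) == 1) next
      sub <- e[e$diseaseA %in% members & e$diseaseB %in% members, ]
      g <- igraph::graph_from_data_frame(sub[, 1:2], directed = FALSE,
        vertices = data.frame(name = members))
      expect_true(igraph::is_connected(g))
    }
  }
})

test_that("leiden is deterministic for a fixed seed and label-invariant", {
  net <- random_network(9, 0.5, seed = 77)
  a <- leidenCommunities(net, seed = 42)
  b <- leidenCommunities(net, seed = 42)
  expect_identical(communityLabels(a), communityLabels(b))
  expect_identical(modularityScore(a), modularityScore(b))
  # permute node identities: same modularity after canonical re-sorting
  nodes <- networkNodes(net)
  perm <- stats::setNames(sprintf("m%02d", seq_along(nodes)), nodes)
  withr::with_seed(1, perm[] <- sample(perm))
  e <- networkEdges(net)
  e$diseaseA <- unname(perm[e$diseaseA])
  e$diseaseB <- unname(perm[e$diseaseB])
  net2 <- disnet:::.new_disease_network(unname(perm), e)
  c2 <- leidenCommunities(net2, seed = 42)
  expect_equal(modularityScore(c2), modularityScore(a), tolerance = 1e-12)
})

test_that("optimal community count is monotone in the resolution parameter", {
  for (s in c(3, 9, 21)) {
    net <- random_network(7, 0.6, seed = s)
    if (is.null(net)) next
    gammas <- c(0.25, 0.5, 1, 2, 4)
    counts <- vapply(gammas, function(g)
      nCommunities(bruteForceBestPartition(net, resolution = g)), integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("singleton partition on a single edge scores -0.5 and leiden merges it", {
  net <- single_edge_network()
  ld <- leidenCommunities(net, seed = 1)
  expect_equal(nCommunities(ld), 1)
  expect_equal(modularityScore(ld), 0)
  bf <- bruteForceBestPartition(net)
  expect_equal(modularityScore(bf), 0)
})

test_that("adjusted Rand index matches oracle and external implementation", {
  expect_equal(adjustedRand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjustedRand(c(1, 1, 1), c(1, 2, 3)) <= 1, TRUE)
  withr::with_seed(33, {
    for (i in 1:20) {
      a <- sample(1:4, 30, replace = TRUE)
      b <- sample(1:3, 30, replace = TRUE)
      expect_equal(adjustedRand(a, b), oracle_ari(a, b), tolerance = 1e-12)
      if (requireNamespace("mclust", quietly = TRUE))
        expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b),
                     tolerance = 1e-12)
    }
  })
})

test_that("partition export writes assignments plus run metadata", {
  net <- two_triangles_network()
  ld <- leidenCommunities(net, seed = 5)
  path <- tempfile(fileext = ".tsv")
  writePartition(ld, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 6)
  expect_setequal(tab$disease_id, networkNodes(net))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$nCommunities, 2)
  expect_equal(meta$seed, 5)
})
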