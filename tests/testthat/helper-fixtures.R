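# Fixture builders and independent oracles shared across the test files.
# Oracles are deliberately naive (enumeration, brute-force set algebra) and
# never call the code paths they validate.

# Build a DiseaseGeneMap from a named list of gene vectors via the public
# ingestion path.
make_map <- function(sets) {
  recs <- do.call(rbind, lapply(names(sets), function(d) {
    data.frame(geneId = NA_integer_, geneSymbol = sets[[d]], diseaseId = d,
               diseaseName = paste("disease", d), score = NA_real_,
               stringsAsFactors = FALSE)
  }))
  buildDiseaseGeneMap(recs)
}

# Two disjoint triangles with unit-ish Jaccard 1/3 edges: gene sets where
# each pair of diseases shares exactly one private gene.
triangle_pair_map <- function() {
  make_map(list(
    d1 = c("G12", "G13"), d2 = c("G12", "G23"), d3 = c("G13", "G23"),
    e1 = c("H12", "H13"), e2 = c("H12", "H23"), e3 = c("H13", "H23")))
}

# Random weighted network on n nodes, Erdos-Renyi edge presence, rational
# weights shaped like Jaccard ratios. Returns NULL when no edge was drawn.
random_network <- function(n, p = 0.5, seed = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    pairs <- pairs[keep, , drop = FALSE]
    if (!nrow(pairs)) return(NULL)
    sh <- sample(1:5, nrow(pairs), replace = TRUE)
    un <- sh + sample(1:10, nrow(pairs), replace = TRUE)
    edges <- data.frame(diseaseA = nodes[pairs[, 1]],
                        diseaseB = nodes[pairs[, 2]],
                        jaccard = sh / un, sharedGenes = sh, unionGenes = un,
                        stringsAsFactors = FALSE)
    disnet:::.new_disease_network(nodes, edges)
  })
}

# Unit-weight network from an explicit edge list (matrix of node-index
# pairs).
unit_network <- function(n, pairs) {
  nodes <- sprintf("n%02d", seq_len(n))
  edges <- data.frame(diseaseA = nodes[pairs[, 1]],
                      diseaseB = nodes[pairs[, 2]],
                      jaccard = 1, sharedGenes = 1L, unionGenes = 1L,
                      stringsAsFactors = FALSE)
  disnet:::.new_disease_network(nodes, edges)
}

single_edge_network <- function() unit_network(2, cbind(1, 2))

two_triangles_network <- function() {
  unit_network(6, rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
}

# --- independent oracles ---------------------------------------------------

oracle_jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# Hypergeometric upper tail by direct combinatorial enumeration.
oracle_hyper <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Step-up BH computed from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  sorted <- p[ord]
  running <- Inf
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    q[ord[i]] <- min(running, 1)
  }
  q
}

# Contingency-table ARI from the definition.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == e) return(1)
  (sij - e) / (mx - e)
}

# Write a data.frame as a TSV fixture in a temp file.
write_fixture <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Four-row variant fixture exercising each filter rule: one clean LoF
# record, one non-LoF, one too-common, one low-quality.
four_row_variants <- function() {
  data.frame(
    sampleId = sprintf("S%d", 1:4),
    geneSymbol = c("SHANK3", "GENEA", "GENEB", "GENEC"),
    consequence = c("stop_gained", "missense_variant", "frameshift_variant",
                    "stop_lost"),
    maf = c(0.001, 0.001, 0.02, 0.001),
    genotypeQuality = c(99, 99, 99, 50),
    parentRefFraction = c(0.99, 0.99, 0.99, 0.99),
    parentAltFraction = c(0.001, 0.001, 0.001, 0.001),
    deNovo = TRUE,
    ref = c("C", "G", "AT", "T"),
    alt = c("T", "A", "A", "C"),
    stringsAsFactors = FALSE)
}

# Random variant table mixing clean and rule-violating rows.
random_variants <- function(n, seed) {
  withr::with_seed(seed, {
    data.frame(
      sampleId = sprintf("S%04d", seq_len(n)),
      geneSymbol = sprintf("G%03d", sample(1:80, n, replace = TRUE)),
      consequence = sample(c("stop_gained", "stop_lost", "frameshift_variant",
                             "missense_variant", "synonymous_variant"),
                           n, replace = TRUE),
      maf = ifelse(stats::runif(n) < 0.1, NA,
                   stats::runif(n, 0, 0.03)),
      genotypeQuality = sample(c(99, 99, 99, 50, NA), n, replace = TRUE),
      parentRefFraction = stats::runif(n, 0.9, 1),
      parentAltFraction = stats::runif(n, 0, 0.02),
      deNovo = stats::runif(n) < 0.9,
      ref = sample(c("A", "AT", "ATT"), n, replace = TRUE),
      alt = sample(c("A", "AT"), n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

# Row-wise filter predicate computed independently of filterDenovoLof.
oracle_variant_keep <- function(df, gqMin = 99, mafMax = 0.01,
                                parentRefMin = 0.95, parentAltMax = 0.01) {
  cls <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    cons <- df$consequence[i]
    cls[i] <- if (cons == "stop_gained") "stop gain"
    else if (cons == "stop_lost") "stop loss"
    else if (cons == "frameshift_variant") {
      if (!is.na(df$ref[i]) && !is.na(df$alt[i]) &&
          nchar(df$ref[i]) < nchar(df$alt[i])) "frameshift insertion"
      else "frameshift deletion"
    } else "other"
  }
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    keep[i] <- isTRUE(df$deNovo[i]) &&
      cls[i] != "other" &&
      (is.na(df$genotypeQuality[i]) || df$genotypeQuality[i] >= gqMin) &&
      (is.na(df$maf[i]) || df$maf[i] < mafMax) &&
      (is.na(df$parentRefFraction[i]) || df$parentRefFraction[i] > parentRefMin) &&
      (is.na(df$parentAltFraction[i]) || df$parentAltFraction[i] < parentAltMax)
  }
  keep
}
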