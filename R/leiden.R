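# Weighted-modularity optimisation: modularity with a resolution
# parameter, an in-package Leiden implementation (queue-based local moving,
# deterministic greedy refinement, graph aggregation), and an
# exhaustive-partition oracle for small graphs.
#
# Internal graph representation: list(n, ea, eb, w) with 1-based node
# indices, unordered edges ea <= eb; self-loops (ea == eb) arise on
# aggregate graphs, where a self-loop of weight w contributes 2w to the
# node strength (the usual A_ii = 2w convention, under which aggregation
# preserves modularity).

.graph_from_network <- function(net) {
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  list(n = length(nodes),
       ea = match(e$diseaseA, nodes),
       eb = match(e$diseaseB, nodes),
       w = e$jaccard,
       nodes = nodes)
}

.graph_strength <- function(g) {
  s <- numeric(g$n)
  for (k in seq_along(g$w)) {
    s[g$ea[k]] <- s[g$ea[k]] + g$w[k]
    s[g$eb[k]] <- s[g$eb[k]] + g$w[k]
  }
  s
}

# Adjacency lists excluding self-loops: per node, integer neighbor vector
# and weight vector (parallel edges pre-merged by construction).
.graph_adjacency <- function(g) {
  nb <- vector("list", g$n)
  wl <- vector("list", g$n)
  for (k in seq_along(g$w)) {
    a <- g$ea[k]; b <- g$eb[k]
    if (a == b) next
    nb[[a]] <- c(nb[[a]], b); wl[[a]] <- c(wl[[a]], g$w[k])
    nb[[b]] <- c(nb[[b]], a); wl[[b]] <- c(wl[[b]], g$w[k])
  }
  list(nb = nb, w = wl)
}

# Modularity of a membership vector on the internal graph.
.q_internal <- function(g, part, gamma) {
  s <- .graph_strength(g)
  twom <- sum(s)
  if (twom <= 0) stop("edgeless network: modularity undefined", call. = FALSE)
  intra <- 2 * sum(g$w[part[g$ea] == part[g$eb]])
  Sc <- rowsum(s, part)
  intra / twom - gamma * sum((Sc / twom)^2)
}

#' Weighted modularity of a partition
#'
#' Computes \deqn{Q = \frac{1}{2m} \sum_{ij} \left[ w_{ij} - \gamma
#' \frac{s_i s_j}{2m} \right] \delta(c_i, c_j)} where \eqn{w_{ij}} are
#' Jaccard edge weights, \eqn{s_i} node strengths, \eqn{2m} the total
#' strength and \eqn{\gamma} the resolution parameter. Deterministic; an
#' edgeless network is an error.
#'
#' @param net a [DiseaseNetwork-class] with at least one edge.
#' @param membership a named integer vector of community labels covering
#'   all network nodes, or a [CommunityPartition-class].
#' @param resolution resolution parameter \eqn{\gamma > 0}; default 1.
#' @return the modularity Q (a scalar in \[-1, 1\]).
#' @examples
#' # any network with all nodes in one community has Q = 0 at gamma = 1
#' @export
networkModularity <- function(net, membership, resolution = 1) {
  stopifnot(resolution > 0)
  if (is(membership, "CommunityPartition"))
    membership <- communityLabels(membership)
  g <- .graph_from_network(net)
  if (!length(g$w)) stop("edgeless network: modularity undefined", call. = FALSE)
  if (is.null(names(membership)) ||
      !all(g$nodes %in% names(membership)))
    stop("membership must be named and cover all network nodes", call. = FALSE)
  part <- as.integer(membership[g$nodes])
  .q_internal(g, part, resolution)
}

# ---- local moving ---------------------------------------------------------

# Queue-based local moving. Candidate targets for a node are the
# communities of its neighbors, its own community, and an empty community;
# a move happens when the modularity gain exceeds `tol` (in Q units).
# Returns list(part, moved).
.local_move <- function(adj, s, twom, part, gamma, order, tol = 1e-12) {
  n <- length(s)
  m <- twom / 2
  maxlab <- max(part)
  S <- numeric(maxlab)
  for (v in seq_len(n)) S[part[v]] <- S[part[v]] + s[v]
  queue <- order
  inq <- rep(FALSE, n)
  inq[order] <- TRUE
  qi <- 1L
  moved_any <- FALSE
  while (qi <= length(queue)) {
    v <- queue[qi]; qi <- qi + 1L
    inq[v] <- FALSE
    cv <- part[v]
    nb <- adj$nb[[v]]; wv <- adj$w[[v]]
    # weight from v to each candidate community, in neighbor scan order
    if (length(nb)) {
      comm <- part[nb]
      cand <- unique(comm)
      kto <- vapply(cand, function(d) sum(wv[comm == d]), numeric(1))
    } else {
      cand <- integer(0); kto <- numeric(0)
    }
    k_cur <- if (cv %in% cand) kto[match(cv, cand)] else 0
    f_cur <- k_cur - gamma * s[v] * (S[cv] - s[v]) / twom
    best_f <- f_cur
    best_d <- cv
    for (ci in seq_along(cand)) {
      d <- cand[ci]
      if (d == cv) next
      f_d <- kto[ci] - gamma * s[v] * S[d] / twom
      if (f_d > best_f + tol * m) { best_f <- f_d; best_d <- d }
    }
    # empty community: f = 0
    if (0 > best_f + tol * m) { best_f <- 0; best_d <- 0L }
    if (best_d != cv) {
      if (best_d == 0L) {  # new singleton community
        maxlab <- maxlab + 1L
        S <- c(S, 0)
        best_d <- maxlab
      }
      S[cv] <- S[cv] - s[v]
      S[best_d] <- S[best_d] + s[v]
      part[v] <- best_d
      moved_any <- TRUE
      for (u in nb) {
        if (!inq[u] && part[u] != best_d) {
          queue <- c(queue, u)
          inq[u] <- TRUE
        }
      }
    }
  }
  list(part = .relabel(part), moved = moved_any)
}

.relabel <- function(part) {
  match(part, unique(part))
}

# ---- refinement -----------------------------------------------------------

# Deterministic greedy refinement: within each community of `part`, start
# from singletons and merge each still-singleton node (scanned in index
# order) into the adjacent sub-community with maximal positive gain. Only
# nodes with a neighbor in the target sub-community are merged, so refined
# clusters are internally connected.
.refine <- function(adj, s, twom, part, gamma, tol = 1e-12) {
  n <- length(s)
  m <- twom / 2
  sub <- seq_len(n)
  Ssub <- s
  for (v in seq_len(n)) {
    if (sum(sub == sub[v]) > 1L) next  # only singleton nodes move
    nb <- adj$nb[[v]]; wv <- adj$w[[v]]
    if (!length(nb)) next
    keep <- part[nb] == part[v]
    nb <- nb[keep]; wv <- wv[keep]
    if (!length(nb)) next
    comm <- sub[nb]
    cand <- sort(unique(comm[comm != sub[v]]))
    if (!length(cand)) next
    kto <- vapply(cand, function(d) sum(wv[comm == d]), numeric(1))
    f_cur <- -gamma * s[v] * (Ssub[sub[v]] - s[v]) / twom  # k within own singleton = 0
    gains <- kto - gamma * s[v] * Ssub[cand] / twom - f_cur
    best <- which(gains == max(gains))[1]
    if (gains[best] > tol * m) {
      Ssub[sub[v]] <- Ssub[sub[v]] - s[v]
      d <- cand[best]
      Ssub[d] <- Ssub[d] + s[v]
      sub[v] <- d
    }
  }
  .relabel(sub)
}

# ---- aggregation ----------------------------------------------------------

.aggregate <- function(g, groups) {
  a <- groups[g$ea]
  b <- groups[g$eb]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)
  w <- as.numeric(rowsum(g$w, key, reorder = FALSE))
  uk <- unique(key)
  parts <- strsplit(uk, " ", fixed = TRUE)
  list(n = max(groups),
       ea = vapply(parts, function(p) as.integer(p[1]), integer(1)),
       eb = vapply(parts, function(p) as.integer(p[2]), integer(1)),
       w = w)
}

# ---- one full Leiden run --------------------------------------------------

# Runs local moving -> refinement -> aggregation until no improving move,
# starting from `init` (default: all-singleton). Node visit orders come
# from sample() under the caller's RNG state.
.leiden_run <- function(g0, gamma, maxIterations, init = NULL) {
  orig2agg <- seq_len(g0$n)
  g <- g0
  part <- if (is.null(init)) seq_len(g$n) else .relabel(init)
  trace <- .q_internal(g0, part[orig2agg], gamma)
  for (iter in seq_len(maxIterations)) {
    adj <- .graph_adjacency(g)
    s <- .graph_strength(g)
    twom <- sum(s)
    lm <- .local_move(adj, s, twom, part, gamma, order = sample.int(g$n))
    part <- lm$part
    q <- .q_internal(g, part, gamma)
    trace <- c(trace, q)
    ncomm <- max(part)
    if (ncomm == g$n) break  # every aggregate node its own community: stable
    refined <- .refine(adj, s, twom, part, gamma)
    agg <- .aggregate(g, refined)
    # induced partition on the aggregate graph: community of each refined
    # cluster under the local-moving partition
    part_new <- integer(agg$n)
    for (v in seq_len(g$n)) part_new[refined[v]] <- part[v]
    orig2agg <- refined[orig2agg]
    no_change <- agg$n == g$n
    g <- agg
    part <- .relabel(part_new)
    if (no_change && !lm$moved) break
  }
  list(membership = part[orig2agg], q = trace[length(trace)], trace = trace)
}

# Split any community that is not internally connected into its connected
# components; with gamma > 0 this never decreases Q.
.split_disconnected <- function(g, part) {
  adj <- .graph_adjacency(g)
  out <- integer(length(part))
  nxt <- 0L
  for (c in unique(part)) {
    members <- which(part == c)
    seen <- logical(length(part))
    for (v0 in members) {
      if (seen[v0]) next
      nxt <- nxt + 1L
      stack <- v0
      seen[v0] <- TRUE
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        out[v] <- nxt
        for (u in adj$nb[[v]]) {
          if (!seen[u] && part[u] == c) {
            seen[u] <- TRUE
            stack <- c(stack, u)
          }
        }
      }
    }
  }
  out
}

# Canonical labels: 0-based, in order of first appearance over nodes
# sorted by id (the internal node order is already id-sorted).
.canonical_membership <- function(part, nodes) {
  lab <- match(part, unique(part)) - 1L
  names(lab) <- nodes
  lab
}

#' Leiden community detection on the disease network
#'
#' Detects communities by weighted-modularity optimisation using the Leiden
#' scheme: queue-based local moving, deterministic greedy refinement within
#' communities, and graph aggregation, iterated until no improving move.
#' Node visit order is shuffled with a seeded RNG and the algorithm is
#' restarted \code{nRestarts} times (the first run from the all-singleton
#' start, later runs from random initial partitions so different
#' attraction basins are explored), keeping the best partition; results
#' are deterministic for a fixed seed. Any community left internally
#' disconnected is split into its connected components (which never lowers
#' Q), so returned communities are connected. The returned modularity is at
#' least that of both the all-singleton and the single-community
#' partitions.
#'
#' @param net a [DiseaseNetwork-class] with at least one edge.
#' @param resolution resolution parameter \eqn{\gamma > 0}; default 1.
#' @param seed integer RNG seed; default 42.
#' @param maxIterations maximum local-move/refine/aggregate cycles per
#'   restart; default 50.
#' @param nRestarts independent restarts with fresh visit orders and
#'   initial partitions; default 25.
#' @return a [CommunityPartition-class]; its \code{trace} slot holds the
#'   non-decreasing modularity trace of the winning restart.
#' @export
leidenCommunities <- function(net, resolution = 1, seed = 42L,
                              maxIterations = 50L, nRestarts = 25L) {
  stopifnot(resolution > 0, nRestarts >= 1)
  g <- .graph_from_network(net)
  if (!length(g$w)) stop("edgeless network", call. = FALSE)
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(nRestarts)) {
      # the first restart starts from singletons; later ones from random
      # partitions, so runs explore different attraction basins of the
      # single-move-stable local optima
      init <- if (r == 1) NULL
              else sample.int(sample.int(g$n, 1), g$n, replace = TRUE)
      res <- .leiden_run(g, resolution, maxIterations, init = init)
      if (is.null(best) || res$q > best$q + 1e-12) best <- res
    }
  })
  part <- .split_disconnected(g, best$membership)
  # guard: never return worse than the single-community partition
  q_split <- .q_internal(g, part, resolution)
  q_one <- .q_internal(g, rep(1L, g$n), resolution)
  if (q_one > q_split + 1e-12) {
    part <- rep(1L, g$n)
    q_split <- q_one
  }
  membership <- .canonical_membership(part, g$nodes)
  new("CommunityPartition",
      membership = membership,
      modularity = networkModularity(net, membership, resolution),
      resolution = as.numeric(resolution),
      seed = as.integer(seed),
      nCommunities = length(unique(membership)),
      trace = c(best$trace, q_split))
}

# ---- exhaustive oracle ----------------------------------------------------

# All set partitions of n elements as restricted growth strings (1-based),
# in lexicographic order. Bell(10) = 115975; larger n is refused upstream.
.rgs_partitions <- function(n) {
  out <- list()
  a <- integer(n)
  recurse <- function(i, mx) {
    if (i > n) {
      out[[length(out) + 1L]] <<- a[seq_len(n)]
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1L)) {
      a[i] <<- v
      recurse(i + 1L, max(mx, v))
    }
  }
  a[1] <- 1L
  recurse(2L, 1L)
  out
}

#' Exhaustive modularity-optimal partition (small-graph oracle)
#'
#' Enumerates every set partition of the node set (restricted-growth-string
#' enumeration; at most 10 nodes) and returns the modularity-maximal one.
#' Ties are broken toward the lexicographically smallest canonical
#' labelling over nodes in sorted order. Intended as a ground-truth oracle
#' for validating heuristic community detection on small instances.
#'
#' @param net a [DiseaseNetwork-class] with at most 10 nodes and at least
#'   one edge.
#' @param resolution resolution parameter \eqn{\gamma > 0}; default 1.
#' @return a [CommunityPartition-class] with the maximal modularity.
#' @export
bruteForceBestPartition <- function(net, resolution = 1) {
  stopifnot(resolution > 0)
  g <- .graph_from_network(net)
  if (g$n > 10) stop("exhaustive search limited to 10 nodes", call. = FALSE)
  if (!length(g$w)) stop("edgeless network", call. = FALSE)
  s <- .graph_strength(g)
  twom <- sum(s)
  bestQ <- -Inf
  bestP <- NULL
  for (p in .rgs_partitions(g$n)) {
    intra <- 2 * sum(g$w[p[g$ea] == p[g$eb]])
    Sc <- rowsum(s, p)
    q <- intra / twom - resolution * sum((Sc / twom)^2)
    if (q > bestQ) { bestQ <- q; bestP <- p }
  }
  membership <- .canonical_membership(bestP, g$nodes)
  new("CommunityPartition",
      membership = membership,
      modularity = networkModularity(net, membership, resolution),
      resolution = as.numeric(resolution),
      seed = NA_integer_,
      nCommunities = length(unique(membership)),
      trace = bestQ)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two community assignments over the
#' same items; 1 for identical partitions (up to label permutation), around
#' 0 for independent ones.
#'
#' @param a,b vectors of community labels; when both are named, \code{b} is
#'   aligned to \code{a} by name.
#' @return the adjusted Rand index (scalar).
#' @export
adjustedRand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    stopifnot(setequal(names(a), names(b)))
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)  # both partitions trivial
  (sij - expected) / (mx - expected)
}

#' Export a partition as TSV plus run metadata
#'
#' Writes the per-disease community assignment (`disease_id`, `community`)
#' and a JSON sidecar with seed, resolution, modularity and community
#' count.
#'
#' @param partition a [CommunityPartition-class].
#' @param path output TSV path; metadata is written to
#'   \code{paste0(path, ".meta.json")}.
#' @return the TSV path, invisibly.
#' @export
writePartition <- function(partition, path) {
  m <- communityLabels(partition)
  .write_tsv(data.frame(disease_id = names(m), community = as.integer(m),
                        stringsAsFactors = FALSE), path)
  meta <- list(seed = partition@seed, resolution = partition@resolution,
               modularity = partition@modularity,
               nCommunities = partition@nCommunities)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
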