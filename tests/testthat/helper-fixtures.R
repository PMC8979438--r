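# Shared fixtures and independent oracles used across the test files.
# Oracles here are deliberately naive re-implementations (enumeration,
# brute force) kept independent of the package code paths they check.

# residue table builder for hand-placed C-alpha fixtures
fixtureResidues <- function(xyz, aa = "A", chain = "A",
                            positions = seq_len(nrow(xyz)), cb = NULL) {
  if (is.null(cb)) cb <- matrix(NA_real_, nrow(xyz), 3)
  data.frame(chain = chain, position = positions,
             resid = vapply(rep_len(aa, nrow(xyz)), function(a)
               c(A = "ALA", G = "GLY", V = "VAL", L = "LEU", S = "SER",
                 K = "LYS", D = "ASP", W = "TRP")[a], ""),
             aa = rep_len(aa, nrow(xyz)),
             ca.x = xyz[, 1], ca.y = xyz[, 2], ca.z = xyz[, 3],
             cb.x = cb[, 1], cb.y = cb[, 2], cb.z = cb[, 3],
             stringsAsFactors = FALSE)
}

fixtureStructure <- function(xyz, ...) {
  structureModel(fixtureResidues(xyz, ...))
}

# straight-chain structure, spacing in A
pathStructure <- function(n, spacing = 3.8, aa = "A") {
  fixtureStructure(cbind(seq(0, by = spacing, length.out = n), 0, 0),
                   aa = aa)
}

# alignment from a character vector of equal-length strings
fixtureAlignment <- function(seqs, ids = sprintf("s%02d", seq_along(seqs)),
                             referenceIndex = 1L) {
  new("SequenceAlignment", ids = ids,
      chars = do.call(rbind, strsplit(seqs, "")),
      referenceIndex = as.integer(referenceIndex))
}

# --- enumeration oracles -------------------------------------------------

# all shortest paths between two nodes by breadth-limited DFS enumeration
.allShortestPaths <- function(adj, s, t) {
  n <- nrow(adj)
  dist <- rep(Inf, n); dist[s] <- 0
  queue <- s
  while (length(queue)) {               # BFS distances
    u <- queue[1]; queue <- queue[-1]
    for (v in which(adj[u, ])) if (dist[v] > dist[u] + 1) {
      dist[v] <- dist[u] + 1; queue <- c(queue, v)
    }
  }
  if (!is.finite(dist[t])) return(list())
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) { paths[[length(paths) + 1L]] <<- path; return() }
    for (v in which(adj[u, ]))
      if (dist[v] == dist[u] + 1) walk(c(path, v))
  }
  walk(s)
  paths
}

# exhaustive centrality oracle for small unweighted graphs: degree,
# pair-normalized betweenness, closeness (per component), clustering
oracleCentralities <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  # components by repeated BFS
  compOf <- rep(NA_integer_, n); cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(compOf[s])) next
    cid <- cid + 1L
    queue <- s; compOf[s] <- cid
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in which(adj[u, ])) if (is.na(compOf[v])) {
        compOf[v] <- cid; queue <- c(queue, v)
      }
    }
  }
  csize <- table(compOf)[compOf]
  bcRaw <- rep(0, n)
  distSum <- rep(0, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || compOf[s] != compOf[t]) next
    paths <- .allShortestPaths(adj, s, t)
    distSum[s] <- distSum[s] + (length(paths[[1]]) - 1)
    distSum[t] <- distSum[t] + (length(paths[[1]]) - 1)
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    for (v in seq_len(n))
      bcRaw[v] <- bcRaw[v] + sum(inner == v) / length(paths)
  }
  pairs <- (csize - 1) * (csize - 2) / 2
  bc <- ifelse(pairs > 0, bcRaw / pairs, 0)
  cc <- ifelse(csize > 1, (csize - 1) / distSum, 0)
  cl <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    2 * links / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  data.frame(DC = deg, BC = bc, BCraw = bcRaw, CC = cc, C = cl,
             componentSize = as.integer(csize))
}

# Erdos-Renyi-ish random adjacency matrix
randomAdjacency <- function(n, p = 0.4) {
  a <- matrix(FALSE, n, n)
  a[upper.tri(a)] <- runif(n * (n - 1) / 2) < p
  a | t(a)
}

# independent RMSD oracle: brute-force minimization over rotations is
# impractical, so use the reference implementation in bio3d
oracleKabschRmsd <- function(a, b) {
  idx <- seq_len(3 * nrow(a))
  as.numeric(bio3d::rmsd(as.vector(t(a)), as.vector(t(b)),
                         a.inds = idx, b.inds = idx, fit = TRUE))
}

# random-graph ResidueNetwork wrapper for centrality tests
adjacencyNetwork <- function(adj, weights = NULL) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- sprintf("A:%d", seq_len(nrow(adj)))
  if (!is.null(weights)) igraph::E(g)$weight <- weights
  g
}
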