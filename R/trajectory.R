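# Trajectory summaries (RMSD, RMSF, delta-RMSF), dynamic residue networks,
# frame-averaged betweenness, and Floyd-Warshall shortest-path extraction
# for allosteric communication analysis.

# frames x 3N coordinate matrix in (x1,y1,z1,x2,...) order
.trajXyz <- function(arr) {
  t(apply(arr, 1, function(m) as.vector(t(m))))
}

# Kabsch superposition of one frame (n x 3) onto a reference (n x 3):
# optimal proper rotation after centroid alignment; degenerate (collinear
# or coincident) configurations fall through cleanly via the SVD
.kabschFit <- function(ref, mob) {
  cr <- colMeans(ref); cm <- colMeans(mob)
  a <- sweep(ref, 2, cr); b <- sweep(mob, 2, cm)
  s <- svd(crossprod(b, a))            # H = B' A = U S V'
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(b %*% rot, 2, cr, "+")
}

.frameMatrix <- function(v) matrix(v, ncol = 3, byrow = TRUE)
.frameVector <- function(m) as.vector(t(m))

#' Per-frame RMSD of a trajectory
#'
#' Each frame is optimally superposed (Kabsch) onto the reference before
#' the root-mean-square deviation is taken over C-alpha atoms.
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param reference "first" frame or the trajectory "mean".
#' @return numeric vector of per-frame RMSD (A).
#' @export
rmsdSeries <- function(traj, reference = c("first", "mean")) {
  reference <- match.arg(reference)
  mat <- .trajXyz(traj@ca)
  refM <- .frameMatrix(if (reference == "first") mat[1, ] else
    colMeans(mat))
  apply(mat, 1, function(v) {
    fit <- .kabschFit(refM, .frameMatrix(v))
    sqrt(mean(rowSums((fit - refM)^2)))
  })
}

# superpose all frames to their running mean, two refinement passes
.superposeToMean <- function(mat, passes = 2L) {
  ref <- mat[1, ]
  fitted <- mat
  for (p in seq_len(passes)) {
    refM <- .frameMatrix(ref)
    for (f in seq_len(nrow(mat)))
      fitted[f, ] <- .frameVector(.kabschFit(refM, .frameMatrix(mat[f, ])))
    ref <- colMeans(fitted)
  }
  list(fitted = fitted, mean = ref)
}

#' Per-residue RMSF of a trajectory
#'
#' Frames are superposed to their mean (two refinement passes), then
#' RMSF_i = sqrt(mean |r_i - <r_i>|^2).
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @return numeric vector of per-residue RMSF (A).
#' @export
rmsfProfile <- function(traj) {
  sp <- .superposeToMean(.trajXyz(traj@ca))
  diff2 <- sweep(sp$fitted, 2, sp$mean)^2
  n <- ncol(diff2) / 3L
  vapply(seq_len(n), function(i)
    sqrt(mean(rowSums(diff2[, (3 * i - 2):(3 * i), drop = FALSE]))),
    numeric(1))
}

#' Differential RMSF between two systems
#'
#' Elementwise mutant-minus-wild-type RMSF difference.
#'
#' @param mutant,wt trajectories (\linkS4class{TrajectoryEnsemble}) or
#'   precomputed RMSF vectors.
#' @return numeric vector of per-residue delta-RMSF (A).
#' @export
deltaRmsf <- function(mutant, wt) {
  a <- if (methods::is(mutant, "TrajectoryEnsemble")) rmsfProfile(mutant)
       else mutant
  b <- if (methods::is(wt, "TrajectoryEnsemble")) rmsfProfile(wt) else wt
  if (length(a) != length(b)) stopf("systems differ in residue count")
  a - b
}

#' Build a dynamic residue network from a trajectory
#'
#' One contact graph per frame on C-beta nodes (C-alpha for glycine): an
#' edge joins two residues within the cutoff (default 6.5 A). The
#' consensus graph keeps edges whose occupancy fraction is at least the
#' threshold (default 0.5, boundary inclusive).
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param cutoff contact distance in A (default 6.5).
#' @param threshold consensus occupancy threshold (default 0.5).
#' @param representative "cb" (C-alpha for glycine) or "ca".
#' @return \linkS4class{DynamicResidueNetwork}
#' @export
buildDrn <- function(traj, cutoff = 6.5, threshold = 0.5,
                     representative = c("cb", "ca")) {
  representative <- match.arg(representative)
  r <- traj@residues
  n <- nrow(r)
  nf <- dim(traj@ca)[1]
  occ <- matrix(0, n, n)
  frameEdges <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- traj@ca[f, , ]
    if (representative == "cb") {
      cb <- traj@cb[f, , ]
      use <- is.finite(cb[, 1]) & r$aa != "G"
      xyz[use, ] <- cb[use, ]
    }
    adj <- as.matrix(stats::dist(xyz)) <= cutoff
    diag(adj) <- FALSE
    occ <- occ + adj
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    frameEdges[[f]] <- unname(cbind(idx[, 1], idx[, 2]))
  }
  occ <- occ / nf
  keys <- residueKey(r$chain, r$position)
  keep <- which(occ >= threshold & upper.tri(occ), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- keys
  if (nrow(keep)) {
    g <- igraph::add_edges(g, t(keep))
    igraph::E(g)$occupancy <- occ[keep]
  }
  nodes <- data.frame(chain = r$chain, position = r$position, aa = r$aa,
                      key = keys, stringsAsFactors = FALSE)
  methods::new("DynamicResidueNetwork", frameEdges = frameEdges,
               occupancy = occ, consensus = g, nodes = nodes,
               cutoff = cutoff, threshold = threshold)
}

#' Frame-averaged betweenness centrality of a DRN
#'
#' Betweenness (normalized by the number of node pairs, per component) is
#' computed on every frame graph and averaged over frames; a frame in
#' which a node is isolated contributes 0 for it.
#'
#' @param drn a \linkS4class{DynamicResidueNetwork}.
#' @return data.frame (key, BC) of per-residue mean betweenness.
#' @export
drnBetweenness <- function(drn) {
  n <- nrow(drn@nodes)
  acc <- numeric(n)
  for (edges in drn@frameEdges) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    acc <- acc + centralities(g)$BC
  }
  data.frame(key = drn@nodes$key, BC = acc / length(drn@frameEdges),
             stringsAsFactors = FALSE)
}

#' All-pairs shortest distances (Floyd-Warshall)
#'
#' Classic dynamic-programming recursion on a dense weight matrix;
#' \code{Inf} marks missing edges. Exposed directly so path extraction can
#' be cross-checked against independent single-source algorithms.
#'
#' @param w square matrix of nonnegative edge lengths, Inf off-edges;
#'   the diagonal is forced to 0.
#' @return matrix of shortest-path distances.
#' @export
floydWarshall <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (any(w < 0, na.rm = TRUE)) stopf("edge lengths must be nonnegative")
  d <- w
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    upd <- dk < d
    d[upd] <- dk[upd]
  }
  d
}

# dense length matrix from a graph-like object
.lengthMatrix <- function(net, weighted = FALSE) {
  if (methods::is(net, "DynamicResidueNetwork")) {
    g <- net@consensus
    lens <- if (weighted) 1 / igraph::E(g)$occupancy else
      rep(1, igraph::ecount(g))
  } else {
    g <- if (methods::is(net, "ResidueNetwork")) net@graph else net
    lens <- if (weighted) {
      w <- abs(igraph::E(g)$weight)
      if (any(w == 0)) stopf("weighted paths require nonzero edge weights")
      1 / w
    } else rep(1, igraph::ecount(g))
  }
  n <- igraph::vcount(g)
  w <- matrix(Inf, n, n)
  if (igraph::ecount(g)) {
    e <- igraph::ends(g, igraph::E(g), names = FALSE)
    w[e] <- pmin(w[e], lens)
    w[e[, 2:1, drop = FALSE]] <- w[e]
  }
  diag(w) <- 0
  rownames(w) <- colnames(w) <- igraph::V(g)$name
  w
}

#' Shortest allosteric paths from a source to target residues
#'
#' One shortest path per (source, target) on the consensus graph of a
#' dynamic residue network (or on a static residue network), using the
#' Floyd-Warshall distance matrix. Paths are unweighted (hop count) by
#' default; the weighted mode uses edge length 1/occupancy (DRN) or
#' 1/|energy| (static). Ties are broken deterministically by the
#' lexicographically smallest node-key sequence. Unreachable targets are
#' reported with a warning, never fatal.
#'
#' @param net \linkS4class{DynamicResidueNetwork},
#'   \linkS4class{ResidueNetwork} or igraph object.
#' @param source node key "chain:position".
#' @param targets character vector of node keys.
#' @param weighted logical (default FALSE: hop metric).
#' @param annotations optional named character of functional-domain
#'   labels per node key, copied onto path nodes.
#' @return named list of \linkS4class{PathResult} (NULL where
#'   unreachable), names "source->target".
#' @export
shortestPaths <- function(net, source, targets, weighted = FALSE,
                          annotations = character(0)) {
  w <- .lengthMatrix(net, weighted)
  keys <- rownames(w)
  si <- match(source, keys)
  if (is.na(si)) stopf("source %s not in network", source)
  d <- floydWarshall(w)
  out <- stats::setNames(vector("list", length(targets)),
                         paste0(source, "->", targets))
  prov <- list(weighted = weighted,
               network = class(net)[1],
               cutoff = if (methods::is(net, "DynamicResidueNetwork"))
                 net@cutoff else NA,
               threshold = if (methods::is(net, "DynamicResidueNetwork"))
                 net@threshold else NA)
  for (t in seq_along(targets)) {
    ti <- match(targets[t], keys)
    if (is.na(ti)) stopf("target %s not in network", targets[t])
    if (!is.finite(d[si, ti])) {
      warnf("target %s unreachable from %s", targets[t], source)
      next
    }
    # greedy reconstruction: at each step take the neighbour on a shortest
    # path with the lexicographically smallest key
    path <- si
    u <- si
    while (u != ti) {
      cand <- which(is.finite(w[u, ]) & w[u, ] > 0)
      cand <- cand[abs(w[u, cand] + d[cand, ti] - d[u, ti]) < 1e-9]
      cand <- setdiff(cand, path)
      if (!length(cand)) stopf("path reconstruction failed (internal)")
      u <- cand[order(keys[cand])][1]
      path <- c(path, u)
    }
    ann <- annotations[keys[path]]
    ann <- ann[!is.na(names(ann))]
    out[[t]] <- methods::new("PathResult", nodes = keys[path],
                             hops = length(path) - 1L,
                             annotations = stats::setNames(
                               unname(annotations[keys[path]]), keys[path]),
                             provenance = prov)
  }
  out
}

#' Compare two sets of allosteric paths
#'
#' Pairs paths by name across two systems (e.g. wild type vs mutant) and
#' reports hop-count differences, shared-node sets, and counts of path
#' nodes per functional-domain label.
#'
#' @param a,b named lists of \linkS4class{PathResult} (as returned by
#'   \code{\link{shortestPaths}}); names are matched, order-insensitive.
#' @param annotations optional named character of domain labels per node
#'   key (used for the per-domain counts).
#' @return data.frame with one row per shared name: hops_a, hops_b,
#'   hop_diff (b - a), n_shared, shared (semicolon-joined), and per-domain
#'   node counts for each system.
#' @export
pathCompare <- function(a, b, annotations = character(0)) {
  ids <- intersect(names(a), names(b))
  doms <- sort(unique(annotations))
  rows <- lapply(ids, function(id) {
    pa <- a[[id]]; pb <- b[[id]]
    if (is.null(pa) || is.null(pb)) return(NULL)
    shared <- intersect(pa@nodes, pb@nodes)
    row <- data.frame(id = id, hops_a = pa@hops, hops_b = pb@hops,
                      hop_diff = pb@hops - pa@hops,
                      n_shared = length(shared),
                      shared = paste(shared, collapse = ";"),
                      stringsAsFactors = FALSE)
    for (dm in doms) {
      keysIn <- names(annotations)[annotations == dm]
      row[[paste0(dm, "_a")]] <- sum(pa@nodes %in% keysIn)
      row[[paste0(dm, "_b")]] <- sum(pb@nodes %in% keysIn)
    }
    row
  })
  do.call(rbind, rows)
}

#' Write paths as a TSV table
#'
#' One row per path with semicolon-joined node lists.
#'
#' @param paths named list of \linkS4class{PathResult}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePathTable <- function(paths, path) {
  keep <- !vapply(paths, is.null, logical(1))
  df <- data.frame(id = names(paths)[keep],
                   hops = vapply(paths[keep], function(p) p@hops, integer(1)),
                   nodes = vapply(paths[keep], function(p)
                     paste(p@nodes, collapse = ";"), ""),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
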