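# Amino-acid contact energy networks (AACEN): building, the four node
# centralities, and mutation-induced centrality changes.

#' Environment-dependent contact energies from counts
#'
#' e_ij = -ln[(N_ij N_00 C_i0 C_j0) / (N_i0 N_j0 C_ij C_00)] for residue
#' types i, j, where N are observed contact counts, C reference counts from
#' a random-mixing model, and class 0 is solvent. Entries whose ratio
#' touches a zero count are NA with a warning unless a pseudo-count is
#' configured.
#'
#' @param counts a \linkS4class{ContactCountTable}.
#' @param pseudocount numeric added to every count before the ratio
#'   (default NULL: no pseudo-count, zeros give NA).
#' @return symmetric 20 x 20 matrix of dimensionless energies, dimnames
#'   \code{AA_ALPHABET20}.
#' @export
contactEnergyFromCounts <- function(counts, pseudocount = NULL) {
  N <- counts@observed
  C <- counts@reference
  if (!is.null(pseudocount)) {
    N <- N + pseudocount
    C <- C + pseudocount
  }
  aa <- AA_ALPHABET20
  e <- matrix(NA_real_, 20, 20, dimnames = list(aa, aa))
  nZero <- 0L
  for (i in aa) for (j in aa) {
    num <- N[i, j] * N["0", "0"] * C[i, "0"] * C[j, "0"]
    den <- N[i, "0"] * N[j, "0"] * C[i, j] * C["0", "0"]
    if (num > 0 && den > 0) e[i, j] <- -log(num / den) else nZero <- nZero + 1L
  }
  if (nZero) warnf("%d contact-energy entries undefined (zero counts)", nZero)
  e
}

# representative coordinate per residue: C-beta, C-alpha for glycine or
# when no C-beta is present
.representativeCoords <- function(residues, representative = c("cb", "ca")) {
  representative <- match.arg(representative)
  ca <- as.matrix(residues[, c("ca.x", "ca.y", "ca.z")])
  if (representative == "ca") return(ca)
  cb <- as.matrix(residues[, c("cb.x", "cb.y", "cb.z")])
  useCb <- is.finite(cb[, 1]) & residues$aa != "G"
  out <- ca
  out[useCb, ] <- cb[useCb, ]
  out
}

#' Build an amino-acid contact energy network
#'
#' Nodes are residues; an edge joins two residues whose representative
#' atoms (C-beta, C-alpha for glycine) lie within the cutoff, excluding
#' sequence neighbours within the same chain; edge weight is the contact
#' energy of the incident residue types.
#'
#' @param struct a \linkS4class{StructureModel}.
#' @param energies 20 x 20 contact-energy matrix from
#'   \code{\link{contactEnergyFromCounts}}.
#' @param contactDef list: cutoff (A, default 8), representative ("cb" or
#'   "ca"), excludeNeighbors (|i-j| <= this within a chain, default 1).
#' @return \linkS4class{ResidueNetwork}
#' @export
buildAacen <- function(struct, energies,
                       contactDef = list(cutoff = 8, representative = "cb",
                                         excludeNeighbors = 1L)) {
  r <- struct@residues
  cutoff <- contactDef$cutoff %||% 8
  excl <- contactDef$excludeNeighbors %||% 1L
  xyz <- .representativeCoords(r, contactDef$representative %||% "cb")
  n <- nrow(r)
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  sameChain <- outer(r$chain, r$chain, "==")
  near <- abs(outer(r$position, r$position, "-")) <= excl
  adj[sameChain & near] <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (!nrow(idx))
    stopf("empty network: no contacts at cutoff %.2f A; review contactDef",
          cutoff)
  w <- energies[cbind(r$aa[idx[, 1]], r$aa[idx[, 2]])]
  nodes <- data.frame(chain = r$chain, position = r$position, aa = r$aa,
                      key = residueKey(r$chain, r$position),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_edgelist(cbind(idx[, 1], idx[, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::gorder(g)))
  igraph::V(g)$name <- nodes$key
  igraph::E(g)$weight <- w
  methods::new("ResidueNetwork", graph = g, nodes = nodes,
               contactDef = list(cutoff = cutoff,
                                 representative = contactDef$representative %||% "cb",
                                 excludeNeighbors = excl))
}

#' Node centralities of a residue network
#'
#' Degree (DC), betweenness (BC) normalized by the number of node pairs
#' (n-1)(n-2)/2, closeness (CC) as the reciprocal of the average shortest
#' path length, and the clustering coefficient (C), with C = 0 for nodes of
#' degree < 2. Shortest paths are unweighted by default; the weighted mode
#' uses edge length 1/|e_ij| for BC and CC and reports DC as the weighted
#' degree (node strength, sum of |e| over incident edges). The clustering
#' coefficient stays the unweighted triangle fraction in both modes. On a
#' disconnected graph BC and CC are computed per component and component
#' sizes are reported.
#'
#' @param net a \linkS4class{ResidueNetwork} (or igraph object).
#' @param weighted logical, use |weight|-aware degree and 1/|weight| edge
#'   lengths for paths.
#' @return data.frame (key, DC, BC, CC, C, component, componentSize).
#' @export
centralities <- function(net, weighted = FALSE) {
  g <- if (methods::is(net, "ResidueNetwork")) net@graph else net
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  csize <- comp$csize[comp$membership]
  lens <- if (weighted) {
    w <- abs(igraph::E(g)$weight)
    if (any(w == 0)) stopf("weighted mode requires nonzero edge weights")
    1 / w
  } else NA
  bcRaw <- igraph::betweenness(g, weights = lens, directed = FALSE)
  pairs <- (csize - 1) * (csize - 2) / 2
  bc <- ifelse(pairs > 0, bcRaw / pairs, 0)
  suppressWarnings(
    clo <- igraph::closeness(g, weights = lens, mode = "all"))
  cc <- ifelse(csize > 1, clo * (csize - 1), 0)
  cc[is.na(cc)] <- 0
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  deg <- if (weighted)
    igraph::strength(g, weights = abs(igraph::E(g)$weight))
  else igraph::degree(g)
  cl[igraph::degree(g) < 2] <- 0
  key <- igraph::V(g)$name %||% as.character(seq_len(n))
  data.frame(key = key, DC = as.numeric(deg), BC = as.numeric(bc),
             CC = as.numeric(cc), C = as.numeric(cl),
             component = comp$membership, componentSize = csize,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Network of a mutant structure or a type-swap proxy
#'
#' With a mutant structure, builds its AACEN. Without one (the default
#' proxy), the mutant network keeps the wild-type contacts and only the
#' edge weights incident to the mutated node are recomputed with the new
#' residue type. A glycine mutated to a non-glycine keeps its C-alpha
#' representative, with a warning, since no C-beta exists to re-derive
#' contacts from.
#'
#' @param struct wild-type \linkS4class{StructureModel}.
#' @param mut one-row mutation data.frame (wt_aa, position, mut_aa, chain).
#' @param energies contact-energy matrix.
#' @param mutantStruct optional mutant \linkS4class{StructureModel}.
#' @param contactDef contact rule, as in \code{\link{buildAacen}}.
#' @param wtNet optional precomputed wild-type network (saves rebuilding).
#' @return \linkS4class{ResidueNetwork}
#' @export
mutateNetwork <- function(struct, mut, energies, mutantStruct = NULL,
                          contactDef = list(cutoff = 8, representative = "cb",
                                            excludeNeighbors = 1L),
                          wtNet = NULL) {
  if (!is.null(mutantStruct))
    return(buildAacen(mutantStruct, energies, contactDef))
  net <- wtNet %||% buildAacen(struct, energies, contactDef)
  key <- residueKey(mut$chain, mut$position)
  v <- match(key, net@nodes$key)
  if (is.na(v)) stopf("mutation site %s not in structure", key)
  if (net@nodes$aa[v] != mut$wt_aa)
    stopf("wild-type mismatch at %s: structure has %s, mutation says %s",
          key, net@nodes$aa[v], mut$wt_aa)
  if (net@nodes$aa[v] == "G" && mut$mut_aa != "G" &&
      (net@contactDef$representative %||% "cb") == "cb")
    warnf("G%d%s under the C-beta rule: keeping C-alpha representative",
          mut$position, mut$mut_aa)
  g <- net@graph
  nodes <- net@nodes
  nodes$aa[v] <- mut$mut_aa
  inc <- igraph::incident(g, v)
  if (length(inc)) {
    ends <- igraph::ends(g, inc, names = FALSE)
    other <- ifelse(ends[, 1] == v, ends[, 2], ends[, 1])
    igraph::E(g)$weight[as.integer(inc)] <-
      energies[cbind(rep(mut$mut_aa, length(other)), nodes$aa[other])]
  }
  methods::new("ResidueNetwork", graph = g, nodes = nodes,
               contactDef = net@contactDef)
}

#' Mutation-induced centrality changes at the mutated site
#'
#' Signed mutant-minus-wild-type differences of DC, BC, CC and C at the
#' mutated node, with absolute values recorded alongside.
#'
#' @param wt,mut centrality data.frames from \code{\link{centralities}}
#'   computed on the same node set.
#' @param site node key "chain:position".
#' @return list with elements \code{signed} and \code{abs}, each a named
#'   numeric vector (dDC, dBC, dCC, dC).
#' @export
deltaCentrality <- function(wt, mut, site) {
  if (!identical(wt$key, mut$key))
    stopf("centrality tables are not on the same node set")
  i <- match(site, wt$key)
  if (is.na(i)) stopf("site %s absent from the network", site)
  signed <- c(dDC = mut$DC[i] - wt$DC[i], dBC = mut$BC[i] - wt$BC[i],
              dCC = mut$CC[i] - wt$CC[i], dC = mut$C[i] - wt$C[i])
  list(signed = signed, abs = abs(signed))
}

#' Whole-network L1 centrality change
#'
#' Sum over all nodes of |mutant - wild-type| for each centrality; an
#' optional global companion to the per-site deltas.
#'
#' @param wt,mut centrality data.frames on the same node set.
#' @return named numeric (dDC_L1, dBC_L1, dCC_L1, dC_L1).
#' @export
deltaCentralityL1 <- function(wt, mut) {
  if (!identical(wt$key, mut$key))
    stopf("centrality tables are not on the same node set")
  c(dDC_L1 = sum(abs(mut$DC - wt$DC)), dBC_L1 = sum(abs(mut$BC - wt$BC)),
    dCC_L1 = sum(abs(mut$CC - wt$CC)), dC_L1 = sum(abs(mut$C - wt$C)))
}

#' Export a residue network as an edge list
#'
#' @param net a \linkS4class{ResidueNetwork}.
#' @param path output TSV (columns: node_a, node_b, weight).
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(net, path) {
  e <- igraph::as_data_frame(net@graph, what = "edges")
  names(e) <- c("node_a", "node_b", "weight")[seq_len(ncol(e))]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
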