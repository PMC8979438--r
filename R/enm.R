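# Gaussian and anisotropic elastic network models and the five dynamics
# features: mean-square fluctuations, perturbation-response effectiveness
# and sensitivity, mechanical bridging score, and stiffness.
#
# Conventions: spring constant gamma = 1 and kBT/gamma = 1 by default; all
# features are used comparatively, so the absolute fluctuation scale is
# configurable but immaterial to the group statistics.

#' KirchhoffMatrix: the GNM connectivity matrix
#'
#' Symmetric N x N matrix with off-diagonal -gamma for node pairs within
#' the cutoff, 0 beyond it, and diagonal minus the row sum of
#' off-diagonals (rows sum to zero).
#'
#' @slot mat numeric matrix.
#' @slot cutoff,gamma parameters used.
#' @slot nodes data.frame (chain, position, aa, key).
#' @export
setClass("KirchhoffMatrix",
         representation(mat = "matrix", cutoff = "numeric",
                        gamma = "numeric", nodes = "data.frame"))

setValidity("KirchhoffMatrix", function(object) {
  m <- object@mat
  if (max(abs(m - t(m))) > 1e-9) return("Kirchhoff matrix must be symmetric")
  if (max(abs(rowSums(m))) > 1e-8) return("rows must sum to zero")
  off <- m[upper.tri(m)]
  if (!all(abs(off) < 1e-12 | abs(off + object@gamma) < 1e-12))
    return("off-diagonals must be 0 or -gamma")
  TRUE
})

#' HessianMatrix: the ANM 3N x 3N Hessian
#'
#' Built from the pairwise harmonic potential on equilibrium distances;
#' a connected, non-degenerate 3-D structure has exactly six zero modes.
#'
#' @slot mat numeric 3N x 3N matrix.
#' @slot cutoff,gamma parameters used.
#' @slot coords N x 3 equilibrium coordinates.
#' @slot nodes data.frame (chain, position, aa, key).
#' @export
setClass("HessianMatrix",
         representation(mat = "matrix", cutoff = "numeric",
                        gamma = "numeric", coords = "matrix",
                        nodes = "data.frame"))

setValidity("HessianMatrix", function(object) {
  if (max(abs(object@mat - t(object@mat))) > 1e-8)
    return("Hessian must be symmetric")
  if (nrow(object@mat) != 3L * nrow(object@coords))
    return("Hessian must be 3N x 3N")
  TRUE
})

.nodeFrame <- function(r) {
  data.frame(chain = r$chain, position = r$position, aa = r$aa,
             key = residueKey(r$chain, r$position), stringsAsFactors = FALSE)
}

#' Build a GNM Kirchhoff matrix
#'
#' C-alpha nodes; default cutoff 7 A. A connectivity report (components at
#' the cutoff) is attached as attribute \code{"components"}; a warning is
#' emitted when the graph is disconnected.
#'
#' @param struct a \linkS4class{StructureModel}.
#' @param cutoff A (default 7).
#' @param gamma spring constant (default 1).
#' @return \linkS4class{KirchhoffMatrix}
#' @export
buildGnm <- function(struct, cutoff = 7, gamma = 1) {
  r <- struct@residues
  d <- as.matrix(stats::dist(as.matrix(r[, c("ca.x", "ca.y", "ca.z")])))
  m <- ifelse(d <= cutoff, -gamma, 0)
  diag(m) <- 0
  diag(m) <- -rowSums(m)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(m < 0, mode = "undirected"))
  if (comp$no > 1L)
    warnf("GNM graph disconnected at %.2f A: %d components of sizes %s",
          cutoff, comp$no, paste(comp$csize, collapse = ", "))
  obj <- methods::new("KirchhoffMatrix", mat = m, cutoff = cutoff,
                      gamma = gamma, nodes = .nodeFrame(r))
  attr(obj@mat, "components") <- comp$membership
  obj
}

#' Build an ANM Hessian
#'
#' Standard super-element Hessian: for a pair within the cutoff the 3 x 3
#' off-diagonal block is -gamma (rhat rhat^T) with rhat the unit
#' inter-node vector; diagonal super-elements are minus the sum of the
#' node's off-diagonal blocks. Default cutoff 13 A.
#'
#' @param struct a \linkS4class{StructureModel}.
#' @param cutoff A (default 13).
#' @param gamma spring constant (default 1).
#' @return \linkS4class{HessianMatrix}
#' @export
buildAnm <- function(struct, cutoff = 13, gamma = 1) {
  r <- struct@residues
  xyz <- as.matrix(r[, c("ca.x", "ca.y", "ca.z")])
  n <- nrow(xyz)
  h <- matrix(0, 3 * n, 3 * n)
  d <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (d[i, j] > cutoff || d[i, j] < 1e-9) next
    rij <- (xyz[j, ] - xyz[i, ]) / d[i, j]
    blk <- -gamma * tcrossprod(rij)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    h[ii, jj] <- blk
    h[jj, ii] <- blk
    h[ii, ii] <- h[ii, ii] - blk
    h[jj, jj] <- h[jj, jj] - blk
  }
  methods::new("HessianMatrix", mat = h, cutoff = cutoff, gamma = gamma,
               coords = xyz, nodes = .nodeFrame(r))
}

#' Eigen-decompose an elastic-network matrix
#'
#' Eigenvalues ascending with explicit zero-mode bookkeeping: modes with
#' lambda < tol * lambda_max are zero modes (rigid-body / connectivity
#' modes) and are excluded from every fluctuation sum.
#'
#' @param model a \linkS4class{KirchhoffMatrix} or
#'   \linkS4class{HessianMatrix}.
#' @param scale kBT/gamma factor carried into MSF (default 1).
#' @param tol relative zero-eigenvalue threshold (default 1e-8).
#' @return \linkS4class{ModeSpectrum}
#' @export
modeSpectrum <- function(model, scale = 1, tol = 1e-8) {
  kind <- if (methods::is(model, "KirchhoffMatrix")) "gnm"
          else if (methods::is(model, "HessianMatrix")) "anm"
          else stopf("model must be a KirchhoffMatrix or HessianMatrix")
  m <- model@mat
  attr(m, "components") <- NULL
  e <- eigen(m, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  zero <- which(abs(vals) <= tol * max(abs(vals)))
  if (length(zero) == length(vals)) stopf("all modes are zero modes")
  coords <- if (kind == "anm") model@coords
            else matrix(NA_real_, nrow(model@nodes), 3)
  methods::new("ModeSpectrum", values = vals, vectors = vecs,
               zeroModes = as.integer(zero), kind = kind, scale = scale,
               coords = coords)
}

#' Per-residue mean-square fluctuations
#'
#' MSF_i = 3 (kBT/gamma) [Gamma^+]_ii for a GNM spectrum (pseudoinverse
#' over the nonzero modes); for an ANM spectrum the three Cartesian
#' diagonal entries of the Hessian pseudoinverse are summed per residue
#' (the factor 3 is then implicit). On a disconnected model the
#' pseudoinverse is per component by construction (zero modes span the
#' component indicators and are excluded).
#'
#' @param spectrum a \linkS4class{ModeSpectrum}.
#' @return numeric vector of per-residue MSF.
#' @export
msf <- function(spectrum) {
  keep <- setdiff(seq_along(spectrum@values), spectrum@zeroModes)
  u <- spectrum@vectors[, keep, drop = FALSE]
  lam <- spectrum@values[keep]
  diagPinv <- rowSums(sweep(u^2, 2, lam, "/"))
  if (spectrum@kind == "gnm") {
    3 * spectrum@scale * diagPinv
  } else {
    n <- length(diagPinv) / 3L
    spectrum@scale * vapply(seq_len(n), function(i)
      sum(diagPinv[(3 * i - 2):(3 * i)]), numeric(1))
  }
}

# pseudoinverse (covariance) from a spectrum
.covFromSpectrum <- function(spectrum) {
  keep <- setdiff(seq_along(spectrum@values), spectrum@zeroModes)
  u <- spectrum@vectors[, keep, drop = FALSE]
  u %*% (t(u) / spectrum@values[keep])
}

#' Perturbation response scanning
#'
#' Response of residue j to a force applied at residue i, averaged over
#' force directions, from the elastic-network covariance (the Hessian or
#' Kirchhoff pseudoinverse). For an ANM spectrum the mean-square response
#' is the squared Frobenius norm of the 3 x 3 covariance block; rows are
#' normalized by the self-response so PRS(i,i) = 1. Effectiveness of i is
#' the row mean over j != i (how strongly the rest of the protein responds
#' when i is perturbed); sensitivity of j is the column mean over i != j.
#'
#' @param spectrum a \linkS4class{ModeSpectrum} ("anm" preferred; "gnm"
#'   uses the squared scalar covariance).
#' @return list: \code{matrix} (N x N), \code{effectiveness},
#'   \code{sensitivity} (numeric N).
#' @export
prs <- function(spectrum) {
  cov <- .covFromSpectrum(spectrum)
  if (spectrum@kind == "anm") {
    n <- nrow(cov) / 3L
    b <- matrix(0, 3L * n, n)
    b[cbind(seq_len(3L * n), rep(seq_len(n), each = 3L))] <- 1
    p <- t(b) %*% (cov * cov) %*% b   # squared F-norm per 3x3 block
  } else {
    p <- cov * cov
    n <- nrow(p)
  }
  self <- diag(p)
  if (any(self <= 0)) stopf("zero self-response: PRS undefined")
  prsm <- p / self                    # row i normalized by p[i,i]
  diag(prsm) <- 1
  eff <- (rowSums(prsm) - 1) / (n - 1)
  sens <- (colSums(prsm) - 1) / (n - 1)
  list(matrix = prsm, effectiveness = eff, sensitivity = sens)
}

# total compliance (sum of reciprocal nonzero Laplacian eigenvalues) of the
# largest connected component of an adjacency matrix
.largestComponentCompliance <- function(adj, gamma, tol = 1e-8) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < 2L) return(0)
  sub <- adj[keep, keep, drop = FALSE]
  lap <- -gamma * sub
  diag(lap) <- gamma * rowSums(sub)
  ev <- eigen(lap, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > tol * max(ev)]
  sum(1 / ev)
}

#' Mechanical bridging score
#'
#' How much the Laplacian spectrum changes when a node's couplings are
#' deleted: for each node, all incident springs are removed, the total
#' compliance (sum of reciprocal nonzero eigenvalues) is recomputed on the
#' largest remaining component, and the normalized absolute change
#' |c_deleted - c_intact| / c_intact is reported. Nodes whose deletion
#' disconnects the graph are flagged.
#'
#' @param model a \linkS4class{KirchhoffMatrix}.
#' @return data.frame (key, MBS, disconnects).
#' @export
mechanicalBridgingScore <- function(model) {
  m <- model@mat
  attr(m, "components") <- NULL
  adj <- m < 0
  n <- nrow(adj)
  g0 <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp0 <- igraph::components(g0)$no
  c0 <- .largestComponentCompliance(adj, model@gamma)
  if (c0 <= 0) stopf("MBS needs a connected component with at least 2 nodes")
  mbs <- numeric(n)
  disc <- logical(n)
  for (i in seq_len(n)) {
    if (!any(adj[i, ])) { mbs[i] <- 0; next }
    a <- adj
    a[i, ] <- FALSE
    a[, i] <- FALSE
    gi <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    # the deleted node is isolated by construction; extra fragmentation
    # beyond that means the node was an articulation point
    disc[i] <- igraph::components(gi)$no > comp0 + 1L
    ci <- .largestComponentCompliance(a, model@gamma)
    mbs[i] <- abs(ci - c0) / c0
  }
  data.frame(key = model@nodes$key, MBS = mbs, disconnects = disc,
             stringsAsFactors = FALSE)
}

#' Pairwise effective spring constants (stiffness)
#'
#' kappa_ij = [ sum_k lambda_k^-1 ((U_k(j) - U_k(i)) . rhat_ij)^2 ]^-1
#' over the nonzero ANM modes, with rhat_ij the unit vector between the
#' equilibrium positions: the effective force constant resisting a change
#' of the i-j distance. The per-residue stiffness is the row mean over
#' j != i.
#'
#' @param spectrum an ANM \linkS4class{ModeSpectrum}.
#' @return list: \code{matrix} (N x N, NA diagonal), \code{perResidue}
#'   (numeric N).
#' @export
stiffness <- function(spectrum) {
  if (spectrum@kind != "anm") stopf("stiffness requires an ANM spectrum")
  xyz <- spectrum@coords
  n <- nrow(xyz)
  keep <- setdiff(seq_along(spectrum@values), spectrum@zeroModes)
  dx <- outer(xyz[, 1], xyz[, 1], "-")
  dy <- outer(xyz[, 2], xyz[, 2], "-")
  dz <- outer(xyz[, 3], xyz[, 3], "-")
  dd <- sqrt(dx^2 + dy^2 + dz^2)
  coincident <- dd < 1e-9
  diag(coincident) <- TRUE
  if (any(coincident[upper.tri(coincident)]))
    warnf("coincident residue pairs skipped in stiffness")
  dd[coincident] <- NA
  rx <- dx / dd; ry <- dy / dd; rz <- dz / dd
  s <- matrix(0, n, n)
  for (k in keep) {
    uk <- matrix(spectrum@vectors[, k], ncol = 3, byrow = TRUE)
    ax <- outer(uk[, 1], uk[, 1], "-")
    ay <- outer(uk[, 2], uk[, 2], "-")
    az <- outer(uk[, 3], uk[, 3], "-")
    s <- s + (ax * rx + ay * ry + az * rz)^2 / spectrum@values[k]
  }
  kap <- 1 / s
  diag(kap) <- NA
  per <- rowMeans(kap, na.rm = TRUE)
  list(matrix = kap, perResidue = per)
}
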