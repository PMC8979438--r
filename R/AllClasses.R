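# S4 class definitions. All coordinate slots are in Angstrom; residue
# positions are 1-based everywhere a user sees them.

#' SequenceAlignment: an aligned set of protein sequences
#'
#' Rows are equal-length aligned sequences over the 20 amino-acid letters
#' plus the gap character \code{"-"}. One row is designated the reference
#' (query) sequence whose ungapped positions map onto structure residues.
#'
#' @slot ids character, sequence identifiers.
#' @slot chars character matrix (sequences x columns) of single characters.
#' @slot referenceIndex integer, which row is the reference sequence.
#' @export
setClass("SequenceAlignment",
         representation(ids = "character", chars = "matrix",
                        referenceIndex = "integer"))

setValidity("SequenceAlignment", function(object) {
  if (nrow(object@chars) != length(object@ids))
    return("number of ids must equal number of rows")
  if (length(object@referenceIndex) != 1L ||
      object@referenceIndex < 1L || object@referenceIndex > length(object@ids))
    return("referenceIndex out of range")
  bad <- !(object@chars %in% c(AA_ALPHABET20, "-", "X"))
  if (any(bad))
    return(sprintf("non-standard characters in alignment: %s",
                   paste(unique(object@chars[bad]), collapse = ", ")))
  TRUE
})

#' StructureModel: a coarse per-residue protein structure
#'
#' Holds one or two chains of residues, each with a mandatory C-alpha
#' coordinate, an optional C-beta coordinate (absent for glycine) and,
#' when the source file had side chains, all heavy atoms (used for
#' accessible-surface-area computation). Optional per-residue functional
#' domain annotations (active site, interface, ...) travel with the model.
#'
#' @slot residues data.frame with columns chain, position, resid (3-letter),
#'   aa (1-letter), ca.x, ca.y, ca.z, cb.x, cb.y, cb.z (NA when no C-beta).
#' @slot atoms data.frame of heavy atoms (chain, position, elety, element,
#'   x, y, z); may have zero rows for coarse-grained models.
#' @slot annotations named character; names are "chain:position" keys,
#'   values functional-domain labels.
#' @export
setClass("StructureModel",
         representation(residues = "data.frame", atoms = "data.frame",
                        annotations = "character"))

setValidity("StructureModel", function(object) {
  r <- object@residues
  need <- c("chain", "position", "resid", "aa",
            "ca.x", "ca.y", "ca.z", "cb.x", "cb.y", "cb.z")
  if (!all(need %in% names(r)))
    return(sprintf("residues must have columns: %s", paste(need, collapse = ", ")))
  if (any(!is.finite(as.matrix(r[, c("ca.x", "ca.y", "ca.z")]))))
    return("every residue must have a finite C-alpha coordinate")
  for (ch in unique(r$chain)) {
    p <- r$position[r$chain == ch]
    if (any(diff(p) <= 0))
      return(sprintf("residue positions must be strictly increasing in chain %s", ch))
  }
  TRUE
})

#' SyntheticSpec: parameters of the synthetic-data generators
#'
#' A fixed seed makes every generator a pure function of this object:
#' identical spec, identical output bytes.
#'
#' @slot seed integer master seed.
#' @slot nSequences,nColumns alignment dimensions.
#' @slot conservationTargets numeric per-column target entropy (nats),
#'   recycled across columns; each within [0, ln 20].
#' @slot coevolvingPairs data.frame (i, j, coupling) with coupling in [0,1].
#' @slot nResiduesPerChain,nChains structure size (nChains 1 or 2).
#' @slot classEffect named numeric, per-feature standardized mean shift
#'   between the control and severe classes (mild halfway).
#' @slot nMutationsPerClass integer.
#' @slot nFrames integer trajectory length.
#' @slot temperatureScale numeric multiplier on the elastic-network
#'   covariance used when sampling trajectory frames.
#' @export
setClass("SyntheticSpec",
         representation(seed = "integer", nSequences = "integer",
                        nColumns = "integer", conservationTargets = "numeric",
                        coevolvingPairs = "data.frame",
                        nResiduesPerChain = "integer", nChains = "integer",
                        classEffect = "numeric",
                        nMutationsPerClass = "integer", nFrames = "integer",
                        temperatureScale = "numeric"))

setValidity("SyntheticSpec", function(object) {
  if (any(object@conservationTargets < 0 |
          object@conservationTargets > log(20) + 1e-12))
    return("conservationTargets must lie within [0, ln 20]")
  if (nrow(object@coevolvingPairs) &&
      (any(object@coevolvingPairs$coupling < 0) ||
       any(object@coevolvingPairs$coupling > 1)))
    return("coupling must lie within [0, 1]")
  if (!object@nChains %in% c(1L, 2L)) return("nChains must be 1 or 2")
  TRUE
})

#' ContactCountTable: observed and reference residue-type contact counts
#'
#' Symmetric counts over the 20 residue types plus a solvent class
#' (labelled \code{"0"}), together with reference counts from a stated
#' random-mixing model. Feeds the contact-energy formula.
#'
#' @slot observed,reference symmetric 21 x 21 numeric matrices with
#'   dimnames \code{c("0", AA_ALPHABET20)}.
#' @export
setClass("ContactCountTable",
         representation(observed = "matrix", reference = "matrix"))

setValidity("ContactCountTable", function(object) {
  for (nm in c("observed", "reference")) {
    m <- slot(object, nm)
    if (!identical(dim(m), c(21L, 21L))) return(sprintf("%s must be 21 x 21", nm))
    if (any(m < 0)) return(sprintf("%s must be nonnegative", nm))
    if (max(abs(m - t(m))) > 1e-9) return(sprintf("%s must be symmetric", nm))
  }
  TRUE
})

#' ResidueNetwork: a weighted residue interaction graph
#'
#' Nodes are residues (chain, position, type); undirected edges carry the
#' environment-dependent contact energy of the incident residue types (or a
#' distance-rule indicator for dynamic networks).
#'
#' @slot graph an igraph object; vertex names are "chain:position" keys.
#' @slot nodes data.frame (chain, position, aa, key) in vertex order.
#' @slot contactDef list recording the contact rule actually used.
#' @export
setClass("ResidueNetwork",
         representation(graph = "ANY", nodes = "data.frame",
                        contactDef = "list"))

setValidity("ResidueNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::is_directed(g)) return("network must be undirected")
  if (any(igraph::which_loop(g))) return("self-edges are not allowed")
  if (igraph::vcount(g) != nrow(object@nodes))
    return("nodes table must match vertex count")
  TRUE
})

#' ModeSpectrum: eigen-decomposition of an elastic-network matrix
#'
#' Eigenvalues ascending, orthonormal eigenvectors, and explicit zero-mode
#' bookkeeping (1 zero mode per connected component for a Kirchhoff matrix,
#' 6 for a connected 3-D Hessian). The kBT/gamma scale multiplies
#' fluctuation predictions.
#'
#' @slot values numeric eigenvalues, ascending.
#' @slot vectors numeric matrix of eigenvectors (columns match values).
#' @slot zeroModes integer indices of the zero modes.
#' @slot kind "gnm" or "anm".
#' @slot scale numeric kBT/gamma factor (default 1).
#' @slot coords N x 3 matrix of node coordinates (needed by ANM features).
#' @export
setClass("ModeSpectrum",
         representation(values = "numeric", vectors = "matrix",
                        zeroModes = "integer", kind = "character",
                        scale = "numeric", coords = "matrix"))

setValidity("ModeSpectrum", function(object) {
  if (!object@kind %in% c("gnm", "anm")) return("kind must be 'gnm' or 'anm'")
  if (is.unsorted(object@values + 1e-12)) return("eigenvalues must be ascending")
  n <- length(object@values)
  if (!identical(dim(object@vectors), c(n, n)))
    return("vectors must be square and match values")
  TRUE
})

#' TrajectoryEnsemble: frames of per-residue representative coordinates
#'
#' @slot ca numeric array (frames x residues x 3) of C-alpha coordinates.
#' @slot cb numeric array (frames x residues x 3) of C-beta coordinates
#'   (NA for glycine).
#' @slot residues data.frame matching \linkS4class{StructureModel} residues.
#' @slot source character tag ("synthetic" or "imported").
#' @export
setClass("TrajectoryEnsemble",
         representation(ca = "array", cb = "array",
                        residues = "data.frame", source = "character"))

setValidity("TrajectoryEnsemble", function(object) {
  if (length(dim(object@ca)) != 3L || dim(object@ca)[3] != 3L)
    return("ca must be a frames x residues x 3 array")
  if (dim(object@ca)[1] < 2L) return("a trajectory needs at least 2 frames")
  if (!identical(dim(object@ca), dim(object@cb)))
    return("ca and cb arrays must agree in shape")
  if (dim(object@ca)[2] != nrow(object@residues))
    return("residue table must match coordinate arrays")
  TRUE
})

#' DynamicResidueNetwork: per-frame contact graphs and their consensus
#'
#' Per-frame residue graphs (nodes C-beta, C-alpha for glycine; edge iff
#' distance at most the cutoff) plus a consensus graph retaining edges whose
#' occupancy fraction reaches a threshold.
#'
#' @slot frameEdges list of 2-column integer matrices (edges per frame,
#'   vertex indices).
#' @slot occupancy symmetric numeric matrix of per-pair edge occupancy.
#' @slot consensus an igraph consensus graph.
#' @slot nodes data.frame (chain, position, aa, key).
#' @slot cutoff,threshold numeric parameters actually used.
#' @export
setClass("DynamicResidueNetwork",
         representation(frameEdges = "list", occupancy = "matrix",
                        consensus = "ANY", nodes = "data.frame",
                        cutoff = "numeric", threshold = "numeric"))

setValidity("DynamicResidueNetwork", function(object) {
  if (any(object@occupancy < 0 | object@occupancy > 1))
    return("occupancy must lie within [0, 1]")
  TRUE
})

#' FeatureTable: mutations by named molecular signatures
#'
#' The pipeline's central exchange object: one row per mutation (identity =
#' wt_aa, position, mut_aa, chain), columns drawn from the registered
#' feature vocabulary. Missing values are explicit NAs, never silent zeros;
#' each column records whether it was computed here or imported.
#'
#' @slot mutations data.frame (wt_aa, position, mut_aa, chain, phenotype).
#' @slot values data.frame of numeric feature columns.
#' @slot provenance named character, "computed" or "imported" per column.
#' @export
setClass("FeatureTable",
         representation(mutations = "data.frame", values = "data.frame",
                        provenance = "character"))

setValidity("FeatureTable", function(object) {
  m <- object@mutations
  need <- c("wt_aa", "position", "mut_aa", "chain", "phenotype")
  if (!all(need %in% names(m)))
    return(sprintf("mutations must have columns: %s", paste(need, collapse = ", ")))
  key <- paste(m$chain, m$position, m$wt_aa, m$mut_aa)
  if (anyDuplicated(key)) return("duplicated mutation keys")
  if (nrow(object@values) != nrow(m))
    return("values must have one row per mutation")
  if (!all(names(object@values) %in% FEATURE_VOCABULARY))
    return(sprintf("unregistered feature columns: %s",
                   paste(setdiff(names(object@values), FEATURE_VOCABULARY),
                         collapse = ", ")))
  if (!all(vapply(object@values, is.numeric, logical(1))))
    return("all feature columns must be numeric")
  if (length(object@provenance) &&
      !all(object@provenance %in% c("computed", "imported")))
    return("provenance entries must be 'computed' or 'imported'")
  TRUE
})

#' PathResult: one shortest residue path with annotations
#'
#' @slot nodes character vector of "chain:position" keys, source to target.
#' @slot hops integer, number of edges.
#' @slot annotations named character, functional-domain label per node key.
#' @slot provenance list (network type, cutoff, threshold, weighting).
#' @export
setClass("PathResult",
         representation(nodes = "character", hops = "integer",
                        annotations = "character", provenance = "list"))

setValidity("PathResult", function(object) {
  if (anyDuplicated(object@nodes)) return("a path must not repeat nodes")
  if (object@hops != length(object@nodes) - 1L)
    return("hops must equal number of nodes minus 1")
  TRUE
})
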