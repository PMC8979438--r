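# Generics, accessors and show methods.

#' @rdname FeatureTable-class
#' @param object a FeatureTable
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname FeatureTable-class
#' @export
setMethod("featureValues", "FeatureTable", function(object) object@values)

#' @rdname FeatureTable-class
#' @export
setGeneric("mutationInfo", function(object) standardGeneric("mutationInfo"))

#' @rdname FeatureTable-class
#' @export
setMethod("mutationInfo", "FeatureTable", function(object) object@mutations)

#' @rdname FeatureTable-class
#' @export
setGeneric("featureProvenance",
           function(object) standardGeneric("featureProvenance"))

#' @rdname FeatureTable-class
#' @export
setMethod("featureProvenance", "FeatureTable",
          function(object) object@provenance)

#' @rdname SequenceAlignment-class
#' @param object a SequenceAlignment
#' @export
setGeneric("alignmentMatrix", function(object) standardGeneric("alignmentMatrix"))

#' @rdname SequenceAlignment-class
#' @export
setMethod("alignmentMatrix", "SequenceAlignment", function(object) object@chars)

#' @rdname SequenceAlignment-class
#' @export
setGeneric("referenceRow", function(object) standardGeneric("referenceRow"))

#' @rdname SequenceAlignment-class
#' @export
setMethod("referenceRow", "SequenceAlignment",
          function(object) object@chars[object@referenceIndex, ])

#' @rdname StructureModel-class
#' @param object a StructureModel
#' @export
setGeneric("residueTable", function(object) standardGeneric("residueTable"))

#' @rdname StructureModel-class
#' @export
setMethod("residueTable", "StructureModel", function(object) object@residues)

#' @rdname StructureModel-class
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))

#' @rdname StructureModel-class
#' @export
setMethod("atomTable", "StructureModel", function(object) object@atoms)

#' @rdname ResidueNetwork-class
#' @param object a ResidueNetwork
#' @export
setGeneric("networkGraph", function(object) standardGeneric("networkGraph"))

#' @rdname ResidueNetwork-class
#' @export
setMethod("networkGraph", "ResidueNetwork", function(object) object@graph)

#' @rdname ModeSpectrum-class
#' @param object a ModeSpectrum
#' @export
setGeneric("eigenValues", function(object) standardGeneric("eigenValues"))

#' @rdname ModeSpectrum-class
#' @export
setMethod("eigenValues", "ModeSpectrum", function(object) object@values)

#' @rdname ModeSpectrum-class
#' @export
setGeneric("zeroModes", function(object) standardGeneric("zeroModes"))

#' @rdname ModeSpectrum-class
#' @export
setMethod("zeroModes", "ModeSpectrum", function(object) object@zeroModes)

#' @rdname PathResult-class
#' @param object a PathResult
#' @export
setGeneric("pathNodes", function(object) standardGeneric("pathNodes"))

#' @rdname PathResult-class
#' @export
setMethod("pathNodes", "PathResult", function(object) object@nodes)

setMethod("show", "SequenceAlignment", function(object) {
  cat(sprintf("SequenceAlignment: %d sequences x %d columns (reference: %s)\n",
              nrow(object@chars), ncol(object@chars),
              object@ids[object@referenceIndex]))
})

setMethod("show", "StructureModel", function(object) {
  r <- object@residues
  tab <- table(r$chain)
  cat(sprintf("StructureModel: %d residues in %d chain(s) [%s]; %d heavy atoms\n",
              nrow(r), length(tab),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", "),
              nrow(object@atoms)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: seed %d; MSA %d x %d; %d chain(s) x %d ",
                     "residues; %d mutations/class; %d frames\n"),
              object@seed, object@nSequences, object@nColumns, object@nChains,
              object@nResiduesPerChain, object@nMutationsPerClass,
              object@nFrames))
})

setMethod("show", "ResidueNetwork", function(object) {
  cat(sprintf("ResidueNetwork: %d nodes, %d edges (%s)\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              paste(names(object@contactDef),
                    unlist(lapply(object@contactDef, format)),
                    sep = "=", collapse = ", ")))
})

setMethod("show", "ModeSpectrum", function(object) {
  cat(sprintf("ModeSpectrum (%s): %d modes, %d zero mode(s), scale %.3g\n",
              object@kind, length(object@values), length(object@zeroModes),
              object@scale))
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat(sprintf("TrajectoryEnsemble (%s): %d frames x %d residues\n",
              object@source, dim(object@ca)[1], dim(object@ca)[2]))
})

setMethod("show", "DynamicResidueNetwork", function(object) {
  cat(sprintf(paste0("DynamicResidueNetwork: %d frames, %d nodes, cutoff ",
                     "%.2f A, consensus occupancy >= %.2f (%d edges)\n"),
              length(object@frameEdges), nrow(object@nodes), object@cutoff,
              object@threshold, igraph::ecount(object@consensus)))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d mutations x %d features [%s]\n",
              nrow(object@mutations), ncol(object@values),
              paste(names(object@values), collapse = ", ")))
  print(table(object@mutations$phenotype))
})

setMethod("show", "PathResult", function(object) {
  cat(sprintf("PathResult: %d hops: %s\n", object@hops,
              paste(object@nodes, collapse = " -> ")))
})

setMethod("show", "ContactCountTable", function(object) {
  cat(sprintf("ContactCountTable: %d observed contacts (incl. solvent class)\n",
              round(sum(object@observed[upper.tri(object@observed, diag = TRUE)]))))
})
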