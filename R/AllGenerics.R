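#' Accessor generics
#'
#' `mirnaIds()` and `diseaseIds()` return the entity registries of a
#' container; `entityIds()` the registry of a similarity matrix;
#' `fittedMatrix()`, `solverTrace()` and `isConverged()` expose the solver
#' result without touching slots.
#'
#' @param x an object of the relevant class.
#' @return character vector of ids, or the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mirnaIds", function(x) standardGeneric("mirnaIds"))
#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))
#' @rdname accessors
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))
#' @rdname accessors
#' @export
setGeneric("fittedMatrix", function(x) standardGeneric("fittedMatrix"))
#' @rdname accessors
#' @export
setGeneric("solverTrace", function(x) standardGeneric("solverTrace"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setMethod("mirnaIds", "AssociationMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("diseaseIds", "AssociationMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("mirnaIds", "HeteroNetwork", function(x) x@mirnas)
#' @rdname accessors
#' @export
setMethod("diseaseIds", "HeteroNetwork", function(x) x@diseases)
#' @rdname accessors
#' @export
setMethod("mirnaIds", "MDADataset", function(x) mirnaIds(x@associations))
#' @rdname accessors
#' @export
setMethod("diseaseIds", "MDADataset", function(x) diseaseIds(x@associations))
#' @rdname accessors
#' @export
setMethod("entityIds", "SimilarityMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("fittedMatrix", "BNNRFit", function(x) x@Z)
#' @rdname accessors
#' @export
setMethod("solverTrace", "BNNRFit", function(x) x@trace)
#' @rdname accessors
#' @export
setMethod("isConverged", "BNNRFit", function(x) x@converged)

#' Coerce containers to a base matrix
#'
#' @param x a `SimilarityMatrix`, `AssociationMatrix` or `HeteroNetwork`.
#' @param ... ignored.
#' @return the underlying numeric matrix (with dimnames).
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@values)
#' @rdname as.matrix-SimilarityMatrix-method
#' @export
setMethod("as.matrix", "AssociationMatrix", function(x, ...) x@values)
#' @rdname as.matrix-SimilarityMatrix-method
#' @export
setMethod("as.matrix", "HeteroNetwork", function(x, ...) x@W)

#' @export
setMethod("dim", "AssociationMatrix", function(x) dim(x@values))

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s, %s): %d x %d\n", object@axis, object@kind,
              nrow(object@values), ncol(object@values)))
  offd <- object@values[upper.tri(object@values)]
  if (length(offd))
    cat(sprintf("  off-diagonal range [%.4f, %.4f], mean %.4f\n",
                min(offd), max(offd), mean(offd)))
})

setMethod("show", "AssociationMatrix", function(object) {
  v <- object@values
  cat(sprintf("AssociationMatrix: %d miRNAs x %d diseases, %d associations (density %.3f)\n",
              nrow(v), ncol(v), sum(v), mean(v)))
})

setMethod("show", "DiseaseDAG", function(object) {
  nEdge <- sum(lengths(object@parents))
  cat(sprintf("DiseaseDAG: %d diseases, %d child->parent edges\n",
              length(object@ids), nEdge))
})

setMethod("show", "GeneNet", function(object) {
  cat(sprintf("GeneNet: %d genes, %d scored pairs, raw LLS range [%.3g, %.3g]\n",
              length(object@genes), length(object@scores@x) / 2,
              object@range[1], object@range[2]))
})

setMethod("show", "HeteroNetwork", function(object) {
  cat(sprintf("HeteroNetwork: side %d (%d miRNAs + %d diseases), %d observed entries\n",
              nrow(object@W), length(object@mirnas), length(object@diseases),
              sum(object@mask)))
})

setMethod("show", "BNNRFit", function(object) {
  tr <- object@trace
  cat(sprintf("BNNRFit: %d iterations, %s (final relChange %.2e, gap %.2e)\n",
              object@iterations,
              if (object@converged) "converged" else "NOT converged",
              tr$relChange[nrow(tr)], tr$gap[nrow(tr)]))
})

setMethod("show", "MDADataset", function(object) {
  v <- object@associations@values
  cat(sprintf("MDADataset: %d miRNAs x %d diseases, %d associations; %d genes in network\n",
              nrow(v), ncol(v), sum(v), length(object@geneNet@genes)))
})
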