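#' @importFrom methods new validObject setClass setGeneric setMethod is slot
#' @importClassesFrom Matrix dgCMatrix
NULL

## Tolerances used by validity methods. Similarity matrices are constructed,
## not measured, so these are tight.
.SYM_TOL  <- 1e-12
.BOX_TOL  <- 1e-12

#' SimilarityMatrix: square symmetric unit-diagonal matrix in [0, 1]
#'
#' Container for disease or microRNA similarity. The entity registry lives in
#' the dimnames; `axis` records which side of the association matrix it
#' describes and `kind` its provenance (semantic, functional, gapk or fused).
#'
#' @slot values numeric matrix with identical row/column names.
#' @slot axis `"disease"` or `"miRNA"`.
#' @slot kind one of `"semantic"`, `"functional"`, `"gapk"`, `"fused"`.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(values = "matrix", axis = "character", kind = "character"),
  validity = function(object) {
    v <- object@values
    msgs <- character()
    if (nrow(v) != ncol(v)) msgs <- c(msgs, "matrix must be square")
    ids <- rownames(v)
    if (is.null(ids) || is.null(colnames(v)) || !identical(ids, colnames(v)))
      msgs <- c(msgs, "row and column names must be present and identical")
    if (!is.null(ids) && anyDuplicated(ids)) msgs <- c(msgs, "entity ids must be unique")
    if (!object@axis %in% c("disease", "miRNA"))
      msgs <- c(msgs, "axis must be 'disease' or 'miRNA'")
    if (!object@kind %in% c("semantic", "functional", "gapk", "fused"))
      msgs <- c(msgs, "kind must be semantic/functional/gapk/fused")
    if (length(v) > 0) {
      if (maxAsymmetry(v) > .SYM_TOL) msgs <- c(msgs, "matrix must be symmetric")
      if (max(abs(diag(v) - 1)) > .BOX_TOL) msgs <- c(msgs, "diagonal must be 1")
      if (min(v) < -.BOX_TOL || max(v) > 1 + .BOX_TOL)
        msgs <- c(msgs, "entries must lie in [0, 1]")
    }
    if (length(msgs)) msgs else TRUE
  })

#' Construct a SimilarityMatrix
#'
#' @param values square numeric matrix.
#' @param ids character vector of entity ids; defaults to `rownames(values)`.
#' @param axis `"disease"` or `"miRNA"`.
#' @param kind provenance tag: `"semantic"`, `"functional"`, `"gapk"` or `"fused"`.
#' @return a validated [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(values, ids = rownames(values), axis, kind) {
  values <- as.matrix(values)
  if (is.null(ids)) stop("entity ids are required")
  dimnames(values) <- list(ids, ids)
  new("SimilarityMatrix", values = values, axis = axis, kind = kind)
}

#' AssociationMatrix: binary miRNA x disease supervision matrix
#'
#' Rows are microRNAs, columns diseases; a 1 records a curated association.
#' Row/column profiles of this matrix are the inputs to the Gaussian
#' association-profile kernel.
#'
#' @slot values binary numeric matrix with miRNA rownames, disease colnames.
#' @exportClass AssociationMatrix
setClass("AssociationMatrix",
  representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    msgs <- character()
    if (is.null(rownames(v)) || is.null(colnames(v)))
      msgs <- c(msgs, "miRNA rownames and disease colnames are required")
    if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
      msgs <- c(msgs, "duplicate miRNA ids")
    if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
      msgs <- c(msgs, "duplicate disease ids")
    if (length(v) && !all(v %in% c(0, 1)))
      msgs <- c(msgs, "entries must be 0 or 1")
    if (length(msgs)) msgs else TRUE
  })

#' Construct an AssociationMatrix
#'
#' @param values binary matrix (miRNA rows, disease columns), or a two-column
#'   data frame of `(mirna_id, disease_id)` pairs when `mirnas`/`diseases`
#'   registries are given.
#' @param mirnas,diseases optional id registries used when `values` is a pair
#'   table; absent pairs become 0.
#' @return a validated [AssociationMatrix-class] object.
#' @export
AssociationMatrix <- function(values, mirnas = NULL, diseases = NULL) {
  if (is.data.frame(values)) {
    if (is.null(mirnas)) mirnas <- sort(unique(as.character(values[[1]])))
    if (is.null(diseases)) diseases <- sort(unique(as.character(values[[2]])))
    X <- matrix(0, length(mirnas), length(diseases),
                dimnames = list(mirnas, diseases))
    keep <- values[[1]] %in% mirnas & values[[2]] %in% diseases
    X[cbind(as.character(values[[1]][keep]), as.character(values[[2]][keep]))] <- 1
    values <- X
  } else {
    values <- as.matrix(values)
  }
  new("AssociationMatrix", values = values)
}

#' DiseaseDAG: ancestor structure derived from tree numbers
#'
#' Stores, for every disease, its direct parents (child-to-parent edges of the
#' hierarchy), the full ancestor set (the disease itself plus everything
#' reachable upward), and its tree numbers.
#'
#' @slot ids disease identifiers.
#' @slot parents named list: disease -> character vector of direct parents.
#' @slot ancestors named list: disease -> ancestor set including itself.
#' @slot treeNumbers named list: disease -> its tree numbers.
#' @exportClass DiseaseDAG
setClass("DiseaseDAG",
  representation(ids = "character", parents = "list", ancestors = "list",
                 treeNumbers = "list"),
  validity = function(object) {
    msgs <- character()
    ids <- object@ids
    if (anyDuplicated(ids)) msgs <- c(msgs, "duplicate disease ids")
    if (!setequal(names(object@parents), ids) ||
        !setequal(names(object@ancestors), ids))
      msgs <- c(msgs, "parents/ancestors must be keyed by the id registry")
    for (d in ids) {
      if (!d %in% object@ancestors[[d]]) {
        msgs <- c(msgs, sprintf("'%s' missing from its own ancestor set", d))
        break
      }
    }
    ## acyclicity: no disease may be a strict ancestor of itself
    for (d in ids) {
      anc <- setdiff(object@ancestors[[d]], d)
      for (a in anc) {
        if (d %in% object@ancestors[[a]] && a != d) {
          msgs <- c(msgs, sprintf("cycle involving '%s' and '%s'", d, a))
          break
        }
      }
    }
    if (length(msgs)) msgs else TRUE
  })

#' GeneNet: normalized gene-gene functional linkage network
#'
#' Symmetric sparse matrix of log-likelihood scores rescaled to [0, 1] by the
#' global minimum/maximum of the raw input network.
#'
#' @slot genes gene id registry.
#' @slot scores symmetric `dgCMatrix` of normalized scores (diagonal unused).
#' @slot range numeric length-2: raw (min, max) log-likelihood scores.
#' @exportClass GeneNet
setClass("GeneNet",
  representation(genes = "character", scores = "dgCMatrix", range = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (anyDuplicated(object@genes)) msgs <- c(msgs, "duplicate gene ids")
    s <- object@scores
    if (nrow(s) != length(object@genes) || ncol(s) != length(object@genes))
      msgs <- c(msgs, "score matrix must match the gene registry")
    if (length(s@x) && (min(s@x) < -.BOX_TOL || max(s@x) > 1 + .BOX_TOL))
      msgs <- c(msgs, "normalized scores must lie in [0, 1]")
    if (length(s@x) && maxAsymmetry(as.matrix(s)) > .SYM_TOL)
      msgs <- c(msgs, "score matrix must be symmetric")
    if (length(object@range) != 2 || object@range[1] >= object@range[2])
      msgs <- c(msgs, "raw score range must be (min, max) with min < max")
    if (length(msgs)) msgs else TRUE
  })

#' HeteroNetwork: block adjacency matrix of the heterogeneous network
#'
#' The (m+n) x (m+n) matrix `[[SM, X], [t(X), SD]]` together with the mask of
#' observed entries: similarity blocks are fully observed, association blocks
#' only at their 1-entries.
#'
#' @slot W numeric matrix of side m+n.
#' @slot mask logical matrix, `TRUE` where the entry is observed.
#' @slot mirnas,diseases id registries for the two blocks.
#' @exportClass HeteroNetwork
setClass("HeteroNetwork",
  representation(W = "matrix", mask = "matrix", mirnas = "character",
                 diseases = "character"),
  validity = function(object) {
    msgs <- character()
    side <- length(object@mirnas) + length(object@diseases)
    if (!all(dim(object@W) == side)) msgs <- c(msgs, "W has the wrong side")
    if (!identical(dim(object@W), dim(object@mask)))
      msgs <- c(msgs, "mask shape must match W")
    if (!is.logical(object@mask)) msgs <- c(msgs, "mask must be logical")
    if (length(object@W)) {
      if (maxAsymmetry(object@W) > 0) msgs <- c(msgs, "W must be exactly symmetric")
      if (any(object@mask != t(object@mask))) msgs <- c(msgs, "mask must be symmetric")
      if (min(object@W) < 0 || max(object@W) > 1)
        msgs <- c(msgs, "W entries must lie in [0, 1]")
    }
    if (length(msgs)) msgs else TRUE
  })

#' BNNRFit: result of the bounded nuclear-norm completion
#'
#' @slot Z completed matrix (entries clipped to [0, 1] by the solver).
#' @slot iterations number of ADMM iterations performed.
#' @slot trace data.frame with per-iteration `iter`, `relChange`
#'   (relative Frobenius change of Z) and `gap` (relative Y - Z residual).
#' @slot converged TRUE if both residuals fell below the tolerance.
#' @exportClass BNNRFit
setClass("BNNRFit",
  representation(Z = "matrix", iterations = "integer", trace = "data.frame",
                 converged = "logical"),
  validity = function(object) {
    msgs <- character()
    if (length(object@Z)) {
      if (min(object@Z) < -1e-9 || max(object@Z) > 1 + 1e-9)
        msgs <- c(msgs, "completed entries must lie in [0, 1] within 1e-9")
    }
    if (!all(c("iter", "relChange", "gap") %in% names(object@trace)))
      msgs <- c(msgs, "trace must have iter/relChange/gap columns")
    if (length(msgs)) msgs else TRUE
  })

#' MDADataset: validated bundle of the four inputs
#'
#' Holds the filtered association matrix plus the structures derived from the
#' three side inputs. Construction applies the upstream filtering rule: a
#' microRNA without target genes, or a disease without a hierarchy position,
#' is removed along with its associations.
#'
#' @slot associations an [AssociationMatrix-class].
#' @slot dag a [DiseaseDAG-class] over (at least) the matrix diseases.
#' @slot geneNet a [GeneNet-class].
#' @slot targets named list: miRNA id -> character vector of target genes.
#' @slot provenance list of file paths / row counts recorded at load time.
#' @exportClass MDADataset
setClass("MDADataset",
  representation(associations = "AssociationMatrix", dag = "DiseaseDAG",
                 geneNet = "GeneNet", targets = "list", provenance = "list"),
  validity = function(object) {
    msgs <- character()
    m <- rownames(object@associations@values)
    d <- colnames(object@associations@values)
    noTarget <- m[!vapply(object@targets[m], function(g) length(g) > 0, logical(1))]
    if (length(noTarget))
      msgs <- c(msgs, sprintf("miRNAs without targets: %s",
                              paste(noTarget, collapse = ", ")))
    missing <- setdiff(d, object@dag@ids)
    if (length(missing))
      msgs <- c(msgs, sprintf("diseases without hierarchy: %s",
                              paste(missing, collapse = ", ")))
    if (length(msgs)) msgs else TRUE
  })
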