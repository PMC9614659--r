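## Similarity layer: disease semantic similarity from the hierarchy DAG,
## microRNA functional similarity from the gene network, Gaussian
## association-profile kernels, and the convex fusion of the two per side.

#' Build the disease hierarchy DAG from tree-number records
#'
#' Tree numbers are dot-delimited hierarchy positions (MeSH dialect, e.g.
#' `C04.588.274`). The parent of the disease holding `p.q` is the disease
#' holding `p`; a disease with several tree numbers contributes the union of
#' its ancestor chains. Prefixes owned by no disease simply terminate the
#' chain.
#'
#' @param records data.frame (or list of pairs) with columns `disease_id`,
#'   `tree_number`.
#' @return a [DiseaseDAG-class] whose ancestor sets include each disease
#'   itself.
#' @examples
#' dag <- buildDiseaseDAG(data.frame(disease_id = c("d1", "d2"),
#'                                   tree_number = c("C04", "C04.100")))
#' @export
buildDiseaseDAG <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (ncol(records) < 2) stop("need columns disease_id, tree_number")
  dis <- as.character(records[[1]])
  tn  <- as.character(records[[2]])
  bad <- dis[is.na(tn) | !nzchar(tn)]
  if (length(bad))
    stop(sprintf("disease without tree number: %s",
                 paste(unique(bad), collapse = ", ")))
  ids <- unique(dis)
  owner <- split(dis, tn)          # tree number -> owning disease ids
  treeNumbers <- lapply(split(tn, dis), unique)[ids]

  parents <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(tn)) {
    parts <- strsplit(tn[i], ".", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    parentTn <- paste(parts[-length(parts)], collapse = ".")
    p <- owner[[parentTn]]
    if (!is.null(p)) {
      p <- setdiff(unique(p), dis[i])    # a disease is never its own parent
      parents[[dis[i]]] <- union(parents[[dis[i]]], p)
    }
  }
  parents <- lapply(parents, function(p) if (is.null(p)) character() else p)

  ## ancestor closure with cycle detection (DFS with colouring)
  ancestors <- stats::setNames(vector("list", length(ids)), ids)
  state <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
  visit <- function(d) {
    if (state[[d]] == 1L)
      stop(sprintf("cyclic hierarchy detected at '%s' (colliding tree numbers)", d))
    if (state[[d]] == 2L) return(ancestors[[d]])
    state[[d]] <<- 1L
    anc <- d
    for (p in parents[[d]]) anc <- union(anc, visit(p))
    ancestors[[d]] <<- anc
    state[[d]] <<- 2L
    anc
  }
  for (d in ids) visit(d)

  new("DiseaseDAG", ids = ids, parents = parents, ancestors = ancestors,
      treeNumbers = treeNumbers)
}

## children of each node restricted to the sub-DAG spanned by `nodes`
.dagChildrenWithin <- function(dag, nodes) {
  kids <- stats::setNames(vector("list", length(nodes)), nodes)
  for (d in nodes) {
    for (p in intersect(dag@parents[[d]], nodes)) {
      kids[[p]] <- c(kids[[p]], d)
    }
  }
  kids
}

#' Semantic contribution of ancestors to a disease
#'
#' The disease contributes 1 to itself; each ancestor `t` contributes
#' `delta` times the largest contribution among its children inside the
#' disease's own sub-DAG, so contributions decay geometrically along ancestor
#' chains (with the max rule resolving multiple paths).
#'
#' @param dag a [DiseaseDAG-class].
#' @param disease a disease id in the DAG.
#' @param delta decay factor in (0, 1]; default 0.5.
#' @return named numeric vector `D_d(t)` over the ancestor set of `disease`.
#' @export
semanticContribution <- function(dag, disease, delta = 0.5) {
  stopIfNotScalar(delta, "delta", lower = 1e-12, upper = 1)
  if (!disease %in% dag@ids)
    stop(sprintf("unknown disease id '%s'", disease))
  Td <- dag@ancestors[[disease]]
  D <- stats::setNames(rep(NA_real_, length(Td)), Td)
  D[[disease]] <- 1
  kids <- .dagChildrenWithin(dag, Td)
  ## fixed-point upward propagation; acyclicity bounds the passes by |Td|
  for (pass in seq_along(Td)) {
    changed <- FALSE
    for (t in Td) {
      if (t == disease) next
      ch <- kids[[t]]
      vals <- D[ch]
      if (length(vals) && !anyNA(vals)) {
        cand <- delta * max(vals)
        if (is.na(D[[t]]) || abs(D[[t]] - cand) > 0) {
          if (!identical(D[[t]], cand)) changed <- TRUE
          D[[t]] <- cand
        }
      }
    }
    if (!changed) break
  }
  if (anyNA(D))
    stop(sprintf("contribution table incomplete for '%s' (disconnected ancestor?)",
                 disease))
  D
}

#' Disease semantic similarity from shared ancestors
#'
#' Pairwise similarity is the summed contribution of shared ancestors from
#' both sides, normalized by the two total semantic values:
#' `sum_{t in Ti ∩ Tj} (Di(t) + Dj(t)) / (sum Di + sum Dj)`.
#'
#' @param dag a [DiseaseDAG-class].
#' @param diseases character vector of disease ids (all in the DAG).
#' @param delta decay factor, see [semanticContribution()].
#' @return a [SimilarityMatrix-class] tagged `disease`/`semantic`.
#' @export
diseaseSemanticSimilarity <- function(dag, diseases = dag@ids, delta = 0.5) {
  if (length(diseases) == 0) stop("empty disease list")
  missing <- setdiff(diseases, dag@ids)
  if (length(missing))
    stop(sprintf("unknown disease id(s): %s", paste(missing, collapse = ", ")))
  contrib <- lapply(diseases, semanticContribution, dag = dag, delta = delta)
  names(contrib) <- diseases
  total <- vapply(contrib, sum, numeric(1))
  n <- length(diseases)
  S <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      Di <- contrib[[i]]
      for (j in (i + 1):n) {
        Dj <- contrib[[j]]
        shared <- intersect(names(Di), names(Dj))
        S[i, j] <- S[j, i] <-
          if (length(shared)) sum(Di[shared] + Dj[shared]) / (total[i] + total[j]) else 0
      }
    }
  }
  SimilarityMatrix(S, ids = diseases, axis = "disease", kind = "semantic")
}

#' Normalize a raw gene-gene log-likelihood network to [0, 1]
#'
#' Min-max rescaling by the global extremes of the full input network
#' (computed once, before any subsetting): the pair with the largest raw
#' score maps to 1, the smallest to 0.
#'
#' @param records data.frame with columns `gene_a`, `gene_b`, `lls`.
#' @return a [GeneNet-class].
#' @export
normalizeLLS <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (ncol(records) < 3) stop("need columns gene_a, gene_b, lls")
  ga <- as.character(records[[1]]); gb <- as.character(records[[2]])
  lls <- as.numeric(records[[3]])
  if (anyNA(lls)) stop("non-numeric LLS value in gene network")
  lo <- min(lls); hi <- max(lls)
  if (hi <= lo)
    stop("degenerate LLS range: all raw scores equal, cannot min-max normalize")
  norm <- (lls - lo) / (hi - lo)
  genes <- sort(unique(c(ga, gb)))
  i <- match(ga, genes); j <- match(gb, genes)
  keep <- i != j                      # self-pairs carry no information (Sg=1 anyway)
  S <- Matrix::sparseMatrix(i = c(i[keep], j[keep]), j = c(j[keep], i[keep]),
                            x = rep(norm[keep], 2), dims = c(length(genes), length(genes)),
                            dimnames = list(genes, genes),
                            use.last.ij = TRUE)
  new("GeneNet", genes = genes, scores = methods::as(S, "CsparseMatrix"),
      range = c(lo, hi))
}

#' Pairwise gene similarity
#'
#' 1 for identical genes; the normalized log-likelihood score when the pair is
#' an edge of the network; 0 otherwise (including genes absent from the
#' network).
#'
#' @param net a [GeneNet-class].
#' @param geneA,geneB gene ids.
#' @return similarity in [0, 1].
#' @export
geneSimilarity <- function(net, geneA, geneB) {
  if (geneA == geneB) return(1)
  i <- match(geneA, net@genes); j <- match(geneB, net@genes)
  if (is.na(i) || is.na(j)) return(0)
  as.numeric(net@scores[i, j])
}

## dense gene-similarity block over two gene sets (identity on the diagonal
## pairs), used by the best-match-average below
.geneSimBlock <- function(net, gsA, gsB) {
  S <- matrix(0, length(gsA), length(gsB), dimnames = list(gsA, gsB))
  ia <- match(gsA, net@genes); ib <- match(gsB, net@genes)
  okA <- !is.na(ia); okB <- !is.na(ib)
  if (any(okA) && any(okB))
    S[okA, okB] <- as.matrix(net@scores[ia[okA], ib[okB], drop = FALSE])
  same <- outer(gsA, gsB, "==")
  S[same] <- 1
  S
}

#' MicroRNA functional similarity (best match average)
#'
#' For microRNAs with target gene sets `Gi`, `Gj`, each gene of one set is
#' matched to its most similar gene in the other set and the two directional
#' sums are averaged:
#' `[sum_{g in Gi} S(g, Gj) + sum_{g in Gj} S(g, Gi)] / (|Gi| + |Gj|)`.
#'
#' @param net a [GeneNet-class].
#' @param targets named list mapping miRNA id to a nonempty character vector
#'   of target genes.
#' @param mirnas miRNA ids to include (default: all names of `targets`).
#' @return a [SimilarityMatrix-class] tagged `miRNA`/`functional`.
#' @export
mirnaFunctionalSimilarity <- function(net, targets, mirnas = names(targets)) {
  if (length(mirnas) == 0) stop("empty miRNA list")
  for (m in mirnas) {
    g <- targets[[m]]
    if (is.null(g) || length(g) == 0)
      stop(sprintf("miRNA '%s' has an empty target set", m))
  }
  n <- length(mirnas)
  S <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      Gi <- unique(targets[[mirnas[i]]])
      for (j in (i + 1):n) {
        Gj <- unique(targets[[mirnas[j]]])
        B <- .geneSimBlock(net, Gi, Gj)
        S[i, j] <- S[j, i] <-
          (sum(apply(B, 1, max)) + sum(apply(B, 2, max))) / (length(Gi) + length(Gj))
      }
    }
  }
  SimilarityMatrix(S, ids = mirnas, axis = "miRNA", kind = "functional")
}

#' Gaussian association-profile kernel similarity
#'
#' Radial basis kernel over binary association profiles with a data-normalized
#' bandwidth: `K(u, v) = exp(-gamma * ||p_u - p_v||^2)` with
#' `gamma = gammaPrime / mean_k ||p_k||^2`. Disease profiles are the columns
#' of the miRNA x disease matrix, microRNA profiles its rows.
#'
#' @param X an [AssociationMatrix-class] (or binary matrix with dimnames).
#' @param axis `"disease"` or `"miRNA"`.
#' @param gammaPrime positive bandwidth multiplier; default 0.5.
#' @return a [SimilarityMatrix-class] tagged `gapk`.
#' @export
gapkSimilarity <- function(X, axis = c("disease", "miRNA"), gammaPrime = 0.5) {
  axis <- match.arg(axis)
  stopIfNotScalar(gammaPrime, "gammaPrime", lower = 1e-12)
  Xm <- if (methods::is(X, "AssociationMatrix")) X@values else as.matrix(X)
  if (sum(Xm) == 0)
    stop("all-zero association matrix: kernel bandwidth undefined")
  P <- if (axis == "disease") t(Xm) else Xm   # profiles as rows
  meanNorm <- mean(rowSums(P^2))
  if (meanNorm == 0) stop("zero mean profile norm: kernel bandwidth undefined")
  gam <- gammaPrime / meanNorm
  nz <- which(rowSums(P^2) == 0)
  if (length(nz))
    mdaLog("gapkSimilarity(%s): %d all-zero profile(s) (%s)", axis, length(nz),
           paste(utils::head(rownames(P)[nz], 5), collapse = ", "))
  D2 <- as.matrix(stats::dist(P))^2
  K <- exp(-gam * D2)
  diag(K) <- 1
  K <- (K + t(K)) / 2               # dist() is exact-symmetric; belt and braces
  SimilarityMatrix(K, ids = rownames(P), axis = axis, kind = "gapk")
}

#' Fuse kernel and base similarity matrices
#'
#' Convex combination `w * kernel + (1 - w) * base`; both inputs must cover
#' the same entities on the same axis. The combination preserves symmetry,
#' the unit diagonal and the [0, 1] range, so no re-normalization is applied.
#'
#' @param kernel,base [SimilarityMatrix-class] objects over the same registry.
#' @param w kernel weight in [0, 1]; default 0.3.
#' @return a [SimilarityMatrix-class] tagged `fused`.
#' @export
fuseSimilarity <- function(kernel, base, w = 0.3) {
  stopIfNotScalar(w, "w", lower = 0, upper = 1)
  if (!identical(entityIds(kernel), entityIds(base)))
    stop("registry mismatch between kernel and base similarity")
  if (!identical(kernel@axis, base@axis))
    stop("axis mismatch between kernel and base similarity")
  SimilarityMatrix(w * kernel@values + (1 - w) * base@values,
                   ids = entityIds(kernel), axis = kernel@axis, kind = "fused")
}
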