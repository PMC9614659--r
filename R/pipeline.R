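## End-to-end convenience wrappers binding the similarity, completion and
## ranking stages together.

#' Compute the fused disease and microRNA similarity matrices
#'
#' Disease side: hierarchy-based semantic similarity fused with the disease
#' profile kernel. MicroRNA side: gene-network best-match-average similarity
#' fused with the miRNA profile kernel. One fusion weight `w` and one kernel
#' multiplier `gammaPrime` are used for both sides.
#'
#' @param dataset an [MDADataset-class].
#' @param delta semantic decay factor (default 0.5).
#' @param w kernel weight of the fusion (default 0.3).
#' @param gammaPrime kernel bandwidth multiplier (default 0.5).
#' @return list with fused `SM` (miRNA) and `SD` (disease)
#'   [SimilarityMatrix-class] objects plus the four constituents.
#' @export
computeSimilarities <- function(dataset, delta = 0.5, w = 0.3,
                                gammaPrime = 0.5) {
  X <- dataset@associations
  Sd <- diseaseSemanticSimilarity(dataset@dag, diseaseIds(X), delta)
  Sm <- mirnaFunctionalSimilarity(dataset@geneNet, dataset@targets, mirnaIds(X))
  GD <- gapkSimilarity(X, "disease", gammaPrime)
  GM <- gapkSimilarity(X, "miRNA", gammaPrime)
  list(SM = fuseSimilarity(GM, Sm, w), SD = fuseSimilarity(GD, Sd, w),
       semantic = Sd, functional = Sm, gapkDisease = GD, gapkMirna = GM)
}

#' Score all microRNA-disease pairs of a dataset
#'
#' Full pipeline: fused similarities, heterogeneous matrix assembly, bounded
#' nuclear-norm completion, and extraction of the association block.
#'
#' @param dataset an [MDADataset-class].
#' @param delta,w,gammaPrime similarity parameters.
#' @param alpha,beta,tol,maxIter solver parameters.
#' @return list with `scores` (miRNA x disease matrix), `fit`
#'   ([BNNRFit-class]), `net` ([HeteroNetwork-class]) and `similarities`.
#' @export
predictAssociations <- function(dataset, delta = 0.5, w = 0.3,
                                gammaPrime = 0.5, alpha = 1, beta = 10,
                                tol = 1e-6, maxIter = 300L) {
  sims <- computeSimilarities(dataset, delta, w, gammaPrime)
  net <- assembleHetero(sims$SM, sims$SD, dataset@associations)
  mdaLog("predictAssociations: completing a side-%d matrix", nrow(net@W))
  fit <- bnnrComplete(net, alpha = alpha, beta = beta, tol = tol,
                      maxIter = maxIter)
  mdaLog("predictAssociations: %d iterations, converged = %s",
         fit@iterations, fit@converged)
  list(scores = extractScores(fit, net = net), fit = fit, net = net,
       similarities = sims)
}
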