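## Evaluation protocol: entry-level k-fold cross validation with Mann-Whitney
## AUC, repeated with derived seeds, plus per-disease candidate ranking.

#' Mann-Whitney AUC
#'
#' Rank-based estimator of the probability that a random positive outscores a
#' random negative, with ties at half credit:
#' `(sum of positive ranks - nPos(nPos+1)/2) / (nPos * nNeg)`.
#'
#' @param scores numeric predictions.
#' @param labels binary ground truth (0/1), same length.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  r <- rank(scores)                      # average ranks give half-credit ties
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Assign association-matrix entries to cross-validation folds
#'
#' Uniformly random partition of all m x n entry indices into `nFolds`
#' near-equal folds (sizes differ by at most one), seeded deterministically
#' from the master seed and the repeat index.
#'
#' @param X an [AssociationMatrix-class] or matrix.
#' @param nFolds number of folds (default 5).
#' @param repeatIndex which repeat this assignment belongs to.
#' @param seed master seed.
#' @return integer matrix of fold labels, same shape as `X`.
#' @export
makeFolds <- function(X, nFolds = 5L, repeatIndex = 1L, seed = 42L) {
  Xm <- if (methods::is(X, "AssociationMatrix")) X@values else as.matrix(X)
  N <- length(Xm)
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stop("nFolds must be >= 2")
  if (N < nFolds) stop("fewer matrix entries than folds")
  set.seed(deriveSeed(seed, repeatIndex))
  labels <- sample(rep(seq_len(nFolds), length.out = N))
  matrix(labels, nrow(Xm), ncol(Xm), dimnames = dimnames(Xm))
}

## Fused similarity pair (SM, SD) recomputed from a training association
## matrix. The semantic and functional bases do not depend on X and are
## passed in precomputed; only the profile kernels are refreshed.
.fusedSimilarities <- function(Xtrain, semBase, funBase, w, gammaPrime) {
  GD <- gapkSimilarity(Xtrain, "disease", gammaPrime)
  GM <- gapkSimilarity(Xtrain, "miRNA", gammaPrime)
  list(SM = fuseSimilarity(GM, funBase, w), SD = fuseSimilarity(GD, semBase, w))
}

## Default scorer: full pipeline from a training matrix to a score matrix.
.bnnrScorer <- function(semBase, funBase, w, gammaPrime, alpha, beta, tol, maxIter) {
  force(semBase); force(funBase)
  function(Xtrain) {
    sims <- .fusedSimilarities(Xtrain, semBase, funBase, w, gammaPrime)
    net <- assembleHetero(sims$SM, sims$SD, Xtrain)
    fit <- bnnrComplete(net, alpha = alpha, beta = beta, tol = tol,
                        maxIter = maxIter)
    extractScores(fit, net = net)
  }
}

#' Repeated cross-validation of the association predictor
#'
#' For every repeat, all m x n entries are partitioned into folds; each test
#' fold is hidden (set to 0) in the training copy, the profile kernels and
#' fused similarities are recomputed from the training copy only (no label
#' leakage), the heterogeneous matrix is completed, and AUC is computed over
#' the test-fold entries against their true labels. Folds whose test entries
#' are single-class are skipped and logged.
#'
#' @param dataset an [MDADataset-class]; alternatively pass `X`, `dag`,
#'   `geneNet`, `targets` individually.
#' @param X,dag,geneNet,targets components, ignored when `dataset` is given.
#' @param nFolds,nRepeats protocol size (defaults 5 and 10).
#' @param seed master seed; fold assignments derive from `(seed, repeat)`.
#' @param delta,w,gammaPrime similarity parameters (defaults 0.5, 0.3, 0.5).
#' @param alpha,beta,tol,maxIter solver parameters (defaults 1, 10, 1e-6, 300).
#' @param mode `"entries"` (default) splits all matrix entries;
#'   `"positives"` splits only the known associations and evaluates each
#'   fold's hidden positives against all never-associated pairs.
#' @param scorer optional function(Xtrain) -> score matrix replacing the
#'   completion pipeline (used for plumbing checks and ablations).
#' @return list with `folds` (data.frame: repeatIndex, fold, auc, nTest,
#'   nPos), `meanAUC` (mean of per-fold AUCs, the headline number),
#'   `pooledAUC` (AUC over all test entries pooled), `skipped`, and the
#'   configuration echo.
#' @export
runCV <- function(dataset = NULL, X = NULL, dag = NULL, geneNet = NULL,
                  targets = NULL, nFolds = 5L, nRepeats = 10L, seed = 42L,
                  delta = 0.5, w = 0.3, gammaPrime = 0.5,
                  alpha = 1, beta = 10, tol = 1e-6, maxIter = 300L,
                  mode = c("entries", "positives"), scorer = NULL) {
  mode <- match.arg(mode)
  if (!is.null(dataset)) {
    X <- dataset@associations; dag <- dataset@dag
    geneNet <- dataset@geneNet; targets <- dataset@targets
  }
  if (!methods::is(X, "AssociationMatrix")) X <- AssociationMatrix(as.matrix(X))
  Xm <- X@values
  if (is.null(scorer)) {
    semBase <- diseaseSemanticSimilarity(dag, diseaseIds(X), delta)
    funBase <- mirnaFunctionalSimilarity(geneNet, targets, mirnaIds(X))
    scorer <- .bnnrScorer(semBase, funBase, w, gammaPrime, alpha, beta,
                          tol, maxIter)
  }
  rows <- list(); skipped <- 0L
  poolScores <- numeric(0); poolLabels <- integer(0)
  for (rep in seq_len(nRepeats)) {
    folds <- if (mode == "entries") {
      makeFolds(X, nFolds, rep, seed)
    } else {
      .makePositiveFolds(Xm, nFolds, rep, seed)
    }
    for (f in seq_len(nFolds)) {
      test <- folds == f
      Xtr <- Xm
      Xtr[test] <- 0
      if (mode == "entries") {
        labels <- Xm[test]
        if (length(unique(labels)) < 2L) {
          skipped <- skipped + 1L
          mdaLog("runCV: repeat %d fold %d skipped (single-class test fold)", rep, f)
          next
        }
        S <- scorer(AssociationMatrix(Xtr))
        sc <- S[test]
      } else {
        ## hidden positives vs all never-associated pairs
        S <- scorer(AssociationMatrix(Xtr))
        evalIdx <- test | (Xm == 0)
        labels <- Xm[evalIdx]
        sc <- S[evalIdx]
        if (length(unique(labels)) < 2L) { skipped <- skipped + 1L; next }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        repeatIndex = rep, fold = f, auc = aucScore(sc, labels),
        nTest = length(labels), nPos = sum(labels == 1))
      poolScores <- c(poolScores, sc)
      poolLabels <- c(poolLabels, labels)
    }
    mdaLog("runCV: repeat %d/%d done", rep, nRepeats)
  }
  if (!length(rows)) stop("every fold was single-class; cannot evaluate")
  folds <- do.call(rbind, rows)
  list(folds = folds,
       meanAUC = mean(folds$auc),
       pooledAUC = aucScore(poolScores, poolLabels),
       skipped = skipped,
       config = list(nFolds = nFolds, nRepeats = nRepeats, seed = seed,
                     delta = delta, w = w, gammaPrime = gammaPrime,
                     alpha = alpha, beta = beta, tol = tol,
                     maxIter = maxIter, mode = mode))
}

## Positives-only folds: partition the 1-entries; 0 marks "not in any fold".
.makePositiveFolds <- function(Xm, nFolds, repeatIndex, seed) {
  pos <- which(Xm == 1)
  if (length(pos) < nFolds) stop("fewer positive entries than folds")
  set.seed(deriveSeed(seed, repeatIndex))
  labels <- sample(rep(seq_len(nFolds), length.out = length(pos)))
  folds <- array(0L, dim(Xm))
  folds[pos] <- labels
  folds
}

#' Rank candidate microRNAs for one disease
#'
#' Sorts all microRNAs by descending association score (ties broken by miRNA
#' id, lexicographically) and flags the known associations. Also reports how
#' many of the k known microRNAs occupy the top k positions — the recovery
#' count used in case studies.
#'
#' @param scores miRNA x disease score matrix (dimnames required).
#' @param X an [AssociationMatrix-class] supplying the known flags.
#' @param disease a disease id present in the score matrix columns.
#' @return list with `table` (data.frame: mirna, score, rank, known) and
#'   `topkKnown` (known microRNAs among the top k, k = number known).
#' @export
rankCandidates <- function(scores, X, disease) {
  scores <- as.matrix(scores)
  if (!disease %in% colnames(scores))
    stop(sprintf("unknown disease id '%s'", disease))
  s <- scores[, disease]
  known <- X@values[, disease] == 1
  ord <- order(-s, names(s), method = "radix")
  tab <- data.frame(mirna = names(s)[ord], score = s[ord],
                    rank = seq_along(s), known = known[ord],
                    row.names = NULL)
  k <- sum(known)
  list(table = tab, topkKnown = if (k > 0) sum(tab$known[seq_len(k)]) else 0L)
}
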