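## Independent brute-force oracles and tiny fixture builders used across the
## suite. Oracles are deliberately naive implementations kept separate from
## the package code paths they validate.

options(bnnrmda.verbose = FALSE)

## AUC as an explicit double loop over (positive, negative) pairs with half
## credit for ties.
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

## Best-match-average microRNA similarity as an explicit double loop over
## genes, calling only the scalar gene similarity.
bruteFunSim <- function(net, Gi, Gj) {
  best <- function(g, G) max(vapply(G, function(h) geneSimilarity(net, g, h),
                                    numeric(1)))
  (sum(vapply(Gi, best, numeric(1), G = Gj)) +
   sum(vapply(Gj, best, numeric(1), G = Gi))) / (length(Gi) + length(Gj))
}

## Objective of the bounded nuclear-norm model.
bnnrObjective <- function(Y, W, mask, alpha) {
  sum(svd(Y)$d) + alpha / 2 * sum((Y[mask] - W[mask])^2)
}

## Independent first-order solver for the same model: proximal gradient
## (ISTA) on alpha/2 ||P_Omega(Y - W)||^2 with the nuclear-norm prox,
## followed by a box projection. Shares no code with bnnrComplete().
istaComplete <- function(W, mask, alpha, iters = 2000) {
  Y <- W * mask
  step <- 1 / alpha
  for (k in seq_len(iters)) {
    G <- array(0, dim(W))
    G[mask] <- alpha * (Y[mask] - W[mask])
    Y <- svt(Y - step * G, step)
    Y[Y < 0] <- 0; Y[Y > 1] <- 1
  }
  Y
}

## Bright symmetric rank-2 matrix in [0, 1]: blend of two positive profiles,
## the regime (similarity-like blocks) the completion targets.
plantedRank2 <- function(n = 20, seed = 1) {
  set.seed(seed)
  u1 <- runif(n, 0.8, 1)
  u2 <- rev(sort(runif(n, 0.8, 1)))
  B <- 0.5 * outer(u1, u1) + 0.5 * outer(u2, u2)
  B / max(B)
}

## Symmetric random observation mask with observed diagonal.
symmetricMask <- function(n, frac = 0.5) {
  M <- matrix(runif(n * n) < frac, n, n)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- TRUE
  M
}

relErr <- function(est, truth, idx) {
  sqrt(sum((est[idx] - truth[idx])^2)) / sqrt(sum(truth[idx]^2))
}

## Three-disease hierarchy: parent p with children a, b.
siblingDagRecords <- function() {
  data.frame(disease_id = c("p", "a", "b"),
             tree_number = c("C04", "C04.1", "C04.2"))
}

## Small fixture used where full default size is unnecessary.
smallFixture <- function(...) {
  synthFixture(nMirnas = 16L, nDiseases = 12L, nGenes = 40L, nFactors = 3L,
               depth = 3L, ...)
}
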