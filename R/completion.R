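## Heterogeneous-network assembly and the bounded nuclear-norm completion
## solver (augmented Lagrangian / ADMM with singular value thresholding).

#' Assemble the heterogeneous block matrix and its observation mask
#'
#' Produces the side-(m+n) symmetric matrix `[[SM, X], [t(X), SD]]`. The
#' similarity blocks are treated as fully observed; in the association blocks
#' only the 1-entries are observed — the 0-entries are precisely the unknown
#' pairs the completion is asked to score.
#'
#' @param SM miRNA-axis [SimilarityMatrix-class] matching the rows of `X`.
#' @param SD disease-axis [SimilarityMatrix-class] matching the columns of `X`.
#' @param X an [AssociationMatrix-class].
#' @return a [HeteroNetwork-class].
#' @export
assembleHetero <- function(SM, SD, X) {
  if (!identical(entityIds(SM), mirnaIds(X)))
    stop("miRNA registry mismatch between SM and the association matrix")
  if (!identical(entityIds(SD), diseaseIds(X)))
    stop("disease registry mismatch between SD and the association matrix")
  if (SM@axis != "miRNA" || SD@axis != "disease")
    stop("SM must be miRNA-tagged and SD disease-tagged")
  Xm <- X@values
  m <- nrow(Xm); n <- ncol(Xm)
  W <- rbind(cbind(SM@values, Xm), cbind(t(Xm), SD@values))
  ids <- c(mirnaIds(X), diseaseIds(X))
  dimnames(W) <- list(ids, ids)
  mask <- matrix(FALSE, m + n, m + n, dimnames = dimnames(W))
  mask[seq_len(m), seq_len(m)] <- TRUE
  mask[m + seq_len(n), m + seq_len(n)] <- TRUE
  obs <- Xm == 1
  mask[seq_len(m), m + seq_len(n)] <- obs
  mask[m + seq_len(n), seq_len(m)] <- t(obs)
  new("HeteroNetwork", W = W, mask = mask,
      mirnas = mirnaIds(X), diseases = diseaseIds(X))
}

#' Singular value thresholding
#'
#' Proximal operator of the nuclear norm: the unique minimizer of
#' `tau * ||Y||_* + 0.5 * ||Y - M||_F^2`, obtained by soft-thresholding the
#' singular values of `M` by `tau`.
#'
#' @param M numeric matrix with finite entries.
#' @param tau nonnegative threshold.
#' @return matrix of the same shape with singular values reduced by `tau`
#'   and floored at zero.
#' @export
svt <- function(M, tau) {
  if (!all(is.finite(M))) stop("non-finite entries passed to svt()")
  stopIfNotScalar(tau, "tau", lower = 0)
  if (tau == 0) return(M)
  s <- svd(M)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(array(0, dim(M)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' Bounded nuclear-norm matrix completion
#'
#' Minimizes `||Y||_* + alpha/2 * ||P_Omega(Z) - P_Omega(W)||_F^2` subject to
#' `Y = Z` and `0 <= Z <= 1`, by an augmented-Lagrangian iteration: a
#' singular-value-thresholding step in `Y`, a separable quadratic step in `Z`
#' (exact under the box constraint via clipping), and a multiplier update.
#' `alpha` trades data fidelity against the low-rank prior; `beta` is the
#' penalty parameter (held fixed).
#'
#' @param W a [HeteroNetwork-class], or a plain numeric matrix.
#' @param mask logical matrix of observed entries; taken from `W` when it is
#'   a `HeteroNetwork`.
#' @param alpha fidelity weight (default 1).
#' @param beta penalty parameter (default 10).
#' @param tol convergence tolerance on both the relative change of `Z` and
#'   the relative `Y - Z` gap (default 1e-6).
#' @param maxIter iteration cap (default 300).
#' @return a [BNNRFit-class] with the completed matrix, iteration count,
#'   residual trace and convergence flag.
#' @export
bnnrComplete <- function(W, mask = NULL, alpha = 1, beta = 10,
                         tol = 1e-6, maxIter = 300L) {
  if (methods::is(W, "HeteroNetwork")) {
    if (is.null(mask)) mask <- W@mask
    W <- W@W
  }
  W <- as.matrix(W)
  if (is.null(mask)) stop("an observation mask is required")
  mask <- as.matrix(mask)
  if (!identical(dim(W), dim(mask))) stop("mask shape must match W")
  stopIfNotScalar(alpha, "alpha", lower = 1e-12)
  stopIfNotScalar(beta, "beta", lower = 1e-12)
  stopIfNotScalar(tol, "tol", lower = 0)
  maxIter <- as.integer(maxIter)
  if (maxIter < 1L) stop("maxIter must be >= 1")

  obs <- which(mask)
  Z <- array(0, dim(W)); Z[obs] <- W[obs]      # Z0 = P_Omega(W)
  L <- array(0, dim(W))                        # zero initial multiplier
  normW <- max(1, frobNorm(W))
  trace <- data.frame(iter = integer(maxIter), relChange = numeric(maxIter),
                      gap = numeric(maxIter))
  converged <- FALSE
  k <- 0L
  while (k < maxIter) {
    k <- k + 1L
    Y <- svt(Z - L / beta, 1 / beta)
    Znew <- Y + L / beta
    Znew[obs] <- (L[obs] + beta * Y[obs] + alpha * W[obs]) / (alpha + beta)
    Znew <- clip01(Znew)
    if (!all(is.finite(Znew)))
      stop(sprintf("solver diverged (non-finite iterate) at iteration %d", k))
    relChange <- frobNorm(Znew - Z) / max(1, frobNorm(Z))
    gap <- frobNorm(Y - Znew) / normW
    L <- L + beta * (Y - Znew)
    Z <- Znew
    trace$iter[k] <- k; trace$relChange[k] <- relChange; trace$gap[k] <- gap
    if (relChange < tol && gap < tol) { converged <- TRUE; break }
  }
  dimnames(Z) <- dimnames(W)
  new("BNNRFit", Z = Z, iterations = k, trace = trace[seq_len(k), , drop = FALSE],
      converged = converged)
}

#' Extract miRNA x disease scores from a completed heterogeneous matrix
#'
#' Reads the top-right `m x n` block of the completed matrix. With symmetric
#' input the bottom-left block agrees to numerical precision; a disagreement
#' beyond 1e-8 is treated as a solver defect and raised.
#'
#' @param fit a [BNNRFit-class] from a side-(m+n) problem.
#' @param m,n numbers of miRNAs and diseases; may be given implicitly via
#'   `net`.
#' @param net optional [HeteroNetwork-class]; supplies `m`, `n` and dimnames.
#' @return numeric `m x n` matrix of association scores in [0, 1].
#' @export
extractScores <- function(fit, m = NULL, n = NULL, net = NULL) {
  if (!is.null(net)) {
    m <- length(net@mirnas); n <- length(net@diseases)
  }
  Z <- fit@Z
  if (is.null(m) || is.null(n) || m + n != nrow(Z))
    stop(sprintf("dimension mismatch: completed side %d != m + n", nrow(Z)))
  top <- Z[seq_len(m), m + seq_len(n), drop = FALSE]
  bottom <- t(Z[m + seq_len(n), seq_len(m), drop = FALSE])
  if (max(abs(top - bottom)) > 1e-8)
    stop("association blocks of the completed matrix disagree beyond 1e-8")
  if (!is.null(net)) dimnames(top) <- list(net@mirnas, net@diseases)
  top
}
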