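test_that("heterogeneous assembly places blocks and masks correctly", {
  ids <- list(m = c("m1", "m2"), d = c("d1", "d2"))
  SM <- SimilarityMatrix(diag(2), ids$m, axis = "miRNA", kind = "fused")
  SD <- SimilarityMatrix(diag(2), ids$d, axis = "disease", kind = "fused")
  X0 <- AssociationMatrix(matrix(0, 2, 2, dimnames = ids))
  net <- assembleHetero(SM, SD, X0)
  expect_equal(unname(net@W), diag(4))          # identity blocks, zero X
  expect_equal(sum(net@mask), 8)                # two 2x2 similarity blocks
  expect_false(any(net@mask[1:2, 3:4]))

  ## a single association adds exactly two symmetric observed positions
  X1 <- AssociationMatrix(matrix(c(0, 0, 1, 0), 2, 2, dimnames = ids))
  net1 <- assembleHetero(SM, SD, X1)
  expect_equal(sum(net1@mask) - sum(net@mask), 2)
  expect_true(net1@mask["m1", "d2"] && net1@mask["d2", "m1"])
  expect_equal(net1@W["m1", "d2"], 1)

  ## registry mismatch is an alignment error
  SDbad <- SimilarityMatrix(diag(2), c("dX", "dY"), axis = "disease",
                            kind = "fused")
  expect_error(assembleHetero(SM, SDbad, X1), "mismatch")
})

test_that("singular value thresholding equals the closed-form prox", {
  expect_equal(svt(diag(c(3, 1)), 2), diag(c(1, 0)))
  M <- matrix(rnorm(12), 3, 4)
  expect_identical(svt(M, 0), M)
  ## diagonal input: elementwise soft threshold, exact
  d <- c(5, 2, 0.4)
  expect_equal(svt(diag(d), 0.5), diag(pmax(d - 0.5, 0)), tolerance = 1e-12)
  expect_error(svt(matrix(c(1, NA, 0, 1), 2, 2), 1), "non-finite")
})

test_that("svt output is a local minimum of the prox objective", {
  obj <- function(Y, M, tau) tau * sum(svd(Y)$d) + 0.5 * sum((Y - M)^2)
  for (seed in 1:20) {
    set.seed(seed)
    M <- matrix(rnorm(16, sd = 2), 4, 4)
    tau <- runif(1, 0.1, 2)
    Y <- svt(M, tau)
    f0 <- obj(Y, M, tau)
    fp <- vapply(1:200, function(p) {
      obj(Y + matrix(rnorm(16, sd = 1e-3), 4, 4), M, tau)
    }, numeric(1))
    expect_gte(min(fp), f0 - 1e-12)
  }
})

test_that("zero input is a fixed point of the completion", {
  W <- matrix(0, 5, 5)
  fit <- bnnrComplete(W, matrix(TRUE, 5, 5))
  expect_true(all(fit@Z == 0))
  expect_lte(fit@iterations, 2)
  expect_true(fit@converged)
})

test_that("large alpha forces data fidelity on observed entries", {
  set.seed(11)
  u <- runif(12); v <- runif(9)
  W <- outer(u, v); W <- W / max(W)
  mask <- matrix(TRUE, 12, 9)
  fit <- bnnrComplete(W, mask, alpha = 100, beta = 10)
  expect_lt(relErr(fit@Z, W, mask), 0.05)
  ## alpha -> infinity limit: observed entries pinned to W
  fit2 <- bnnrComplete(W, mask, alpha = 1e4, beta = 10)
  expect_lt(max(abs(fit2@Z[mask] - W[mask])), 0.02)
})

test_that("completed matrices are box-feasible and symmetry-preserving", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(5:40, 1)
    A <- matrix(runif(n * n), n, n)
    W <- (A + t(A)) / 2
    mask <- symmetricMask(n, runif(1, 0.3, 0.9))
    fit <- bnnrComplete(W, mask, tol = 1e-5, maxIter = 100)
    expect_gte(min(fit@Z), -1e-9)
    expect_lte(max(fit@Z), 1 + 1e-9)
    expect_lte(max(abs(fit@Z - t(fit@Z))), 1e-8)
  }
})

test_that("planted low-rank structure is recovered from half the entries", {
  B <- plantedRank2(20, seed = 1)
  set.seed(1)
  mask <- symmetricMask(20, 0.5)
  fit <- bnnrComplete(B, mask, alpha = 1, beta = 10, maxIter = 1000)
  hid <- !mask
  expect_lt(relErr(fit@Z, B, hid), 0.15)

  ## independent first-order solver reaches a comparable optimum
  Yref <- istaComplete(B, mask, alpha = 1)
  expect_lt(relErr(Yref, B, hid), 0.15)
  fZ <- bnnrObjective(fit@Z, B, mask, alpha = 1)
  fY <- bnnrObjective(Yref, B, mask, alpha = 1)
  expect_lt(abs(fZ - fY) / fY, 0.02)

  ## low-rank bias: completed nuclear norm below the zero-filled baseline
  expect_lt(sum(svd(fit@Z)$d), sum(svd(B * mask)$d))
})

test_that("the duality gap trace is non-increasing near convergence", {
  fx <- smallFixture(seed = 6)
  ds <- fixtureDataset(fx)
  res <- predictAssociations(ds)
  gap <- tail(solverTrace(res$fit)$gap, 10)
  expect_true(all(diff(gap) <= 1e-12))
})

test_that("score extraction returns the association block", {
  ids <- list(m = c("m1", "m2"), d = c("d1", "d2", "d3"))
  SM <- SimilarityMatrix(diag(2), ids$m, axis = "miRNA", kind = "fused")
  SD <- SimilarityMatrix(diag(3), ids$d, axis = "disease", kind = "fused")
  Xv <- matrix(0, 2, 3, dimnames = ids); Xv["m1", "d2"] <- 1
  net <- assembleHetero(SM, SD, AssociationMatrix(Xv))
  fit <- bnnrComplete(net, alpha = 100, beta = 10)
  S <- extractScores(fit, net = net)
  expect_equal(dim(S), c(2L, 3L))
  ## fidelity-dominated observed association stays near 1
  expect_gte(S["m1", "d2"], 0.9)
  expect_error(extractScores(fit, m = 3, n = 3), "dimension mismatch")

  ## all-zero input completes to all-zero scores
  fit0 <- bnnrComplete(matrix(0, 5, 5), matrix(TRUE, 5, 5))
  expect_true(all(extractScores(fit0, m = 2, n = 3) == 0))
})
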