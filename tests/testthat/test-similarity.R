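test_that("DAG construction follows tree-number prefixes", {
  dag <- buildDiseaseDAG(data.frame(d = c("d1", "d2"),
                                    t = c("C04", "C04.100")))
  expect_setequal(dag@ancestors[["d2"]], c("d2", "d1"))
  expect_setequal(dag@ancestors[["d1"]], "d1")

  ## several tree numbers contribute the union of ancestor chains
  dag2 <- buildDiseaseDAG(data.frame(
    d = c("d1", "d2", "d3", "d3"),
    t = c("C04", "C06", "C04.1", "C06.2")))
  expect_setequal(dag2@ancestors[["d3"]], c("d3", "d1", "d2"))

  ## an unowned prefix terminates the chain; duplicates appear once
  dag3 <- buildDiseaseDAG(data.frame(
    d = c("r", "a", "b", "c", "c"),
    t = c("C01", "C01.1", "C01.2", "C01.1.1", "C01.2.1")))
  expect_setequal(dag3@ancestors[["c"]], c("c", "a", "b", "r"))
})

test_that("DAG construction rejects malformed input", {
  expect_error(buildDiseaseDAG(data.frame(d = "d1", t = "")),
               "without tree number.*d1")
  ## colliding tree numbers that create a two-cycle
  expect_error(buildDiseaseDAG(data.frame(
    d = c("a", "a", "b", "b"),
    t = c("C04", "C05.1", "C05", "C04.1"))), "cycl")
})

test_that("semantic contributions decay by delta with the max rule", {
  chain <- buildDiseaseDAG(data.frame(d = c("g", "p", "d"),
                                      t = c("C01", "C01.1", "C01.1.1")))
  D <- semanticContribution(chain, "d", 0.5)
  expect_identical(unname(D["d"]), 1)
  expect_identical(unname(D["p"]), 0.5)
  expect_identical(unname(D["g"]), 0.25)

  ## diamond: two parents both at 0.5, grandparent takes the max
  diamond <- buildDiseaseDAG(data.frame(
    d = c("g", "g", "p1", "p2", "d", "d"),
    t = c("C01", "C02", "C01.1", "C02.1", "C01.1.1", "C02.1.1")))
  Dd <- semanticContribution(diamond, "d", 0.5)
  expect_equal(unname(Dd[c("p1", "p2", "g")]), c(0.5, 0.5, 0.25))

  ## delta = 1 keeps every ancestor at full contribution
  D1 <- semanticContribution(chain, "d", 1)
  expect_true(all(D1 == 1))

  expect_error(semanticContribution(chain, "nope"), "unknown disease")
})

test_that("disease semantic similarity matches hand-computed values", {
  dag <- buildDiseaseDAG(siblingDagRecords())
  S <- as.matrix(diseaseSemanticSimilarity(dag, c("a", "b"), 0.5))
  expect_equal(S["a", "a"], 1)
  expect_equal(S["a", "b"], 1 / 3, tolerance = 1e-14)

  ## disjoint ancestor sets share nothing
  two <- buildDiseaseDAG(data.frame(d = c("x", "y"), t = c("C01", "C02")))
  expect_equal(as.matrix(diseaseSemanticSimilarity(two, c("x", "y")))["x", "y"], 0)

  ## vanishing delta kills off-diagonals
  Ssmall <- as.matrix(diseaseSemanticSimilarity(dag, c("a", "b"), 1e-9))
  expect_lt(Ssmall["a", "b"], 1e-6)

  expect_error(diseaseSemanticSimilarity(dag, character()), "empty")
})

test_that("disease semantic similarity is permutation-equivariant", {
  fx <- smallFixture(seed = 3)
  dag <- buildDiseaseDAG(fx$treeRecords)
  ids <- dag@ids
  set.seed(1)
  perm <- sample(ids)
  S1 <- as.matrix(diseaseSemanticSimilarity(dag, ids))
  S2 <- as.matrix(diseaseSemanticSimilarity(dag, perm))
  expect_equal(S2, S1[perm, perm], tolerance = 1e-14)
})

test_that("LLS normalization maps the global extremes to 0 and 1", {
  net <- normalizeLLS(data.frame(a = c("g1", "g1", "g2"),
                                 b = c("g2", "g3", "g3"),
                                 lls = c(3, 1, 5)))
  expect_equal(geneSimilarity(net, "g1", "g2"), 0.5)
  expect_equal(geneSimilarity(net, "g1", "g3"), 0)   # carries LLSmin
  expect_equal(geneSimilarity(net, "g2", "g3"), 1)   # carries LLSmax
  expect_error(normalizeLLS(data.frame(a = "g1", b = "g2", lls = 2)),
               "degenerate")
})

test_that("gene similarity handles identity and absent edges", {
  net <- normalizeLLS(data.frame(a = c("g1", "g2"), b = c("g2", "g3"),
                                 lls = c(1, 5)))
  expect_equal(geneSimilarity(net, "g1", "g1"), 1)
  expect_equal(geneSimilarity(net, "g1", "g3"), 0)        # no edge
  expect_equal(geneSimilarity(net, "gX", "gY"), 0)        # absent genes
  expect_equal(geneSimilarity(net, "gX", "gX"), 1)        # identity wins
})

test_that("miRNA functional similarity matches hand values and the BMA oracle", {
  net <- normalizeLLS(data.frame(a = c("g1", "g1", "g2"),
                                 b = c("g2", "g3", "g3"),
                                 lls = c(3, 1, 5)))
  tg <- list(mA = "g1", mB = "g2", mC = c("g1", "g2"))
  S <- as.matrix(mirnaFunctionalSimilarity(net, tg))
  expect_equal(S["mA", "mB"], 0.5)          # (0.5 + 0.5) / 2
  expect_equal(S["mC", "mC"], 1)

  ## identical target sets are maximally similar
  S2 <- as.matrix(mirnaFunctionalSimilarity(net, list(x = c("g1", "g2"),
                                                      y = c("g1", "g2"))))
  expect_equal(S2["x", "y"], 1)

  ## disjoint sets with no edges between them are dissimilar
  net0 <- normalizeLLS(data.frame(a = c("g1", "g3"), b = c("g2", "g4"),
                                  lls = c(1, 5)))
  S3 <- as.matrix(mirnaFunctionalSimilarity(net0, list(x = c("g1", "g2"),
                                                       y = c("g3", "g4"))))
  expect_equal(S3["x", "y"], 0)
  expect_equal(S3["x", "y"], bruteFunSim(net0, c("g1", "g2"), c("g3", "g4")))

  expect_error(mirnaFunctionalSimilarity(net, list(mA = character())),
               "empty target set")

  ## randomized agreement with the double-loop oracle
  for (seed in 1:20) {
    set.seed(seed)
    genes <- sprintf("g%d", 1:6)
    pairs <- t(combn(genes, 2))
    take <- sample(nrow(pairs), 8)
    netR <- normalizeLLS(data.frame(a = pairs[take, 1], b = pairs[take, 2],
                                    lls = runif(8, 0, 10)))
    nM <- sample(2:5, 1)
    tgR <- lapply(seq_len(nM), function(i) sample(genes, sample(1:4, 1)))
    names(tgR) <- sprintf("m%d", seq_len(nM))
    S <- as.matrix(mirnaFunctionalSimilarity(netR, tgR))
    for (i in seq_len(nM)) for (j in seq_len(nM)) {
      if (i == j) next
      expect_equal(S[i, j],
                   bruteFunSim(netR, unique(tgR[[i]]), unique(tgR[[j]])),
                   tolerance = 1e-12)
    }
  }
})

test_that("profile kernel matches the hand example and is well-behaved", {
  X <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(c("m1", "m2"),
                                                   c("d1", "d2")))
  G <- as.matrix(gapkSimilarity(X, "disease", 0.5))
  ## gamma = 0.5 / ((1 + 0) / 2) = 1; ||p1 - p2||^2 = 1
  expect_equal(G["d1", "d2"], exp(-1), tolerance = 1e-14)
  expect_equal(diag(G), c(d1 = 1, d2 = 1))

  ## identical profiles are maximally similar
  X2 <- matrix(c(1, 1, 0, 0, 1, 1), 2, 3,
               dimnames = list(c("m1", "m2"), c("d1", "d2", "d3")))
  G2 <- as.matrix(gapkSimilarity(X2, "disease"))
  expect_equal(G2["d1", "d3"], 1)

  expect_error(gapkSimilarity(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                              c("x", "y")))),
               "all-zero")
})

test_that("profile kernel is invariant to simultaneous axis permutation", {
  fx <- smallFixture(seed = 9)
  X <- as.matrix(fx$X)
  set.seed(2)
  pm <- sample(nrow(X)); pd <- sample(ncol(X))
  for (axis in c("disease", "miRNA")) {
    K1 <- as.matrix(gapkSimilarity(X, axis))
    K2 <- as.matrix(gapkSimilarity(X[pm, pd], axis))
    ids <- if (axis == "disease") colnames(X)[pd] else rownames(X)[pm]
    expect_equal(K2, K1[ids, ids], tolerance = 1e-12)
  }
})

test_that("similarity fusion is the convex combination with invariants intact", {
  fx <- smallFixture(seed = 4)
  X <- fx$X
  GD <- gapkSimilarity(X, "disease")
  dag <- buildDiseaseDAG(fx$treeRecords)
  SD <- diseaseSemanticSimilarity(dag, diseaseIds(X))
  expect_equal(as.matrix(fuseSimilarity(GD, SD, 0)), as.matrix(SD))
  expect_equal(as.matrix(fuseSimilarity(GD, SD, 1)), as.matrix(GD))

  ## hand arithmetic on the two module examples
  expect_equal(0.3 * exp(-1) + 0.7 * (1 / 3),
               as.numeric(0.3 * exp(-1) + 0.7 / 3))
  f <- as.matrix(fuseSimilarity(GD, SD, 0.3))
  expect_equal(f, 0.3 * as.matrix(GD) + 0.7 * as.matrix(SD), tolerance = 1e-14)

  ## monotone in w where the kernel exceeds the base
  i <- which(as.matrix(GD) > as.matrix(SD), arr.ind = TRUE)[1, ]
  vals <- vapply(c(0.1, 0.3, 0.6, 0.9), function(w)
    as.matrix(fuseSimilarity(GD, SD, w))[i[1], i[2]], numeric(1))
  expect_true(all(diff(vals) > 0))

  ## registry mismatch is refused
  GM <- gapkSimilarity(X, "miRNA")
  expect_error(fuseSimilarity(GM, SD), "mismatch")
})

test_that("produced similarity matrices satisfy the container invariants", {
  fx <- smallFixture(seed = 5)
  ds <- fixtureDataset(fx)
  sims <- computeSimilarities(ds)
  for (S in sims) {
    v <- as.matrix(S)
    expect_lt(max(abs(v - t(v))), 1e-12)
    expect_equal(unname(diag(v)), rep(1, nrow(v)))
    expect_true(min(v) >= 0 && max(v) <= 1)
  }
})
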