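## Seeded synthetic data with planted latent-factor structure shared across
## the three layers (disease hierarchy, gene network / target sets,
## association matrix), so similarity fusion is genuinely informative and the
## whole pipeline is testable without external downloads.

## balanced factor assignment: contiguous blocks of entities per factor
.assignFactors <- function(n, nFactors) {
  sort(rep_len(seq_len(nFactors), n))
}

#' Synthetic disease hierarchy as tree-number records
#'
#' Builds one rooted subtree per latent factor: the factor's first disease is
#' the root and the remaining diseases fill a `branching`-ary tree of at most
#' `depth` levels in breadth-first order, so siblings share parents and the
#' semantic similarity spectrum is graded within a factor and zero across
#' factors.
#'
#' @param nDiseases total diseases.
#' @param nFactors number of subtrees (latent factors).
#' @param depth maximum tree depth (levels; default 3).
#' @param branching children per node (default 2).
#' @return data.frame with columns `disease_id`, `tree_number`.
#' @export
synthDiseaseTree <- function(nDiseases, nFactors = 1L, depth = 3L,
                             branching = 2L) {
  if (branching < 2L || depth < 2L) stop("need branching >= 2 and depth >= 2")
  capacity <- sum(branching^(0:(depth - 1L)))
  factor <- .assignFactors(nDiseases, nFactors)
  if (max(table(factor)) > capacity)
    stop(sprintf("tree of depth %d, branching %d holds %d diseases per factor",
                 depth, branching, capacity))
  ids <- sprintf("d%03d", seq_len(nDiseases))
  tn <- character(nDiseases)
  for (f in seq_len(nFactors)) {
    members <- which(factor == f)
    queue <- sprintf("C%02d", f)          # root tree number
    childCount <- integer(0)
    assigned <- character(0)
    for (idx in seq_along(members)) {
      if (idx == 1L) {
        tn[members[idx]] <- queue[1]
        assigned <- queue[1]
        childCount <- stats::setNames(0L, queue[1])
        next
      }
      ## attach to the earliest assigned node with spare child slots
      parent <- assigned[which(childCount[assigned] < branching)[1]]
      childCount[parent] <- childCount[parent] + 1L
      node <- paste0(parent, ".", sprintf("%03d", childCount[parent]))
      tn[members[idx]] <- node
      assigned <- c(assigned, node)
      childCount[node] <- 0L
    }
  }
  data.frame(disease_id = ids, tree_number = tn, stringsAsFactors = FALSE)
}

#' Synthetic gene network and miRNA target sets
#'
#' Genes are partitioned into one pool per factor. Within-pool pairs receive
#' raw log-likelihood scores from `llsWithin`, plus `nCrossEdges` random
#' cross-pool edges from `llsCross`. Each microRNA draws `targetsPerMirna`
#' genes: a deterministic shared core of `ceil(overlap * targetsPerMirna)`
#' pool genes common to its whole factor, the rest sampled from its pool, so
#' within-factor target sharing is controlled by `overlap`.
#'
#' @param nMirnas,nGenes,nFactors sizes.
#' @param targetsPerMirna targets per microRNA (default 8).
#' @param overlap within-factor shared-core fraction in [0, 1] (default 0.6).
#' @param llsWithin,llsCross uniform ranges for raw scores
#'   (defaults c(2, 5) and c(0.5, 2)).
#' @param nCrossEdges random cross-pool edges (default `nGenes`); set 0 for
#'   exactly zero cross-factor similarity.
#' @param seed RNG seed.
#' @return list with `geneRecords` (gene_a, gene_b, lls) and
#'   `targetRecords` (mirna_id, gene_id).
#' @export
synthGeneLayer <- function(nMirnas, nGenes, nFactors = 1L, targetsPerMirna = 8L,
                           overlap = 0.6, llsWithin = c(2, 5),
                           llsCross = c(0.5, 2), nCrossEdges = nGenes,
                           seed = 17L) {
  if (nGenes < 2L) stop("need at least 2 genes")
  set.seed(deriveSeed(seed, 2L))
  genes <- sprintf("g%03d", seq_len(nGenes))
  genePool <- .assignFactors(nGenes, nFactors)
  mirnas <- sprintf("m%03d", seq_len(nMirnas))
  mirnaFactor <- .assignFactors(nMirnas, nFactors)

  edges <- list()
  for (f in seq_len(nFactors)) {
    pool <- genes[genePool == f]
    if (length(pool) >= 2) {
      pairs <- utils::combn(pool, 2)
      edges[[f]] <- data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
                               lls = stats::runif(ncol(pairs), llsWithin[1],
                                                  llsWithin[2]))
    }
  }
  ge <- do.call(rbind, edges)
  if (nCrossEdges > 0 && nFactors > 1) {
    a <- sample(genes, nCrossEdges, replace = TRUE)
    b <- sample(genes, nCrossEdges, replace = TRUE)
    keep <- genePool[match(a, genes)] != genePool[match(b, genes)]
    if (any(keep))
      ge <- rbind(ge, data.frame(gene_a = a[keep], gene_b = b[keep],
                                 lls = stats::runif(sum(keep), llsCross[1],
                                                    llsCross[2])))
  }
  ge <- ge[!duplicated(t(apply(ge[, 1:2], 1, sort))), ]

  core <- max(0L, min(targetsPerMirna, ceiling(overlap * targetsPerMirna)))
  tgt <- list()
  for (i in seq_len(nMirnas)) {
    pool <- genes[genePool == mirnaFactor[i]]
    shared <- utils::head(pool, core)
    rest <- setdiff(pool, shared)
    extra <- if (targetsPerMirna > core && length(rest))
      sample(rest, min(targetsPerMirna - core, length(rest))) else character()
    t_i <- unique(c(shared, extra))
    if (!length(t_i)) t_i <- pool[1]        # every miRNA keeps >= 1 target
    tgt[[i]] <- data.frame(mirna_id = mirnas[i], gene_id = t_i)
  }
  rownames(ge) <- NULL
  list(geneRecords = ge, targetRecords = do.call(rbind, tgt))
}

#' Synthetic association matrix with planted low-rank block structure
#'
#' Binary factor memberships `U` (miRNA x r) and `V` (disease x r) follow the
#' same balanced factor assignment as the other layers, thinned by an
#' inclusion probability chosen so the clean matrix `threshold(U V^T)` has
#' approximately the requested density. Each entry is then flipped
#' independently with probability `noise`.
#'
#' @param nMirnas,nDiseases,nFactors sizes; `nFactors` must be below both.
#' @param density target fraction of 1-entries in (0, 1) (default 0.1).
#' @param noise per-entry flip probability in [0, 0.5) (default 0.05).
#' @param seed RNG seed; regenerated with the next derived seed (up to 10
#'   attempts) if the noisy matrix comes out all-zero.
#' @return list with `X` (noisy [AssociationMatrix-class]), `clean` (binary
#'   matrix before noise), `U`, `V` (binary factor memberships),
#'   `mirnaFactor`, `diseaseFactor`.
#' @export
synthAssociations <- function(nMirnas, nDiseases, nFactors = 4L, density = 0.1,
                              noise = 0.05, seed = 17L) {
  if (nFactors >= min(nMirnas, nDiseases))
    stop("nFactors must be smaller than both entity counts")
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  if (noise < 0 || noise >= 0.5) stop("noise must be in [0, 0.5)")
  mirnas <- sprintf("m%03d", seq_len(nMirnas))
  diseases <- sprintf("d%03d", seq_len(nDiseases))
  mf <- .assignFactors(nMirnas, nFactors)
  df <- .assignFactors(nDiseases, nFactors)
  q <- sqrt(min(1, density * nFactors))   # per-side membership inclusion
  for (attempt in seq_len(10L)) {
    set.seed(deriveSeed(seed, 100L + attempt))
    U <- matrix(0L, nMirnas, nFactors)
    U[cbind(seq_len(nMirnas), mf)] <- as.integer(stats::runif(nMirnas) < q)
    V <- matrix(0L, nDiseases, nFactors)
    V[cbind(seq_len(nDiseases), df)] <- as.integer(stats::runif(nDiseases) < q)
    clean <- (U %*% t(V) > 0) + 0L
    flip <- matrix(stats::runif(nMirnas * nDiseases) < noise,
                   nMirnas, nDiseases)
    noisy <- ifelse(flip, 1L - clean, clean)
    if (sum(noisy) > 0) {
      storage.mode(clean) <- storage.mode(noisy) <- "double"
      dimnames(clean) <- dimnames(noisy) <- list(mirnas, diseases)
      rownames(U) <- mirnas; rownames(V) <- diseases
      return(list(X = AssociationMatrix(noisy), clean = clean, U = U, V = V,
                  mirnaFactor = stats::setNames(mf, mirnas),
                  diseaseFactor = stats::setNames(df, diseases)))
    }
  }
  stop("degenerate all-zero association matrix after 10 attempts")
}

#' Generate a complete synthetic fixture
#'
#' Bundles the three layers with one shared factor assignment. Defaults are
#' the package's standard study conditions: 40 microRNAs, 30 diseases, 120
#' genes, 4 latent factors, density 0.1, flip noise 0.05, seed 17.
#'
#' @param nMirnas,nDiseases,nGenes,nFactors sizes.
#' @param density,noise association-matrix parameters, see
#'   [synthAssociations()].
#' @param depth,branching disease-tree shape, see [synthDiseaseTree()].
#' @param targetsPerMirna,overlap,nCrossEdges gene-layer parameters, see
#'   [synthGeneLayer()].
#' @param seed master seed; every layer derives its own stream from it.
#' @return list with `treeRecords`, `geneRecords`, `targetRecords`,
#'   `assocRecords` (pair table of the noisy 1-entries), `X`, `clean`,
#'   `mirnaFactor`, `diseaseFactor`.
#' @export
synthFixture <- function(nMirnas = 40L, nDiseases = 30L, nGenes = 120L,
                         nFactors = 4L, density = 0.1, noise = 0.05,
                         depth = 4L, branching = 2L, targetsPerMirna = 8L,
                         overlap = 0.6, nCrossEdges = nGenes, seed = 17L) {
  tree <- synthDiseaseTree(nDiseases, nFactors, depth, branching)
  gl <- synthGeneLayer(nMirnas, nGenes, nFactors, targetsPerMirna, overlap,
                       nCrossEdges = nCrossEdges, seed = seed)
  assoc <- synthAssociations(nMirnas, nDiseases, nFactors, density, noise, seed)
  ones <- which(assoc$X@values == 1, arr.ind = TRUE)
  assocRecords <- data.frame(
    mirna_id = rownames(assoc$X@values)[ones[, 1]],
    disease_id = colnames(assoc$X@values)[ones[, 2]],
    stringsAsFactors = FALSE)
  assocRecords <- assocRecords[order(assocRecords$mirna_id,
                                     assocRecords$disease_id), ]
  list(treeRecords = tree, geneRecords = gl$geneRecords,
       targetRecords = gl$targetRecords, assocRecords = assocRecords,
       X = assoc$X, clean = assoc$clean,
       mirnaFactor = assoc$mirnaFactor, diseaseFactor = assoc$diseaseFactor)
}

#' Assemble an in-memory fixture into a validated dataset
#'
#' Equivalent to writing the fixture with [writeFixture()] and reloading it
#' with [loadDataset()], without touching disk.
#'
#' @param fixture output of [synthFixture()].
#' @return an [MDADataset-class].
#' @export
fixtureDataset <- function(fixture) {
  new("MDADataset",
      associations = fixture$X,
      dag = buildDiseaseDAG(fixture$treeRecords),
      geneNet = normalizeLLS(fixture$geneRecords),
      targets = lapply(split(fixture$targetRecords$gene_id,
                             fixture$targetRecords$mirna_id), unique),
      provenance = list(source = "synthetic"))
}
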