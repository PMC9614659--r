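---
title: "Methods: bounded nuclear-norm completion for miRNA-disease association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bounded nuclear-norm completion for miRNA-disease association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnnrmda)
options(bnnrmda.verbose = FALSE)
```

## The problem and the model

Curated miRNA-disease catalogues record a few thousand experimentally
supported associations between hundreds of microRNAs and hundreds of
diseases; the overwhelming majority of pairs are simply unobserved. The
package treats scoring those unknown pairs as matrix completion on a
heterogeneous network. With `m` microRNAs and `n` diseases, the block matrix

$$W = \begin{bmatrix} SM & X \\ X^\top & SD \end{bmatrix}$$

combines a fused miRNA similarity matrix `SM`, a fused disease similarity
matrix `SD`, and the binary association matrix `X`. Functionally related
microRNAs tend to associate with semantically related diseases, so `W` is
approximately low-rank, and all of its entries are probabilities-like values
in [0, 1]. The completion therefore minimizes

$$\min_Y \|Y\|_* + \frac{\alpha}{2}\,\|P_\Omega(Y) - P_\Omega(W)\|_F^2
  \quad \text{s.t.} \quad 0 \le Y \le 1,$$

where $\|\cdot\|_*$ is the nuclear norm (the convex surrogate for rank),
$\Omega$ is the set of observed entries and $P_\Omega$ the projection onto
them. The soft fidelity term (rather than an exact constraint) tolerates
curation noise; the box constraint keeps scores interpretable.

**What is observed.** Both similarity blocks are fully observed. In the
association blocks only the 1-entries belong to $\Omega$: a 0 means
"unknown", not "absent", and those are exactly the entries the solver is
asked to fill in. Anchoring the similarity blocks is what makes the
completion informative — without it they would be free variables and the
minimizer would collapse.

## Similarity construction

**Disease semantic similarity.** Each disease sits in a hierarchy given by
dot-delimited tree numbers (MeSH dialect: the parent of `C04.588` is the
disease holding `C04`). A disease contributes 1 to itself; an ancestor `t`
contributes $\Delta \cdot \max_{t' \in \mathrm{children}(t)} D_d(t')$, so
contributions decay geometrically along chains, with the max rule resolving
multiple paths (diseases commonly hold several tree numbers; the package
merges their ancestor chains). Pairwise similarity is the contribution mass
of shared ancestors from both sides over the two total masses. The decay
factor defaults to $\Delta = 0.5$, the value in standard use for this family
of measures: each generation of ancestry counts half as much.

**MicroRNA functional similarity.** Gene-gene functional-linkage
log-likelihood scores (HumanNet-style, consumed as input) are min-max
normalized to [0, 1] by the global extremes of the full network. Gene
similarity is 1 for identity, the normalized score for an edge, 0 otherwise
— including gene pairs absent from the network. MicroRNA similarity is the
best-match average over their target gene sets: every gene is matched to its
most similar counterpart in the other set and the two directional sums are
divided by the total number of targets. MicroRNAs without any target genes
cannot be placed on this scale and are removed at load time, as are diseases
without hierarchy positions.

**Profile kernels.** The Gaussian association-profile kernel compares binary
association profiles (rows of `X` for microRNAs, columns for diseases):
$\exp(-\gamma \|p_u - p_v\|^2)$ with $\gamma = \gamma' / \overline{\|p\|^2}$,
the bandwidth normalized by the mean squared profile norm so that $\gamma'$
is dimensionless. One $\gamma' = 0.5$ is used for both axes. An all-zero
profile is permitted (the kernel distance is still well-defined) but logged,
since such entities carry no profile information.

**Fusion.** Final similarities are the convex combination
$w \cdot \mathrm{kernel} + (1 - w) \cdot \mathrm{base}$ with $w = 0.3$:
most of the weight stays on the curated structural similarity, with the
kernel contributing association-profile signal. Convex combination preserves
symmetry, the unit diagonal and the [0, 1] range, so nothing is
re-normalized afterwards.

Defaults $\alpha = 1$, $\beta = 10$, $w = 0.3$, $\gamma' = 0.5$ are the
grid-searched operating point reported for this method family; they are all
exposed as arguments and in `runConfig()`.

## The solver

The augmented Lagrangian of the model, with auxiliary `Z` splitting the
nuclear norm from the fidelity-plus-box part, is minimized alternately:

1. `Y <- svt(Z - L/beta, 1/beta)` — singular value thresholding, the exact
   proximal operator of the nuclear norm;
2. `Z`: on $\Omega$, $(L + \beta Y + \alpha W)/(\alpha + \beta)$; off
   $\Omega$, $Y + L/\beta$; then clipped to [0, 1]. The quadratic
   subproblem is separable per entry, so clipping is the exact
   box-constrained minimizer, not an approximation;
3. `L <- L + beta * (Y - Z)` — multiplier update.

Initialization is $Z_0 = P_\Omega(W)$, $L_0 = 0$. Iteration stops when both
the relative Frobenius change of `Z` and the relative `Y - Z` gap fall below
`tol`, or at `maxIter`. Defaults are `tol = 1e-6`, `maxIter = 300` with
$\beta$ held fixed; on study-sized problems the residual decays smoothly at
under one percent per iteration, so runs often stop at the iteration cap
with the gap already near 1e-5 — the `converged` flag and the full residual
trace are reported rather than hidden. Scores are read from the top-right
block only; the transposed block is checked to agree within 1e-8, so a
symmetry bug cannot be silently averaged away. The SVD is the full
`svd()` — correctness first; the single swap-in point for a truncated or
randomized SVD is `svt()`.

Two numerical caveats worth knowing. First, symmetry of the iterates is
preserved by construction for symmetric input, but it is *measured* (to
1e-8) rather than enforced, so a defect would surface in tests instead of
being projected away. Second, the nuclear-norm penalty shrinks every
retained singular value by roughly $1/\alpha$ in absolute terms; at
$\alpha = 1$ this is the intended noise tolerance for bright similarity-like
blocks (singular values well above 1), but a dim, sparse low-rank matrix is
*not* recoverable at that setting — its singular values are comparable to
the shrinkage itself. This is a property of the model, not of the
implementation, and it is why recovery checks in the test-suite plant
bright, dense low-rank structure.

## Evaluation protocol

Cross validation splits **all** `m x n` entries — hidden positives and
hidden zeros alike — into `nFolds` near-equal random folds, repeated
`nRepeats` times with fold seeds derived deterministically from
`(masterSeed, repeatIndex)`. For each fold the test entries are zeroed in
the training copy, and the profile kernels and fused similarities are
recomputed from the training copy only: the kernel is a function of `X`, so
reusing full-data profiles would leak test labels. AUC is the Mann-Whitney
estimator (ties at half credit) over the test-fold entries; the headline
number is the mean of per-fold AUCs, with the pooled-entries variant also
reported. A positives-only protocol (hide a fold of the 1-entries and score
them against all never-associated pairs) is available via
`mode = "positives"`; it is the common alternative in this literature and
yields numbers that are not comparable to the entry-level protocol.

Per-disease candidate ranking sorts microRNAs by descending score with ties
broken lexicographically by id, flags known associations, and reports how
many of the `k` known microRNAs occupy the top `k` ranks.

## The synthetic generator

Real inputs for this problem come from curated databases that cannot be
bundled; the generator produces inputs with the statistical structure the
method assumes, at a size (40 microRNAs, 30 diseases, 120 genes by default)
that completes end-to-end in seconds. One balanced assignment of entities to
`r = 4` latent factors is planted in *all three* layers: each factor is a
subtree of the disease hierarchy, a gene pool plus shared target core, and a
block of the association matrix. This mirrors the method's premise —
functionally similar microRNAs associate with semantically similar diseases
— and is what makes fusion genuinely informative on synthetic data.

The clean association matrix is `threshold(U V^T)` with binary memberships
thinned at probability `sqrt(density * r)` per side, so the realized density
is approximately the requested `density` (default 0.1, in the vicinity of
curated-catalogue sparsity). Each entry is then flipped independently with
probability `noise` (default 0.05). Two consequences deserve emphasis:

* thinning leaves some entities with all-zero clean profiles — permitted,
  logged, and handled throughout;
* symmetric flip noise at density 0.1 makes a substantial fraction
  (roughly a third) of the observed positives pure label noise. Hidden
  test positives of that kind are unrecoverable *by construction* — no
  ranker, however good, can order them above typical negatives — which caps
  the achievable cross-validation AUC on the default fixture near the low
  0.80s and makes the measured AUC noticeably seed-dependent. Passing
  synthetic tests therefore demonstrate pipeline correctness and fusion
  gain, not the ceiling performance the method attains on curated data,
  where positives are experimentally supported and the noise is
  predominantly missingness rather than false positives.

The generator does not attempt to emulate the degree distributions or sizes
of the real catalogues, and `r`, `density` and `noise` interact: results on
non-default settings should be compared only within a setting.

## Worked example

```{r example}
fx <- synthFixture(seed = 17)
ds <- fixtureDataset(fx)
res <- predictAssociations(ds)
res$fit
head(sort(res$scores[as.matrix(ds@associations) == 0], decreasing = TRUE))
```

```{r cv, eval = FALSE}
cv <- runCV(ds, nFolds = 5, nRepeats = 3, seed = 17)
cv$meanAUC
```

## Known limitations

* Full SVD limits practical problem sides to a few thousand.
* Dim low-rank structure is not recoverable at small `alpha` (see above).
* Only the simplified tree-number TSV dialect is parsed, not MeSH XML.
* LLS scores are consumed, never computed; the gene network is an input.
* The dense gene-similarity block is built per miRNA pair; with tens of
  thousands of genes a sparse best-match strategy would be needed.
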