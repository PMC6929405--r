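---
title: "Predicting synthetic-lethal gene pairs by self-representative matrix factorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting synthetic-lethal gene pairs by self-representative matrix factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsmf)
```

## The problem

A synthetic-lethal (SL) interaction is a gene pair whose simultaneous loss
kills a cell while loss of either gene alone does not. SL partners of
tumour-mutated genes are candidate anticancer drug targets, and validated
SL pairs are scarce and expensive to screen, so ranking the untested pairs
computationally is worthwhile. The data are a symmetric binary matrix
$X \in \{0,1\}^{n \times n}$ over $n$ genes: $X_{ij} = 1$ for a validated
SL pair, $X_{ij} = 0$ for an *unknown* pair — absence of evidence, not
evidence of absence. The diagonal is fixed at zero and $(i,j)$ and
$(j,i)$ are the same pair.

Only positive labels exist: there is no catalogue of verified
*non*-interactions. This rules out ordinary supervised classification and
motivates a matrix-completion view in which every zero entry is a
candidate to be scored.

## The model

Instead of factoring $X$ into low-rank latent factors — which requires
choosing a latent dimension — the model represents $X$ by itself:

$$
\min_{U}\; \|X - U^\top X U\|_F^2 \;+\; \lambda \|U\|_F^2
\;+\; \beta\, \mathrm{Tr}(U^\top L U)
\quad \text{s.t. } 0 \le U_{li} \le 1,\; \sum_{l=1}^n U_{li} = 1 .
$$

Because $X$ is symmetric, rows and columns share a single coefficient
matrix $U \in \mathbb{R}^{n \times n}$, applied on both sides. Column $i$
of $U$ lies on the probability simplex and $U_{li}$ reads as the
probability that gene $g_i$ is represented by gene $g_l$; two genes end
up with similar columns when they share SL partners. The $\ell_2$ term
(weight $\lambda$) discourages the degenerate one-hot solution in which
each gene represents only itself.

The third term injects prior biology. Given a gene functional-similarity
matrix $S \in [0,1]^{n\times n}$ (in practice Gene Ontology
biological-process semantic similarity, consumed here as a precomputed
matrix), let $D = \mathrm{diag}(D_{ii})$, $D_{ii} = \sum_j S_{ij}$, and
$L = D - S$ be the graph Laplacian. Then

$$
\mathrm{Tr}(U^\top L U)
 = \tfrac12 \sum_{l}\sum_{i,j} (U_{il} - U_{jl})^2\, S_{ij} \;\ge\; 0,
$$

so the penalty pulls functionally similar genes toward similar
representation *rows*. Note two identities that the tests exploit: the
quadratic form is invariant to the diagonal of $S$ (self-similarity
cancels in $D-S$), and $L\mathbf{1} = 0$ exactly. With $\beta = 0$ the
model reduces to plain self-representative factorization (called SMF
throughout); this ablation is first-class in the package.

## Optimization

The objective is minimized by relaxed majorization–minimization
multiplicative updates. The gradient splits into elementwise non-negative
parts

$$
\nabla^{+} = 4 (XU)(U^\top X U) + 2\lambda U + 2\beta D U, \qquad
\nabla^{-} = 4 (XU) X + 2\beta S U ,
$$

and the simplex constraint enters through two per-column scalars

$$
a_i = \sum_l \frac{U_{li}}{\nabla^{+}_{li}}, \qquad
b_i = \sum_l U_{li}\frac{\nabla^{-}_{li}}{\nabla^{+}_{li}},
$$

giving the update

$$
U_{li} \leftarrow U_{li}\,
\frac{a_i \nabla^{-}_{li} + 1}{a_i \nabla^{+}_{li} + b_i}.
$$

Non-negativity is preserved from a positive start. Iteration stops when
the relative objective change drops below $10^{-4}$ (absolute change when
the objective is exactly zero), or after `max_iter` (default 1000)
updates. The prediction is $\hat{X} = U^\top X U$, symmetric and
non-negative by construction; unknown pairs are ranked by
$\hat{X}_{ij}$ descending.

A useful closed-form check: with $X = 0$, $\beta = 0$ and any
$\lambda > 0$, one update sends every positive feasible column to the
uniform vector $1/n$, which is then a fixed point with objective exactly
$\lambda$. The test suite verifies this to $10^{-12}$, and verifies the
analytic gradient against centered finite differences on random small
instances.

## Numerical choices

* **Initialization.** Not dictated by the method; the default is the
  uniform matrix $U_{li} = 1/n$ — deterministic, feasible, strictly
  positive. A seeded symmetric-Dirichlet initialization
  (`init = "dirichlet"`) is available for multi-start studies.
* **Division guard.** Denominators in the update and the scalars are
  floored at `eps_div = 1e-12`; sparse $X$ routinely produces zero
  gradients, and the guard keeps the update defined without affecting
  non-degenerate entries.
* **Column-sum drift.** The multiplicative update preserves
  $\sum_l U_{li} = 1$ only at fixed points, not at every iterate. The
  default follows the update literally and *monitors* drift
  (`fit$column_sum_drift`); at convergence on the synthetic suite it stays
  below 0.05, typically around 0.015. `renormalize_columns = TRUE` opts
  into exact per-iteration rescaling (rescale, clip to $[0,1]$, rescale).
  Note that a *single* update taken from an arbitrary simplex point — not
  on the optimization path — can overshoot the constraint substantially;
  the drift guarantee is a property of trajectories from feasible
  initialization, which is what the tests assert.
* **Monotonicity.** Relaxed MM is not provably monotone. Empirically the
  trace is non-increasing (within $10^{-9}$ slack) for the default
  configuration across all seeded synthetic runs, and the suite asserts
  exactly that. Rare transient ascents of a fraction of a percent do occur
  (observed once with $\beta = 0$ on a masked training fold) and still
  converge, so the divergence guard in `grsmf_fit()` aborts only when the
  objective grows by more than `ascent_slack + divergence_tol * |J|`
  (defaults $10^{-9}$ and 2%) for more than `max_ascent = 5` consecutive
  iterations.
* **Dense algebra.** All matrices are dense; the intended scale is a few
  thousand genes at most, and the synthetic suite uses $n \le 300$.

## Hyperparameters

$\lambda$ (ridge weight on $U$) and $\beta$ (graph weight) default to
$2^{-7}$ and $2^{-5}$, the values selected by grid search over
$\{2^{-8}, 2^{-7}, \dots, 2^5\}$ on the full human SL corpus;
`default_grid()` reproduces that candidate set. Cross-validated AUC is
insensitive to $\lambda$ over orders of magnitude, while large $\beta$
(e.g. $2^3$) degrades performance sharply — the similarity graph should
bias, not dominate, the reconstruction. `grid_search()` tunes on the same
fold split it reports (no nested CV), mirroring common practice for this
method family; the selected score is therefore optimistically biased and
should be read as a selection criterion, not an unbiased performance
estimate. Ties prefer the smaller penalties.

## Evaluation protocol

`cross_validate()` splits the known pairs into 5 near-equal folds
(deterministic per seed), masks each fold's pairs out of the training
matrix (both orientations), refits, and scores the held-out pairs against
the negatives. The candidate/negative set is a modelling decision the
method description leaves open; here negatives are **all** unordered pairs
with $X_{ij} = 0$ in the *full* data, so training positives belong to
neither class and an uninformative model scores 0.5. A seeded negative
subsample (`n_negative`) is available for speed at full scale. AUC is the
rank-based Mann–Whitney estimator with ties counted one-half, and the
across-fold summary is the normal-approximation interval
$\bar{A} \pm 1.96\, s/\sqrt{5}$. Per-fold averaging (not pooled scoring)
is used. Hyperparameters are held fixed across folds.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` stands in for the real corpus (a database of
~20k validated human SL pairs) plus a GO-derived similarity matrix,
neither of which ships with the package. Genes fall into functional
groups; SL edges are planted **between** designated partner groups
(Bernoulli `p_in = 0.3` across partner groups, `p_out = 0.01` elsewhere),
mimicking the compensatory-pathway picture in which members of two
redundant pathways — say, parallel DNA-repair routes — are mutually
lethal. Similarity is high **within** groups
(`sim_signal = 0.8` plus Gaussian noise, sd `sim_noise = 0.1`, clipped to
$[0,1]$), so $S$ is informative about the block structure of $U$ without
encoding $X$ itself. The default scenario — 150 genes, 6 groups of 25,
partner pairs (1,2), (3,4), (5,6) — was fixed once so that default
hyperparameters reach a 5-fold CV mean AUC of at least 0.80, and the
ablation ordering GRSMF $\ge$ SMF holds across seeds.

The generator does **not** reproduce the heavy-tailed degree distribution
of curated SL databases, ascertainment bias (well-studied genes
accumulate interactions), GO's DAG-structured similarity (noise here is
i.i.d. Gaussian), or the real corpus's scale and sparsity (~0.1%
density vs ~4% planted here). A green synthetic suite therefore
establishes correctness of the machinery and directional behaviour of the
regularizer, not the headline accuracy on the real database — reproducing
that requires supplying the external pair list and similarity matrix
through the CLI.

## Worked example

```{r example}
sim <- generate_synthetic(synthetic_scenario(seed = 1))
fit <- grsmf_fit(sim$interactions, sim$similarity)
fit

cv <- cross_validate(sim$interactions, sim$similarity, seed = 1)
cv

rank_candidates(sim$interactions, fit, top_k = 5)
```

## Known limitations

* Quadratic memory in $n$ ($U$, $\hat{X}$ are $n \times n$ dense); tens of
  thousands of genes would need sparse or blocked variants (out of scope).
* The column-simplex constraint is enforced only approximately unless
  renormalization is enabled; the two variants can converge to slightly
  different stationary points.
* No convergence proof for the relaxed-MM scheme; the guard detects, not
  prevents, divergence.
* Genes missing from the similarity source receive all-zero similarity
  rows — neutral under the graph penalty, but also unaided by it.
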