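---
title: "Path-based scoring of lncRNA-disease associations: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-based scoring of lncRNA-disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpllda)
```

## The model

`bpllda` treats association prediction as a connectivity problem in one
heterogeneous graph. Nodes are lncRNAs and diseases. Three edge classes
exist:

* **association edges** (lncRNA–disease) of weight exactly 1 wherever the
  binary association matrix `LD` records a confirmed pair;
* **lncRNA–lncRNA edges** weighted by the integrated lncRNA similarity `LS`,
  kept only when `LS ≥ T`;
* **disease–disease edges** weighted by the integrated disease similarity
  `DS`, kept only when `DS ≥ T`.

The confidence that lncRNA $l$ and disease $d$ are associated is

$$\mathrm{score}(l,d) \;=\; \sum_{p \,\in\, P_\tau(l,d)} \Big(\prod_{e \in p} w_e\Big)\, \alpha^{-\mathrm{len}(p)},$$

where $P_\tau(l,d)$ is the set of *simple* (node-repetition-free) paths with
at most $\tau$ edges connecting $l$ and $d$. The model's assumptions are
explicit in this formula: associated pairs are connected by many short paths
through similar entities; similarity edges are probability-like weights in
$(0,1]$ whose product measures the reliability of a relay chain; and longer
chains are geometrically less trustworthy. The method needs no negative
training examples, and can score entities with no known associations at all
(a path can enter through a kernel-similarity edge).

### Why the decay is $\alpha^{-\mathrm{len}}$

The decay must *penalize* long paths — that is the model's stated premise,
and it is what makes the $\tau=1$ limit (only direct edges score) and the
general case consistent: adding a detour can only add a term smaller than
the weight product it rides on. A multiplicative factor that *grows*
linearly with length would invert this premise. We therefore use the
exponential-decay form $(\prod w)\,\alpha^{-\mathrm{len}}$ as the default
and ship the alternative $(\prod w)^{\alpha\cdot \mathrm{len}}$ — which also
decays, by driving products in $(0,1)$ toward zero — behind
`decay_form = "product_power"` for sensitivity analysis. Both preserve the
ranking behavior that the evaluation depends on at $\tau = 1$.

### Similarities

The disease semantic similarity `SS` is an *input* (in practice computed
from the Disease Ontology by external tooling); everything else derives
from `SS` and `LD`:

* **Functional similarity** `FS`: lncRNAs are similar when their
  associated-disease sets are. We aggregate with the best-match rule
  $\mathrm{SIM}(d, D) = \max_{d' \in D} SS(d, d')$, the convention under
  which two lncRNAs with identical disease sets get similarity exactly 1.
  A mean-based aggregation is available (`agg = "mean"`) for sensitivity
  checks.
* **Gaussian interaction-profile kernels** `GL`, `GD`:
  $\exp(-\gamma\|IP_i - IP_j\|^2)$ over rows/columns of `LD`, with
  $\gamma = \gamma' / \overline{\|IP\|^2}$ and $\gamma' = 1$. The bandwidth
  mean runs over *all* entities of the class, zero rows included, so it
  reflects the overall density of the association matrix.
* **Integration**: sparse curated data leave some diseases with no semantic
  similarity to any other disease (set `NS`), and some lncRNAs with no
  functional similarity to any other lncRNA (`NF`). For pairs touching
  those entities the kernel value is substituted (`DS`, `LS`); all other
  entries keep `SS`/`FS`. Kernels are strictly positive, so integration can
  only reduce the zero fraction.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `T` | similarity edge threshold, unitless in $[0,1]$ | 0.2 | keeps the similarity layers sparse enough that paths are informative; AUC is flat in `T` over 0.1–0.5, so the choice is not delicate |
| `tau` | maximum path length, edges | 3 | length 3 is the longest path that adds signal; the pair-enumeration cost grows steeply beyond it |
| `alpha` | decay factor, unitless $> 1$ | 2.26 | the standard value in the decay-weighted path-counting literature this score family comes from |
| `gamma_prime_l`, `gamma_prime_d` | kernel bandwidth scales | 1 | the customary normalization for interaction-profile kernels |

Boundary handling: the threshold comparison is `≥ T` (an edge exactly at the
threshold is kept), the threshold never applies to association edges, and
diagonal similarity entries never create self-loops — a self-loop cannot
occur on a simple path anyway.

## Cross-validation protocol

*Global LOOCV* holds out each association once. Within a fold, the held-out
entry is zeroed in the training matrix and **everything downstream is
recomputed from the training matrix**: `FS`, both kernels (including their
bandwidths), `NS`/`NF`, the integrations, and the network. This prevents
the held-out label from leaking back in through the kernels, which are
functions of `LD`. The cheaper variant that freezes full-data similarities
and merely deletes the association edge is available as
`reuse_similarities = TRUE`. Negative scores are computed once for all
unassociated pairs on the full-data network — their own edges are never held
out, so nothing leaks, and the protocol matches the common practice for
this task family. Both choices are isolated behind single functions so the
alternatives can be swapped.

*Local LOOCV* removes an entity's entire row (novel lncRNA) or column
(novel disease) and scores it against every entity of the other class;
positives and negatives are pooled over folds.

AUC is the Mann–Whitney statistic with half-credit for ties, which is also
what the threshold-sweep ROC curve integrates to. Ties are real here: many
disconnected pairs score exactly 0.

## The synthetic generator

`generate_synthetic()` emulates the statistical regime of curated
association data: entities fall into planted communities; associations are
dense within a community (0.3) and rare across (0.01); every lncRNA keeps
at least one association (curated sets have minimum degree 1); the disease
similarity matrix has unit diagonal, higher within-community means (0.6 vs
0.1, Beta-distributed with concentration 10 — only the rank structure
matters downstream), and ~58% exact zeros, the sparsity level typical of
ontology-derived similarity matrices. The default size is 40×40 with 4
blocks, which keeps a full 10-seed cross-validation study under a minute
while leaving enough structure to recover.

`structureless_config()` produces the matched null: within- and
between-community parameters collapsed to their block-size-weighted
averages (association probability $0.25\cdot0.3 + 0.75\cdot0.01 = 0.0825$,
similarity mean $0.225$), so overall density and similarity level are
preserved and *only* the community signal is removed. On such data the
global-LOOCV AUC should sit near 0.5; the residual deviation comes from
degree heterogeneity (high-degree entities collect both more positives and
higher scores), a known property of LOOCV on networks, not of this scorer.

What the generator does *not* emulate: the directed-acyclic-graph topology
behind real semantic similarities (only the marginal distribution of the
matrix), the heavy-tailed degree distribution of real catalogs (maximum
degrees of 41 vs 15 on 352 pairs), and name noise. Passing the synthetic
recovery tests therefore demonstrates that the pipeline extracts planted
relational structure, not that a particular real-data AUC will be attained —
real-data results additionally depend on the externally supplied semantic
similarity matrix.

Novel-lncRNA local LOOCV is close to chance on synthetic data by
construction: an lncRNA's community membership is encoded *only* in its
association row, so deleting the row removes all recoverable signal. Novel
diseases keep their semantic similarity and are recovered well. On real
data both modes benefit from the externally supplied `SS`.

## Numerical choices

* Matrix entries are 64-bit doubles; symmetry of input similarity matrices
  is enforced to `1e-9` and exact-symmetrized by averaging; values within
  `1e-9` outside $[0,1]$ are clipped, anything worse is an error.
* Path sums are plain left-to-right accumulations: all terms are
  non-negative and path counts are modest (≤ ~10⁵), so compensated
  summation is unnecessary.
* The depth-first search marks the nodes of the current stack as visited,
  treats the target as terminal (a simple path cannot pass through its own
  endpoint), and prunes at depth `tau`. Scores are sums over an unordered
  path set, hence independent of node insertion order and child-visit
  order; a property test permutes node order to confirm this.
* Degenerate inputs: an edgeless network scores every pair 0; an entity
  isolated in a fold scores 0 against everything; an all-zero association
  matrix makes the kernel bandwidth undefined and is an error; an empty
  disease group in the best-match rule is an error rather than 0, to
  surface upstream bookkeeping mistakes.
* The `T`/`L` sweep accepts a per-cell time budget; a cell is skipped once
  a cheaper cell at the same threshold has exceeded the budget, since cost
  grows steeply with `L`. Skipped cells are reported as `NA`, never as a
  value.

## Worked example

```{r example, eval = FALSE}
syn <- generate_synthetic(synth_config(seed = 1))
res <- global_loocv(syn$data, syn$SS, network_config())
res$auc
pb <- precision_bins(res, quantile(res$positive_scores, c(0, .5, .9, 1)))
pb
```

## Known limitations

* Association edges have weight exactly 1; evidence strength or recency is
  not modeled.
* `FS` is itself derived from `LD`, so functional similarity and the
  association labels are not independent — a bias shared by the whole
  method family and the reason the fold protocol recomputes similarities.
* Exact path enumeration is tractable at the few-hundred-node scale this
  method targets (cost roughly cubic in node count at `tau = 3`); it is not
  intended for networks with thousands of entities without sampling.
* The precision-by-bin table inherits the arbitrariness of its bin edges;
  edges are caller-supplied, and empty bins are flagged `NA` rather than
  interpolated.
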