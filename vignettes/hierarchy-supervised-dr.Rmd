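---
title: "Hierarchy-supervised dimensionality reduction: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchy-supervised dimensionality reduction: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierdr)
```

## The model

`hierdr` perturbs the high-dimensional geometry of a labelled dataset before
embedding, rather than modifying any embedding algorithm. Given a
sample-by-feature matrix, per-sample labels, and an undirected label graph
$G$, every pairwise distance is multiplied by a factor
$\theta_{ij} \in [0, 1]$ derived from the shortest-path distance between the
two samples' labels:

$$\theta_{ij} = (1 - \mathrm{str}) + \mathrm{str}\cdot
\bar{d}(i', j'),$$

where $\bar d$ is the label-graph distance normalized to $[0,1]$ and
$\mathrm{str} \in [0,1)$ interpolates between no effect and full
hierarchical scaling. The perturbed matrix $H = (\theta_{ij} d_{ij})$ is
handed to t-SNE, UMAP or PHATE through their precomputed-distance
interfaces, or to PCA executed on $H$ itself. Because the perturbation is
multiplicative and bounded by 1, it only ever *contracts* distances — pairs
whose labels are close in the hierarchy become more similar, pairs at
maximal distance, in different graph components, or involving an unlabeled
sample are left exactly alone.

The method assumes the hierarchy is trustworthy where it is supplied: a
wrong hierarchy will be imprinted on the embedding just as faithfully as a
right one. It also assumes the base distance is meaningful at small scales,
since contraction reorders neighbourhoods.

### Effect on the embedding kernels

All three supported NLDR methods build similarities by exponentiating
(functions of) distances, so the perturbation acts as exponent weighting.
For a Gaussian kernel on squared distances (the t-SNE convention),
$\hat{s}_{j|i} = \exp(-\theta_{ij} d^2 / 2\sigma_i^2) =
(s_{j|i})^{\theta_{ij}}$; for an $\alpha$-decay kernel applied to the
precomputed matrix (the PHATE pathway),
$\hat{s}_{j|i} = \exp(-(\theta_{ij} d/\sigma_i)^\alpha) =
(s_{j|i})^{\theta_{ij}^\alpha}$, which preserves the role of the decay
exponent but makes the hierarchical effect stronger for larger $\alpha$.
`kernel_check()` evaluates both sides of the relevant identity on a given
distance/factor pair and reports the maximum absolute deviation; it is a
diagnostic of internal consistency, not a fit to data. At $\mathrm{str}=1$ a
same-label pair would have $\theta = 0$ and $\hat{s} = 1$ exactly, dropping
out of the embedding cost altogether — which is why `hdr_config()` rejects
strength 1 and sweeps top out at 0.999.

## The normalization pipeline

The label-level distance matrix is normalized in a fixed order, and the
order matters:

1. connected label pairs are divided by `maxdist`, the largest finite
   shortest path in the graph;
2. pairs in *different components* are set to `disconnected_distance`
   verbatim (default 1 — cross-component pairs keep raw distances);
3. only if any entry now exceeds 1 (i.e. `disconnected_distance > 1`), the
   whole off-diagonal matrix is min-max rescaled to $[0,1]$. This step
   deliberately compresses within-component contrast: exaggerating
   cross-component separation is paid for in resolution elsewhere;
4. diagonal entries are 0, except labels listed in `avoid_self`, which
   receive `self_distance` *after* all other normalization.

Samples whose label is missing (`NA`/empty) or not a node of the graph are
handled outside this pipeline: their $\theta$ row and column are forced to
1. They also do not participate in step 3 — an off-graph label must behave
exactly like a missing one, so its sentinel value is never allowed to drag
the min-max range for real label pairs.

### Probability-weighted labels

With predicted labels, per-sample probabilities enter through
$m_{ij} = \min(p_i, p_j)$ and the path term is scaled as
$(\overline{j'i'}-1)/(\mathrm{maxdist}-1)$ on raw path lengths. The two
normalizations — $\mathrm{path}/\mathrm{maxdist}$ in label mode versus
$(\mathrm{path}-1)/(\mathrm{maxdist}-1)$ in probability mode — are
deliberately kept distinct rather than unified: each is implemented exactly
as specified, and `normalize_paths(mode =)` exposes both so a user can make
the modes consistent if desired. In probability mode an adjacent label pair
at full confidence reaches $\theta = 1-\mathrm{str}$ (the path term is 0),
a stronger contraction than label mode gives the same pair. When
$\mathrm{maxdist} = 1$ the probability scaling is 0/0; the package defines
the path term as 0 for the unique finite case (adjacent labels) and warns.

### Degenerate and edge cases

* `maxdist = 0` (single node or edgeless graph): every $\theta$ is set to 1
  with a warning; there is no hierarchy to impose.
* Self-loop edges are rejected at parse time — intra-label behaviour is
  governed solely by `self_distance`/`avoid_self`.
* Duplicate undirected edges merge silently when their weights agree and
  are an error otherwise.
* Null ("dummy") nodes added by the user to reweight connections are
  ordinary vertices and participate in `maxdist`.
* $\theta$ bounds: disconnected and unlabeled pairs sit exactly at 1, so
  the factor's true range is the closed interval $[0, 1]$.

## Tunable parameters

| parameter | range / default | role |
|---|---|---|
| `strength` | $[0,1)$, default 0 | global interpolation toward full hierarchical scaling |
| `self_distance` | $[0,1]$, default 0 | post-normalization intra-class value for labels in `avoid_self`; 0 contracts same-label pairs maximally, 1 disables intra-class contraction |
| `avoid_self` | label subset, empty | which labels use `self_distance` |
| `disconnected_distance` | $\ge 0$, default 1 | pre-min-max value for cross-component pairs; $>1$ exaggerates component separation and triggers the global rescale |
| `squared` | default TRUE | squared-Euclidean convention for the t-SNE pathway |

At strength 1 the minimum of $\theta$ within a component follows three
boundary cases, realized here at 0.999 within $10^{-3}$: the implicit
configuration gives $\theta_{\min} \to 0$ (same-label pairs); with
`avoid_self` covering all labels, $\theta_{\min} \to$ `self_distance` when
that is below the smallest normalized inter-label distance, and
$\to \overline{j'i'}_{\min}/\mathrm{maxdist}$ otherwise.

High strength combined with a large neighbourhood parameter (perplexity,
`n_neighbors`, `knn`) crowds the embedding, because strongly contracted
neighbourhoods saturate; `hdr_embed()` warns when strength exceeds 0.5 and
the neighbourhood parameter exceeds $n/10$, but never adjusts parameters
silently.

## Evaluation metrics

**Neighbourhood concordance (`hc_score`).** For each embedded point, the
labels of its $k$ nearest neighbours (self included; conventional $k$: 3,
$n/100$, $n/10$) are compared by chi-squared statistic, on the count scale,
to an expected distribution in which label $c$ has weight linearly mapped
from normalized graph distance — 1 for the point's own label down to
$1/\mathrm{maxdist}$ at maximal distance — then L1-normalized. The score is
$1 - \sqrt{\text{mean statistic}}$, so 1 is ideal. Labels with expected
count 0 but positive observed count contribute through a floor of
$1/(kL)$. Points with missing or off-graph labels are excluded from the
mean. Two properties of this definition are worth stating plainly, since
both follow from it mathematically and are visible in the test suite: for a
2-node graph the expected distribution is uniform, so a *mixed* embedding
outscores a separated one; and because the expected same-label share on a
7-label tree is only ~0.25 while any class-preserving embedding yields
nearly pure neighbourhoods, the absolute score *decreases* as strength
purifies neighbourhoods. The informative comparison is therefore relative:
the same sweep driven by an equal-weight complete graph (the
"independent classes" baseline from `equal_weight_graph()`) scores worse
than the hierarchy-driven sweep, seed for seed in most cases, because the
hierarchy orders the residual neighbourhood contamination correctly.

**Hierarchical silhouette (`h_silhouette`).** The classical silhouette's
inter-class term $b(i)$ is replaced by the minimum over classes of
(normalized graph distance to that class) × (mean embedding distance to
it); the per-point score is $(b_w - a)/\max(a, b_w)$ and the dataset score
is the mean. 0 is ideal — classes separated exactly in proportion to
hierarchy distance; positive values indicate over-separation, negative
under-separation. The exact weighting is an interpretation (the minimal
modification of the standard silhouette consistent with hierarchy-weighted
inter-class distance and a 0-ideal reading) and is isolated in one function
so it can be swapped. Singleton classes contribute 0.

**Convex-hull overlap (`hull_overlap`).** Per label: points beyond a
per-coordinate z-score threshold (default 3) are dropped, the convex hull
built, the nearest other-label hull located by centroid distance (an
interpretive choice; boundary distance would also be defensible), and
intersection area divided by own hull area. The mean over labels is a
percentage. Degenerate (collinear) hulls contribute 0 with a warning.
Convex-convex intersection is computed by Sutherland–Hodgman clipping and
areas by the shoelace formula.

**Strength sweeps.** `strength_sweep()` re-embeds once per strength on the
grid $0, 0.1, \ldots, 0.9, 0.999$ with a shared seed and integrates the
metric curve by composite Simpson's rule on the actual node positions —
pairs of intervals use the non-uniform three-point formula; a trailing odd
interval falls back to the trapezoid rule. On the default 11-point grid the
10 intervals pair exactly, and a constant curve of 1 integrates to 0.999,
the interval length.

## The synthetic generator

`make_hierarchical_blobs()` emulates a labelled expression matrix whose
latent geometry partially reflects a known hierarchy: one Gaussian blob per
graph node, centroids interpolating between a hierarchy-faithful layout and
an i.i.d. random one. The faithful layout is classical MDS of the
label-graph distances with the Cailliez additive correction — tree metrics
need not be Euclidean, and the additive constant restores embeddability
while preserving rank order, so at fidelity 1 centroid distances are a
monotone transform of graph distances for any connected graph.
Disconnected label pairs are assigned twice `maxdist` before scaling. Both
layouts are scaled to a common root-mean-square pairwise distance
(`centroid_scale`, default 5) before mixing, and points receive isotropic
Gaussian noise (`noise_sd`, default 1). Defaults of 50 points per class and
30 features give clusters that overlap substantially — within-class
distances of roughly $\sqrt{2 \times 30} \approx 7.7$ against centroid
separations around 5 — which is the regime the method targets: structure
present but not legible in the raw embedding. The generator does not model
count noise, sparsity/dropout, library-size variation or batch effects, so
passing tests on it demonstrate the geometry of the method, not robustness
to real single-cell noise.

`dropout_labels()` builds the semi-supervised fixture: an exact seeded
fraction of one class is relabelled with a dummy that must not be a graph
node. Because off-graph labels keep $\theta = 1$ everywhere, the relabelled
samples retain raw distances at every strength — the invariance the test
suite checks bitwise. `expression_classifier()` is the deliberately simple
predictor for probability mode: gene-set sums per node, argmax label,
probability = winning sum over total, ties to the first node in gene-set
order, all-zero samples left unlabelled with probability 0. The
normalization (sum over nodes rather than per gene-set size) is one of
several defensible readings and is isolated for replacement.
`preprocess_counts()` mirrors the count preprocessing used upstream of the
distances: variance filter (default threshold 0.1), then per-sample min-max
normalization (not z-scoring), constant rows mapping to 0.

## Numerical and design choices

* Shortest paths, components and `maxdist` come from igraph; label-level
  factors are computed once per label pair and broadcast to samples, so
  cost is $O(L^2 + n^2)$.
* The $\theta$ matrix is symmetrized by averaging and clipped to $[0,1]$
  to absorb floating-point drift; `apply_theta()` restores an exactly zero
  diagonal.
* PCA is the always-available backend and is deterministic; t-SNE and UMAP
  are seeded (`set.seed` before each call, single-threaded SGD for UMAP) so
  identical inputs give identical coordinates within a session. PHATE is
  supported through the optional phateR package; its kernel identity is
  verified analytically and needs no backend.
* t-SNE uses the squared-Euclidean convention by default, overridable.
* Tie-breaks: nearest-neighbour ties resolve by index order; classifier
  ties by gene-set order, reported via a message.
* Problem sizes in the test suite and acceptance script — graphs of up to 8
  nodes against an exhaustive-path oracle, 350-sample blob datasets, 20
  seeds for recovery statistics — were chosen to make every check exact or
  well-resolved at desk scale.

## Known limitations

Directed hierarchies, automatic hierarchy inference, automatic strength
selection, and depth-diminishing weighting are out of scope (the first and
last are natural extensions). The hull-overlap heuristic requires a 2-D
embedding and at least two labels with three usable points each. The HC
score's absolute level is not comparable across graphs with different
`maxdist`, and, as noted above, its absolute trend in strength rewards
blended neighbourhoods; use it comparatively. Embeddings inherit the
spatial and temporal cost of the backend plus the $n \times n$ distance
matrix; nothing here reduces that footprint.
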