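---
title: "Co-regularized NMF for lincRNA-disease association prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-regularized NMF for lincRNA-disease association prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnmf)
```

## The problem

Long intergenic non-coding RNAs (lincRNAs) regulate many disease processes,
but experimentally validated lincRNA–disease associations are scarce and
expensive to obtain. Given a small binary association matrix
$\hat X \in \{0,1\}^{n_l \times n_d}$ (lincRNAs × diseases), the task is to
score the unobserved cells so that true-but-unreported associations rank
high. Because $\hat X$ alone is too sparse to support this, the model
integrates side information from a heterogeneous network: a lincRNA
co-expression network, a gene genetic-interaction network, gene–disease
associations $\hat Y$, and gene–lincRNA associations $\hat Z$ (a gene and a
lincRNA are linked when they share at least one disease).

## The model

`crnmf_fit()` factorizes $\hat X \approx BF$ with non-negative
$B \in \mathbb{R}^{n_l \times r}$ (latent lincRNA representations) and
$F \in \mathbb{R}^{r \times n_d}$ (latent disease profiles), minimizing

$$
\mathcal{L}(B,F) \;=\; \tfrac12\,\lVert \hat X - BF \rVert_F^2
\;+\; \alpha\, \operatorname{Tr}\!\left(B^{\top} L\, B\right)
\;+\; \tfrac{\beta}{2}\, \lVert BF - T \rVert_F^2,
\qquad B, F \ge 0 .
$$

The first regularizer uses the normalized Laplacian
$L = I - D^{-1/2} W^{[l]} D^{-1/2}$ of the lincRNA co-expression network:
its quadratic form is half the edge-weighted sum of squared differences of
latent rows, so strongly co-expressed lincRNAs are pushed toward similar
representations. The second couples the reconstruction to the path-support
matrix $T = \hat Z^{\top} W^{[g]} \hat Y$, which counts (weighted)
lincRNA → gene → gene → disease paths through the genetic-interaction
network: associations supported by many molecular paths are favored.

Two conventions deserve comment.

* **Orientation of the path target.** With $\hat Z$ stored genes ×
  lincRNAs, the product $\hat Z W^{[g]} \hat Y$ is not conformable; the
  only orientation compatible with $BF$ ($n_l \times n_d$) is
  $\hat Z^{\top} W^{[g]} \hat Y$, which is what `path_target()` computes.
* **Scale of the path target.** $T$ counts paths, so its entries grow with
  gene-network size (thousands at database scale) while $BF$ lives on the
  label scale $[0,1]$. Coupling the two raw quantities would let the path
  term dominate any $\beta \sim 1$ and push all clipped predictions to 1.
  The pipeline drivers therefore rescale $T$ to unit maximum before
  fitting (`scale_target = TRUE`), making $\beta$ dimensionless.
  `path_target()` itself always returns the raw product, and the rescaling
  can be disabled.

## Optimization

Direct minimization is non-convex; the optimizer alternates multiplicative
updates derived from the Karush–Kuhn–Tucker conditions. The gradients are

$$
\nabla_B \mathcal{L} = (1+\beta)\,BFF^{\top} - \hat X F^{\top}
 - \beta\, T F^{\top} + 2\alpha L B,
\qquad
\nabla_F \mathcal{L} = (1+\beta)\,B^{\top}BF - B^{\top}\hat X
 - \beta\, B^{\top} T ,
$$

and the updates place every gradient-negative term in the numerator and
every gradient-positive term in the denominator:

$$
B \leftarrow B \odot
\frac{\hat X F^{\top} + \beta T F^{\top} + 2\alpha \bar W B}
     {(1+\beta) B F F^{\top} + 2\alpha I_d B + \varepsilon},
\qquad
F \leftarrow F \odot
\frac{B^{\top} \hat X + \beta B^{\top} T}
     {(1+\beta) B^{\top} B F + \varepsilon}.
$$

Here the Laplacian is split into its non-negative parts
$L = I_d - \bar W$ ($I_d$: identity restricted to nonzero-degree nodes;
$\bar W = D^{-1/2} W^{[l]} D^{-1/2}$), the standard device of
graph-regularized NMF: dividing by $LB$ directly would mix signs and could
drive factors negative or undefined. With $\alpha = \beta = 0$ the updates
reduce exactly — bit for bit, given the same initialization — to the
classical NMF multiplicative rules, which is how `plain_nmf()` is
implemented and tested.

Properties the test suite verifies on randomized instances:

* the objective is non-increasing at every iteration for all
  $(\alpha, \beta)$ combinations tried;
* non-negativity is preserved; all-zero rows are absorbing;
* the objective matches an element-wise loop evaluation to $10^{-12}$;
* KKT residuals $\min(B, \nabla_B \mathcal{L})$ vanish at interior optima.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `r` | 4 | latent dimension; must be well below $\min(n_l, n_d)$ |
| `alpha` | 1 | weight of the co-expression Laplacian term |
| `beta` | 1 | weight of the path term (after unit-max target scaling) |
| `max_iter` | 200 | iteration budget; the objective typically flattens within ~60 iterations on the bundled synthetic sizes |
| `tol` | 1e-6 | stop when the relative objective change drops below this |
| `epsilon` | 1e-12 | denominator guard inside every divide |
| `threshold` | 0.5 | co-expression cutoff: edges keep weight $\lvert r_{\text{Pearson}}\rvert$ when it reaches the cutoff |
| `theta` | 0.5 | label-propagation mixing weight (baseline) |

$\alpha = \beta = 1$ treats the two networks as equally informative and sits
at the flat region of the sensitivity profile; both weights are exposed
because the best value is data-dependent. The co-expression measure
(Pearson, absolute value, hard threshold) is the standard construction;
signed or soft-thresholded variants are deliberately out of scope because
the Laplacian regularizer requires non-negative weights.

## Evaluation protocol

Metrics over a test set $\tau$ of matrix positions:
$\mathrm{MAE} = \frac{1}{|\tau|} \sum_{(i,j)\in\tau} |\hat x_{ij} - x_{ij}|$,
$\mathrm{Accuracy} = 1 - \mathrm{MAE}$ (exactly, by construction),
$\mathrm{RMSE} = \sqrt{\frac{1}{|\tau|} \sum_{(i,j)\in\tau} (\hat x_{ij} - x_{ij})^2}$,
and full-matrix $\mathrm{RSS} = \sum_{i,j} (\hat x_{ij} - x_{ij})^2$ (no
$\tau$ restriction; used for rank selection in `param_sweep()`).

**Leave-one-disease-out.** For each disease, all its associations are
removed from a training copy, the method refit, and the held-out cells
scored; runs are repeated with distinct seeds and accuracy is reported as
mean ± sd over repeats, plus a pooled per-cell mean (both are emitted
because either aggregation is defensible).

The default test set of a fold is the *removed associations* (positive
cells), so fold accuracy is the mean predicted score on the masked
associations. The alternative — scoring the entire held-out column — is
available (`tau = "column"`) but degenerate as a comparison instrument at
realistic sparsity: a predictor that outputs all zeros scores near 1, and
any multiplicative-update NMF zeroes a fully-masked column's coefficients
in one step, so whole-column accuracy collapses to the zero-rate and cannot
separate methods. Scoring the held-out associations keeps the metric
aligned with what the protocol actually hides. Under this default, plain
NMF and label propagation score exactly 0 in leave-one-disease-out (their
masked-column predictions are identically zero), which is precisely the
weakness the path regularizer addresses: the gene–disease layer still
carries signal about the masked disease.

The association networks ($\hat Y$, $\hat Z$, $W^{[g]}$, hence $T$) are
treated as fixed side information across folds — only the association
column is masked — mirroring how such layers come from independent
databases. Temporal external validation (`external_validation()`,
`temporal_split()`) is stricter: the gene–lincRNA layer and path target are
rebuilt from the training snapshot, and a leakage guard rejects any
held-out position that is nonzero in training.

## The synthetic study

`simulate_bundle()` generates instances with planted structure:
exponential (sparse, non-negative) latent factors of rank `r_true`; the
association matrix is the planted score matrix binarized at the quantile
matching the target density (density-targeted binarization keeps instance
difficulty comparable across sizes); the expression profile is the planted
basis times Gaussian loadings plus Gaussian noise, so co-expression
recovers latent proximity; the gene network is random with target density;
gene–disease associations are random; the gene–lincRNA layer is derived
from shared diseases, which is what makes the path target genuinely
correlate with the planted associations; finally a `noise` fraction of
association cells is flipped.

Defaults (60 lincRNAs × 30 diseases, 100 genes, rank 4, densities
0.10/0.10/0.05, noise 0.05, 22 samples) keep a full
leave-one-disease-out comparison in seconds while leaving the planted
structure detectable rather than trivial. What passing tests on these
bundles shows is that the machinery behaves as designed — monotone
optimization, signal recovery, correct protocol accounting. What it does
not show is performance on real databases: the generator has no RNA-seq
count noise, no tissue structure, no disease ontology, and no hub-dominated
degree distributions, and real association matrices are an order of
magnitude sparser.

## Numerical choices and limitations

* **Initialization**: factors are i.i.d. uniform on $(0,1)$ scaled by
  $\sqrt{\overline{\hat x} / r}$ from a seeded generator, so the initial
  reconstruction is on the data scale and every run is bit-reproducible.
* **Zero degrees**: $d^{-1/2} := 0$ for isolated nodes (pseudo-inverse
  convention); their Laplacian rows vanish and they contribute nothing to
  the regularizer.
* **Ties and duplicates** in input files: duplicate association pairs
  collapse to one; conflicting duplicate edge weights take the maximum
  (order-independent); self-loops are dropped; ids sort in C-locale
  lexicographic order so results do not depend on file order.
* **Convergence speed**: multiplicative updates are first-order and slow
  near optima. On exact-rank instances the relative reconstruction error
  typically plateaus around $10^{-3}$–$10^{-2}$ after 500 iterations and
  needs a few thousand iterations to pass below $10^{-3}$; entries pushed
  onto the $B \ge 0$ boundary by the Laplacian term decay only like $1/t$.
  Budgets should be chosen accordingly (the defaults suffice for score
  ranking, not for high-precision reconstruction).
* **Clipping**: predictions are clipped to $[0,1]$ for evaluation against
  binary labels (MAE is only calibrated on the label scale); raw scores
  remain available (`clip = FALSE`).
* **Label propagation** solves
  $(\theta L + (1-\theta) I)X = (1-\theta)\hat X$ directly — exact, unique
  for $\theta < 1$, and equivalent to per-disease propagation because
  disease columns decouple.
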