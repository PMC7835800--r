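# crnmf

Predicting lincRNA–disease associations with co-regularized non-negative
matrix factorization.

Long intergenic non-coding RNAs (lincRNAs) are implicated in many complex
diseases, but validated lincRNA–disease associations are few; computational
prioritization of candidate associations guides which pairs are worth
experimental follow-up. This package is for computational biologists who
have a sparse binary association matrix plus molecular side information —
a lincRNA expression profile, a gene genetic-interaction network, and
gene–disease associations — and want calibrated association scores,
baselines, and a defensible evaluation protocol.

## The model

Given known associations `X̂` (lincRNAs × diseases), the method finds
non-negative factors `B` (lincRNAs × r) and `F` (r × diseases) minimizing

    L(B, F) = ½‖X̂ − BF‖²_F  +  α·Tr(BᵀLB)  +  (β/2)‖BF − T‖²_F,   B, F ≥ 0

where `L = I − D^{−1/2} W D^{−1/2}` is the normalized Laplacian of the
lincRNA co-expression network (latent representations of co-expressed
lincRNAs are pulled together) and `T = ẐᵀW⁽ᵍ⁾Ŷ` accumulates support over
lincRNA → gene → gene-network → disease paths (associations backed by many
molecular paths are favored). Optimization uses multiplicative updates
that provably preserve non-negativity and never increase the objective;
with `α = β = 0` they reduce exactly to classical NMF. Predicted scores
are `BF`, clipped to the label scale `[0, 1]`. Label propagation over the
co-expression network and plain NMF are included as baselines, together
with leave-one-disease-out cross-validation, temporal external validation,
parameter sweeps, and a synthetic heterogeneous-network generator with
planted structure.

See the methods vignette (`vignettes/crnmf-methods.Rmd`) for the full
account: update-rule derivation, parameter meanings, protocol decisions,
and known limitations.

## Worked example

```r
library(crnmf)

bundle <- simulate_bundle(seed = 1)      # synthetic heterogeneous network
bundle
#> crnmf_bundle: 60 lincRNAs x 30 diseases (density 0.139), 100 genes, r_true = 4, noise = 0.05, seed = 1

net <- build_coexpression_network(bundle$expr, threshold = 0.5)
lap <- build_normalized_laplacian(net)
target <- path_target(bundle$z, bundle$gene_net, bundle$y)

cfg <- crnmf_config(r = 4, alpha = 1, beta = 1)
fit <- crnmf_fit(bundle$x, lap, target / max(target), cfg)
fit
#> crnmf_fit: 60 x 30, r = 4, alpha = 1, beta = 1
#>   200 iterations, not converged, objective 156.098 -> 75.8339

loocv(bundle$x, "crnmf", cfg, laplacian = lap, target = target, repeats = 3)
#> crnmf_eval (crnmf): 30 folds x 3 repeats
#>   accuracy 0.1351 +/- 0.0005 (pooled over cells 0.1304)
loocv(bundle$x, "nmf", cfg, repeats = 3)
#> crnmf_eval (nmf): 30 folds x 3 repeats
#>   accuracy 0.0000 +/- 0.0000 (pooled over cells 0.0000)
```

The objective drops monotonically from 156.1 to 75.8 over the 200-iteration
budget. In leave-one-disease-out validation each disease's associations are
masked in turn and the fold's accuracy is the mean predicted score on the
masked associations, so it measures how much signal the model recovers for
a disease it has never seen an association for. Plain NMF scores exactly 0
there — with the column fully masked its multiplicative update zeroes the
disease's coefficients in one step — while the co-regularized model reaches
0.135 ± 0.001 purely through the path and co-expression regularizers. That
gap, not the absolute number (which depends on data density and noise), is
the point of the integration.

A command-line pipeline wraps the same functions (`exec/crnmf`):

```sh
crnmf simulate --seed 1 --out data/
crnmf fit --x data/x.tsv --y data/y.tsv --gene-net data/gene_net.tsv \
      --lincrna-expr data/expr.tsv --r 4 --out fit/
crnmf evaluate-loocv --x data/x.tsv --method nmf --r 4 --tau column --out eval/
```

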