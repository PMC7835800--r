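# Synthetic heterogeneous-network generator with planted low-rank + path
# structure, so every stage of the pipeline is testable without external
# databases.
#
# What it emulates: a binary lincRNA x disease association matrix whose
# positives come from thresholding a planted non-negative low-rank score
# matrix; a lincRNA expression profile whose pairwise correlations track
# similarity of the planted latent rows; a random weighted gene
# genetic-interaction network; random gene-disease associations; and a
# gene-lincRNA association matrix derived from shared diseases, so the
# path-target matrix genuinely correlates with the planted associations.
# What it does NOT emulate: RNA-seq count noise, tissue structure, disease
# ontologies, or the hub-dominated degree distributions of real
# interaction networks.

#' Generate a synthetic heterogeneous-network bundle
#'
#' Plants rank-`r_true` structure: latent factors `b_true` (`n_l x r_true`)
#' and `f_true` (`r_true x n_d`) are drawn from Exp(1) (sparse,
#' non-negative); the score matrix `b_true %*% f_true` is binarized at the
#' quantile hitting `x_density` to give the association matrix `x`; the
#' expression profile is `b_true` times Gaussian loadings plus Gaussian
#' noise (sd `noise`), so co-expression recovers latent proximity; the gene
#' network is a random symmetric graph with edge density `g_density` and
#' Unif(0, 1) weights; `y` is random binary with density `y_density`; `z`
#' is derived from `y` and `x` via [build_gene_lincrna_associations()];
#' finally a fraction `noise` of `x`'s cells is flipped.
#'
#' @param n_l,n_g,n_d Numbers of lincRNAs, genes, diseases. Defaults
#'   (60/100/30) run in seconds; for benchmarks mirroring the relative
#'   shape of curated association databases use e.g. 56/1342/64.
#' @param r_true Planted latent dimension.
#' @param x_density,y_density Target association densities in (0, 1).
#' @param g_density Gene-network edge density in (0, 1).
#' @param noise Fraction of association cells flipped, and the sd of the
#'   additive expression noise; 0 gives a noiseless bundle.
#' @param n_samples Number of expression samples (tissues).
#' @param seed Integer seed; the same seed yields an identical bundle.
#' @return A `crnmf_bundle` list: `x`, `y`, `z`, `gene_net`, `expr`, plus
#'   ground truth `b_true`, `f_true`, `scores_true` (pre-binarization) and
#'   `flipped` (cell positions altered by noise), and the `params` echo.
#' @export
simulate_bundle <- function(n_l = 60L, n_g = 100L, n_d = 30L, r_true = 4L,
                            x_density = 0.10, y_density = 0.10,
                            g_density = 0.05, noise = 0.05,
                            n_samples = 22L, seed = 1L) {
  if (r_true > min(n_l, n_d)) stop_validation("r_true must be <= min(n_l, n_d)")
  for (dens in c(x_density, y_density, g_density)) {
    if (dens <= 0 || dens >= 1) stop_validation("densities must lie in (0, 1)")
  }
  if (noise < 0 || noise > 1) stop_validation("noise must lie in [0, 1]")
  linc_ids <- sprintf("l%03d", seq_len(n_l))
  gene_ids <- sprintf("g%04d", seq_len(n_g))
  dis_ids <- sprintf("d%03d", seq_len(n_d))
  samp_ids <- sprintf("s%02d", seq_len(n_samples))
  with_seed(seed, {
    b_true <- matrix(stats::rexp(n_l * r_true), n_l, r_true,
                     dimnames = list(linc_ids, NULL))
    f_true <- matrix(stats::rexp(r_true * n_d), r_true, n_d,
                     dimnames = list(NULL, dis_ids))
    scores <- b_true %*% f_true
    q <- stats::quantile(scores, 1 - x_density, names = FALSE)
    if (q <= 0 || q >= max(scores)) {
      stop_validation("x_density %.3f is infeasible for the planted scores", x_density)
    }
    x <- (scores > q) * 1
    loadings <- matrix(stats::rnorm(r_true * n_samples), r_true, n_samples)
    expr <- b_true %*% loadings +
      matrix(stats::rnorm(n_l * n_samples, sd = noise), n_l, n_samples)
    dimnames(expr) <- list(linc_ids, samp_ids)
    w <- matrix(0, n_g, n_g, dimnames = list(gene_ids, gene_ids))
    upper <- which(upper.tri(w))
    edges <- upper[stats::runif(length(upper)) < g_density]
    w[edges] <- stats::runif(length(edges))
    w <- w + t(w)
    gene_net <- weighted_network(w, kind = "gene")
    y <- matrix(stats::rbinom(n_g * n_d, 1L, y_density), n_g, n_d,
                dimnames = list(gene_ids, dis_ids))
    z <- build_gene_lincrna_associations(y, x)
    flipped <- NULL
    n_flip <- round(noise * length(x))
    if (n_flip > 0) {
      cells <- sample(length(x), n_flip)
      x[cells] <- 1 - x[cells]
      flipped <- cbind(row = (cells - 1L) %% n_l + 1L,
                       col = (cells - 1L) %/% n_l + 1L)
    }
    structure(list(x = x, y = y, z = z, gene_net = gene_net, expr = expr,
                   b_true = b_true, f_true = f_true, scores_true = scores,
                   flipped = flipped,
                   params = list(n_l = n_l, n_g = n_g, n_d = n_d,
                                 r_true = r_true, x_density = x_density,
                                 y_density = y_density, g_density = g_density,
                                 noise = noise, n_samples = n_samples,
                                 seed = seed)),
              class = "crnmf_bundle")
  })
}

#' @export
print.crnmf_bundle <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "crnmf_bundle: %d lincRNAs x %d diseases (density %.3f), %d genes, r_true = %d, noise = %g, seed = %d\n",
    p$n_l, p$n_d, mean(x$x), p$n_g, p$r_true, p$noise, p$seed))
  invisible(x)
}

#' Hold out a random fraction of associations (temporal-split emulation)
#'
#' Moves a random fraction of the positive cells of the association matrix
#' into a test mask, emulating an external-validation split where
#' later-reported associations are held out. Every disease that has any
#' association keeps at least one training positive (the draw is repeated
#' otherwise).
#'
#' @param x Binary association matrix, or a `crnmf_bundle` (its `x` is
#'   used).
#' @param fraction Fraction of positives to hold out, in (0, 1].
#' @param seed Integer seed.
#' @param max_tries Redraw budget for the keep-one-positive constraint.
#' @return A list: `train` (matrix with held-out cells zeroed) and `mask`
#'   (two-column position matrix of the held-out associations).
#' @export
temporal_split <- function(x, fraction = 0.2, seed = 1L, max_tries = 100L) {
  if (inherits(x, "crnmf_bundle")) x <- x$x
  pos <- which(x == 1, arr.ind = TRUE)
  n_hold <- round(fraction * nrow(pos))
  if (n_hold < 1L) {
    stop_validation("holdout fraction %.3f yields an empty test mask", fraction)
  }
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      take <- sample(nrow(pos), n_hold)
      mask <- pos[take, , drop = FALSE]
      kept <- x
      kept[mask] <- 0
      affected <- unique(mask[, 2])
      if (all(colSums(kept[, affected, drop = FALSE]) >= 1)) {
        colnames(mask) <- c("row", "col")
        return(list(train = kept, mask = mask))
      }
    }
    stop_validation("could not draw a split leaving every disease a training positive (after %d tries)",
                    max_tries)
  })
}

#' Serialize a synthetic bundle to a directory of TSV files
#'
#' Writes `x.tsv`, `y.tsv`, `z.tsv` (labeled matrices), `gene_net.tsv`
#' (edge list) and `expr.tsv` (labeled matrix), so the CLI pipeline can
#' consume generated data exactly like real data.
#'
#' @param bundle A `crnmf_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "crnmf_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_labeled_matrix(bundle$x, file.path(dir, "x.tsv"))
  write_labeled_matrix(bundle$y, file.path(dir, "y.tsv"))
  write_labeled_matrix(bundle$z, file.path(dir, "z.tsv"))
  write_edge_list(bundle$gene_net, file.path(dir, "gene_net.tsv"))
  write_labeled_matrix(bundle$expr, file.path(dir, "expr.tsv"))
  invisible(dir)
}
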