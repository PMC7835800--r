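# Co-regularized NMF: objective, multiplicative updates, optimizer.
#
# Model. Given the binary lincRNA x disease association matrix X, a
# normalized Laplacian L = I_d - Wbar over the lincRNA co-expression
# network, and a path-target matrix T (lincRNA x disease support counted
# over lincRNA -> gene -> gene-network -> disease paths), find non-negative
# factors B (n_l x r) and F (r x n_d) minimizing
#
#   L(B, F) = 1/2 ||X - BF||_F^2 + alpha Tr(B' L B) + beta/2 ||BF - T||_F^2.
#
# Optimization. Alternating multiplicative updates derived from the KKT
# conditions of the objective above:
#
#   dL/dB = (1+beta) B FF' - X F' - beta T F' + 2 alpha L B
#   dL/dF = (1+beta) B'B F - B'X  - beta B'T
#
# with the Laplacian split L B = I_d B - Wbar B routing the non-negative
# pieces to the denominator/numerator, giving updates that preserve
# non-negativity and never increase the objective:
#
#   B <- B * (X F' + beta T F' + 2 alpha Wbar B) /
#            ((1+beta) B FF' + 2 alpha I_d B + eps)
#   F <- F * (B'X + beta B'T) / ((1+beta) B'B F + eps)

#' Cr-NMF configuration
#'
#' @param r Latent dimension (number of features); must satisfy
#'   `r <= min(n_l, n_d)` (a warning is raised at fit time otherwise).
#' @param alpha Weight of the co-expression Laplacian regularizer (>= 0).
#' @param beta Weight of the path regularizer (>= 0).
#' @param max_iter Maximum number of alternating update iterations.
#' @param tol Relative objective-change stopping threshold (> 0).
#' @param seed Integer seed for the factor initialization.
#' @param epsilon Denominator guard added inside every divide (> 0).
#' @param normalize_gene_net Use the degree-normalized gene adjacency in the
#'   path target instead of the raw one.
#' @param clip_predictions Clip predicted scores onto `[0, 1]` (the label
#'   scale) by default in [predict.crnmf_fit()].
#' @param scale_target Rescale the path-target matrix to unit maximum before
#'   fitting in the pipeline drivers, so `beta` is dimensionless (the raw
#'   path-count magnitudes grow with gene-network size).
#' @return A `crnmf_config` list.
#' @export
crnmf_config <- function(r = 4L, alpha = 1, beta = 1, max_iter = 200L,
                         tol = 1e-6, seed = 1L, epsilon = 1e-12,
                         normalize_gene_net = FALSE, clip_predictions = TRUE,
                         scale_target = TRUE) {
  if (!is.numeric(r) || length(r) != 1L || r < 1 || r != as.integer(r)) {
    stop_validation("r must be a positive integer")
  }
  if (alpha < 0 || beta < 0) stop_validation("alpha and beta must be >= 0")
  if (max_iter < 0 || max_iter != as.integer(max_iter)) {
    stop_validation("max_iter must be a non-negative integer")
  }
  if (tol <= 0) stop_validation("tol must be > 0")
  if (epsilon <= 0) stop_validation("epsilon must be > 0")
  structure(list(r = as.integer(r), alpha = alpha, beta = beta,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), epsilon = epsilon,
                 normalize_gene_net = isTRUE(normalize_gene_net),
                 clip_predictions = isTRUE(clip_predictions),
                 scale_target = isTRUE(scale_target)),
            class = "crnmf_config")
}

#' Path-target matrix over lincRNA-gene-gene-disease paths
#'
#' Accumulates, for each (lincRNA j, disease d) pair, the total weight of
#' paths lincRNA j -> gene g -> gene h -> disease d through the gene
#' genetic-interaction network: `T = t(Z) %*% W %*% Y` (lincRNA x disease,
#' all entries >= 0). The more supporting paths, the larger the target
#' score, and the factorization `BF` is regularized toward it.
#'
#' @param z gene x lincRNA binary association matrix.
#' @param gene_net [weighted_network()] over genes.
#' @param y gene x disease binary association matrix.
#' @param normalize Use the degree-normalized adjacency
#'   `D^{-1/2} W D^{-1/2}` instead of the raw weights.
#' @return Numeric lincRNA x disease matrix.
#' @export
path_target <- function(z, gene_net, y, normalize = FALSE) {
  stopifnot(inherits(gene_net, "weighted_network"))
  if (nrow(z) != nrow(gene_net$weights) || nrow(y) != nrow(gene_net$weights)) {
    stop_validation("z, gene_net and y must share the gene index (run align_matrices)")
  }
  w <- if (normalize) {
    build_normalized_laplacian(gene_net)$adjacency_part
  } else {
    gene_net$weights
  }
  tt <- t(z) %*% w %*% y
  dimnames(tt) <- list(colnames(z), colnames(y))
  tt
}

# Rescale a path target onto the label scale (unit maximum); no-op on an
# all-zero target.
scale_unit <- function(target) {
  m <- max(target)
  if (m > 0) target / m else target
}

#' Cr-NMF objective value
#'
#' Evaluates
#' `0.5 * ||x_hat - B F||_F^2 + alpha * Tr(B' L B) + 0.5 * beta * ||B F - target||_F^2`
#' with `L = identity_part - adjacency_part`.
#'
#' @param x_hat Observed association matrix.
#' @param B,F Non-negative factors (`n_l x r`, `r x n_d`).
#' @param laplacian A `normalized_laplacian` over the lincRNAs (required
#'   when `alpha > 0`).
#' @param target Path-target matrix (required when `beta > 0`).
#' @param alpha,beta Regularization weights.
#' @return A finite scalar.
#' @export
crnmf_objective <- function(x_hat, B, F, laplacian = NULL, target = NULL,
                            alpha = 0, beta = 0) {
  check_matrix_finite(x_hat, "x_hat")
  check_matrix_finite(B, "B")
  check_matrix_finite(F, "F")
  bf <- B %*% F
  obj <- 0.5 * sum((x_hat - bf)^2)
  if (alpha > 0) {
    lb <- laplacian$identity_part %*% B - laplacian$adjacency_part %*% B
    obj <- obj + alpha * sum(B * lb)
  }
  if (beta > 0) {
    check_matrix_finite(target, "target")
    obj <- obj + 0.5 * beta * sum((bf - target)^2)
  }
  if (!is.finite(obj)) stop_numeric("objective is non-finite")
  obj
}

#' One multiplicative update of the basis matrix B
#'
#' `B <- B * (X F' + beta T F' + 2 alpha Wbar B) /
#'          ((1+beta) B FF' + 2 alpha I_d B + epsilon)`.
#' Preserves non-negativity and never increases the objective. An all-zero
#' row of `B` stays zero (absorbing under multiplicative updates).
#'
#' @inheritParams crnmf_objective
#' @param epsilon Denominator guard.
#' @return Updated `B`.
#' @export
crnmf_update_b <- function(B, F, x_hat, laplacian = NULL, target = NULL,
                           alpha = 0, beta = 0, epsilon = 1e-12) {
  num <- x_hat %*% t(F)
  den <- (1 + beta) * (B %*% (F %*% t(F)))
  if (beta > 0) num <- num + beta * (target %*% t(F))
  if (alpha > 0) {
    num <- num + 2 * alpha * (laplacian$adjacency_part %*% B)
    den <- den + 2 * alpha * (laplacian$identity_part %*% B)
  }
  B * num / (den + epsilon)
}

#' One multiplicative update of the feature matrix F
#'
#' `F <- F * (B'X + beta B'T) / ((1+beta) B'B F + epsilon)`.
#'
#' @inheritParams crnmf_update_b
#' @return Updated `F`.
#' @export
crnmf_update_f <- function(B, F, x_hat, target = NULL, beta = 0,
                           epsilon = 1e-12) {
  num <- t(B) %*% x_hat
  den <- (1 + beta) * ((t(B) %*% B) %*% F)
  if (beta > 0) num <- num + beta * (t(B) %*% target)
  F * num / (den + epsilon)
}

# Seeded initialization: i.i.d. uniform(0, 1) entries scaled by
# sqrt(mean(x_hat) / r), so B %*% F starts on the scale of x_hat.
init_factors <- function(x_hat, r, seed, epsilon) {
  n_l <- nrow(x_hat); n_d <- ncol(x_hat)
  s <- sqrt(max(mean(x_hat), epsilon) / r)
  with_seed(seed, {
    B <- matrix(stats::runif(n_l * r), n_l, r) * s
    F <- matrix(stats::runif(r * n_d), r, n_d) * s
    list(B = B, F = F)
  })
}

#' Fit the co-regularized NMF model
#'
#' Alternates [crnmf_update_b()] and [crnmf_update_f()] from a seeded random
#' non-negative initialization, recording the objective at every iteration
#' (including iteration 0), and stops when the relative objective change
#' falls below `config$tol` or `config$max_iter` is reached. The trajectory
#' is monotone non-increasing. The same seed yields a bit-identical fit.
#'
#' @param x_hat Observed lincRNA x disease association matrix (binary).
#' @param laplacian `normalized_laplacian` over the lincRNAs; required when
#'   `config$alpha > 0`.
#' @param target Path-target matrix (see [path_target()]); required when
#'   `config$beta > 0`. Passed as-is: rescaling (see `scale_target`) is the
#'   caller's responsibility and is applied by the pipeline drivers.
#' @param config A [crnmf_config()].
#' @return A `crnmf_fit` object: list with non-negative factors `B`
#'   (`n_l x r`) and `F` (`r x n_d`), the per-iteration `objective` vector,
#'   `iterations`, `converged`, and the `config` echo.
#' @export
crnmf_fit <- function(x_hat, laplacian = NULL, target = NULL,
                      config = crnmf_config()) {
  stopifnot(inherits(config, "crnmf_config"), is.matrix(x_hat))
  check_matrix_finite(x_hat, "x_hat")
  if (any(x_hat < 0)) stop_validation("x_hat must be non-negative")
  alpha <- config$alpha; beta <- config$beta
  if (alpha > 0 && !inherits(laplacian, "normalized_laplacian")) {
    stop_validation("alpha > 0 requires a normalized_laplacian")
  }
  if (beta > 0) {
    if (is.null(target)) stop_validation("beta > 0 requires a path target")
    check_matrix_finite(target, "target")
    if (!identical(dim(target), dim(x_hat))) {
      stop_validation("target must have the shape of x_hat")
    }
  }
  if (config$r > min(dim(x_hat))) {
    warning(sprintf("r = %d exceeds min(n_l, n_d) = %d; the factorization is overcomplete",
                    config$r, min(dim(x_hat))))
  }
  fac <- init_factors(x_hat, config$r, config$seed, config$epsilon)
  B <- fac$B; F <- fac$F
  obj <- crnmf_objective(x_hat, B, F, laplacian, target, alpha, beta)
  converged <- FALSE
  iterations <- 0L
  if (config$max_iter > 0L) {
    for (t in seq_len(config$max_iter)) {
      B <- crnmf_update_b(B, F, x_hat, laplacian, target, alpha, beta,
                          config$epsilon)
      F <- crnmf_update_f(B, F, x_hat, target, beta, config$epsilon)
      if (!all(is.finite(B)) || !all(is.finite(F))) {
        stop_numeric("non-finite factor entries at iteration %d", t)
      }
      o <- crnmf_objective(x_hat, B, F, laplacian, target, alpha, beta)
      obj <- c(obj, o)
      iterations <- t
      prev <- obj[t]
      if (abs(o - prev) / max(prev, config$epsilon) < config$tol) {
        converged <- TRUE
        break
      }
    }
  }
  rownames(B) <- rownames(x_hat)
  colnames(F) <- colnames(x_hat)
  structure(list(B = B, F = F, objective = obj, iterations = iterations,
                 converged = converged, config = config,
                 dimnames = dimnames(x_hat)),
            class = "crnmf_fit")
}

#' @export
print.crnmf_fit <- function(x, ...) {
  cat(sprintf(
    "crnmf_fit: %d x %d, r = %d, alpha = %g, beta = %g\n  %d iterations, %s, objective %.6g -> %.6g\n",
    nrow(x$B), ncol(x$F), x$config$r, x$config$alpha, x$config$beta,
    x$iterations, if (x$converged) "converged" else "not converged",
    x$objective[1], x$objective[length(x$objective)]))
  invisible(x)
}

#' Predicted association scores from fitted factors
#'
#' Returns `B %*% F`, by default clipped onto `[0, 1]` so scores live on the
#' label scale of the binary association matrix; raw scores are available
#' with `clip = FALSE`.
#'
#' @param object A `crnmf_fit`.
#' @param clip Clip scores to `[0, 1]`; defaults to the fit's
#'   `clip_predictions` config.
#' @param ... Ignored.
#' @return Real-valued lincRNA x disease score matrix, labels carried from
#'   the training matrix.
#' @export
predict.crnmf_fit <- function(object, clip = object$config$clip_predictions,
                              ...) {
  scores <- object$B %*% object$F
  if (isTRUE(clip)) scores <- clip01(scores)
  dimnames(scores) <- object$dimnames
  scores
}
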