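# Evaluation: MAE / Accuracy / RMSE / RSS, leave-one-disease-out
# cross-validation, temporal external validation, and parameter sweeps.
#
# A test mask is a two-column integer matrix of (row, col) positions — the
# test set tau over which MAE, Accuracy and RMSE are averaged. RSS is
# defined over ALL cells of the matrix (no tau restriction) and is the
# quantity used for rank selection.

as_test_mask <- function(mask, dims) {
  mask <- as.matrix(mask)
  if (ncol(mask) != 2L || nrow(mask) == 0L) {
    stop_validation("test mask must be a non-empty two-column (row, col) matrix")
  }
  storage.mode(mask) <- "integer"
  if (any(mask[, 1] < 1L) || any(mask[, 1] > dims[1]) ||
      any(mask[, 2] < 1L) || any(mask[, 2] > dims[2])) {
    stop_validation("test mask positions out of matrix bounds")
  }
  colnames(mask) <- c("row", "col")
  mask
}

#' Mean absolute error over a test mask
#'
#' `MAE = mean(|observed - predicted|)` over the mask positions only.
#'
#' @param observed,predicted Matrices of identical shape.
#' @param mask Two-column (row, col) position matrix defining the test set.
#' @return A scalar in `[0, Inf)`.
#' @export
eval_mae <- function(observed, predicted, mask) {
  stopifnot(identical(dim(observed), dim(predicted)))
  mask <- as_test_mask(mask, dim(observed))
  mean(abs(observed[mask] - predicted[mask]))
}

#' Accuracy over a test mask
#'
#' `Accuracy = 1 - MAE`, exactly.
#'
#' @inheritParams eval_mae
#' @return A scalar.
#' @export
eval_accuracy <- function(observed, predicted, mask) {
  1 - eval_mae(observed, predicted, mask)
}

#' Root mean squared error over a test mask
#'
#' @inheritParams eval_mae
#' @return A scalar in `[0, Inf)`.
#' @export
eval_rmse <- function(observed, predicted, mask) {
  stopifnot(identical(dim(observed), dim(predicted)))
  mask <- as_test_mask(mask, dim(observed))
  sqrt(mean((observed[mask] - predicted[mask])^2))
}

#' Residual sum of squares over the full matrix
#'
#' `RSS = sum((observed - predicted)^2)` over every cell (no test-mask
#' restriction); used for rank selection.
#'
#' @param observed,predicted Matrices of identical shape.
#' @return A scalar in `[0, Inf)`.
#' @export
eval_rss <- function(observed, predicted) {
  stopifnot(identical(dim(observed), dim(predicted)))
  sum((observed - predicted)^2)
}

# Fit the requested method on a training matrix and return a score matrix.
# `external_scores` stands in for methods defined outside the package.
score_method <- function(method, train, laplacian, target, config, theta,
                         seed, external_scores) {
  switch(method,
    crnmf = {
      cfg <- config; cfg$seed <- as.integer(seed)
      predict(crnmf_fit(train, laplacian, target, cfg))
    },
    nmf = {
      cfg <- config; cfg$seed <- as.integer(seed)
      predict(plain_nmf(train, cfg))
    },
    lp = label_propagation(train, laplacian, theta = theta),
    external = {
      if (is.null(external_scores)) {
        stop_validation("method 'external' requires external_scores")
      }
      external_scores
    },
    stop_validation("unknown method '%s'", method)
  )
}

fold_metrics <- function(observed, predicted, mask) {
  c(mae = eval_mae(observed, predicted, mask),
    accuracy = eval_accuracy(observed, predicted, mask),
    rmse = eval_rmse(observed, predicted, mask))
}

#' Leave-one-disease-out cross-validation
#'
#' For each disease column `d`, all its associations are removed from a
#' training copy of `x_hat`, the method is refit, and the held-out cells
#' are scored: fold `d`'s test set is either the removed associations (the
#' positive cells of column `d`; default) or the entire column. Folds with
#' no test cells are skipped. The run is repeated `repeats` times with
#' seeds `config$seed, config$seed + 1, ...` and accuracy is aggregated as
#' mean over fold means (sd across repeats) plus a pooled per-cell mean.
#'
#' The association networks behind the path target are treated as fixed
#' side information: `laplacian` and `target` are not recomputed per fold,
#' only the association column is masked.
#'
#' @param x_hat Binary lincRNA x disease association matrix.
#' @param method One of `"crnmf"`, `"nmf"`, `"lp"`, `"external"`.
#' @param config A [crnmf_config()] (factorization methods).
#' @param laplacian `normalized_laplacian` over the lincRNAs (needed by
#'   `"crnmf"` and `"lp"`).
#' @param target Path-target matrix (needed by `"crnmf"`); rescaled to unit
#'   maximum when `config$scale_target` is set.
#' @param theta Label-propagation weight.
#' @param repeats Number of repeated runs with distinct seeds.
#' @param external_scores Fixed score matrix for `method = "external"`.
#' @param tau `"positives"` (test set = the removed associations) or
#'   `"column"` (test set = every cell of the held-out column).
#' @param per_cell If `TRUE`, leave one positive cell out at a time instead
#'   of a whole disease column (one fold per association; expensive).
#' @return A `crnmf_eval` report: `per_fold` data frame (repeat, fold,
#'   disease, n_test, mae, accuracy, rmse) and an `aggregate` list with
#'   `accuracy_mean`, `accuracy_sd` (across repeats), `accuracy_pooled`
#'   (cell-weighted), and `n_folds`.
#' @export
loocv <- function(x_hat, method = c("crnmf", "nmf", "lp", "external"),
                  config = crnmf_config(), laplacian = NULL, target = NULL,
                  theta = 0.5, repeats = 1L, external_scores = NULL,
                  tau = c("positives", "column"), per_cell = FALSE) {
  method <- match.arg(method)
  tau <- match.arg(tau)
  if (repeats < 1L) stop_validation("repeats must be >= 1")
  if (!is.null(target) && isTRUE(config$scale_target)) {
    target <- scale_unit(target)
  }
  folds <- if (per_cell) {
    pos <- which(x_hat == 1, arr.ind = TRUE)
    if (nrow(pos) == 0L) stop_validation("x_hat has no associations to hold out")
    lapply(seq_len(nrow(pos)), function(i) {
      list(id = i, disease = colnames(x_hat)[pos[i, 2]],
           cells = pos[i, , drop = FALSE])
    })
  } else {
    lapply(seq_len(ncol(x_hat)), function(d) {
      rows <- if (tau == "positives") which(x_hat[, d] == 1) else seq_len(nrow(x_hat))
      list(id = d, disease = colnames(x_hat)[d],
           cells = if (length(rows)) cbind(rows, d) else NULL)
    })
  }
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    seed_i <- config$seed + rep_i - 1L
    for (f in folds) {
      if (is.null(f$cells)) next  # disease with no held-out cells
      train <- x_hat
      if (per_cell) train[f$cells] <- 0 else train[, f$id] <- 0
      scores <- score_method(method, train, laplacian, target, config, theta,
                             seed_i, external_scores)
      met <- fold_metrics(x_hat, scores, f$cells)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = rep_i, fold = f$id,
        disease = if (is.null(f$disease)) NA_character_ else f$disease,
        n_test = nrow(f$cells), mae = met["mae"], accuracy = met["accuracy"],
        rmse = met["rmse"], row.names = NULL)
    }
  }
  per_fold <- do.call(rbind, rows)
  if (is.null(per_fold)) stop_validation("no evaluable folds (no associations?)")
  by_rep <- tapply(per_fold$accuracy, per_fold$repeat_id, mean)
  aggregate <- list(
    accuracy_mean = mean(by_rep),
    accuracy_sd = if (repeats > 1L) stats::sd(by_rep) else NA_real_,
    accuracy_pooled = sum(per_fold$accuracy * per_fold$n_test) /
      sum(per_fold$n_test),
    n_folds = length(unique(per_fold$fold))
  )
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 method = method, tau = tau, repeats = repeats),
            class = "crnmf_eval")
}

#' @export
print.crnmf_eval <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "crnmf_eval (%s): %d folds x %d repeats\n  accuracy %.4f%s (pooled over cells %.4f)\n",
    x$method, a$n_folds, x$repeats, a$accuracy_mean,
    if (is.na(a$accuracy_sd)) "" else sprintf(" +/- %.4f", a$accuracy_sd),
    a$accuracy_pooled))
  invisible(x)
}

#' Temporal external validation
#'
#' Fits the method on the training association matrix and evaluates on a
#' held-out set of association positions (e.g. associations reported after
#' the training snapshot). The held-out positions must be zero in the
#' training matrix (leakage guard); the observed value at every held-out
#' position is 1, since the test set is a set of true associations.
#'
#' @param train Training association matrix (held-out cells zeroed).
#' @param test_mask Two-column (row, col) matrix of held-out association
#'   positions.
#' @inheritParams loocv
#' @return A single-fold `crnmf_eval` report.
#' @export
external_validation <- function(train, test_mask,
                                method = c("crnmf", "nmf", "lp", "external"),
                                config = crnmf_config(), laplacian = NULL,
                                target = NULL, theta = 0.5,
                                external_scores = NULL) {
  method <- match.arg(method)
  test_mask <- as_test_mask(test_mask, dim(train))
  if (any(train[test_mask] != 0)) {
    stop_validation("leakage: %d held-out positions are nonzero in the training matrix",
                    sum(train[test_mask] != 0))
  }
  if (!is.null(target) && isTRUE(config$scale_target)) {
    target <- scale_unit(target)
  }
  observed <- train
  observed[test_mask] <- 1
  scores <- score_method(method, train, laplacian, target, config, theta,
                         config$seed, external_scores)
  met <- fold_metrics(observed, scores, test_mask)
  per_fold <- data.frame(repeat_id = 1L, fold = 1L, disease = NA_character_,
                         n_test = nrow(test_mask), mae = met["mae"],
                         accuracy = met["accuracy"], rmse = met["rmse"],
                         row.names = NULL)
  structure(list(per_fold = per_fold,
                 aggregate = list(accuracy_mean = met[["accuracy"]],
                                  accuracy_sd = NA_real_,
                                  accuracy_pooled = met[["accuracy"]],
                                  n_folds = 1L),
                 method = method, tau = "positives", repeats = 1L),
            class = "crnmf_eval")
}

#' Parameter sweep driver
#'
#' Refits the model at each grid value of one tunable — latent dimension
#' `r`, the tied regularization weights `alpha_beta`, or the iteration
#' budget `iterations` — and records reconstruction quality: full-matrix
#' RSS of the (unclipped) reconstruction, plus MAE and RMSE of the clipped
#' scores over all cells, the final objective, and the iteration count.
#'
#' @param param One of `"r"`, `"alpha_beta"`, `"iterations"`.
#' @param grid Numeric vector of values to sweep.
#' @param x_hat Association matrix.
#' @param laplacian,target Side information as in [crnmf_fit()]; `target`
#'   is rescaled per `config$scale_target`.
#' @param config Base [crnmf_config()]; one field is overridden per grid
#'   point, everything else (including the seed) held fixed.
#' @return A data frame: `param`, `value`, `rss`, `mae`, `rmse`,
#'   `objective`, `iterations`, `converged`.
#' @export
param_sweep <- function(param = c("r", "alpha_beta", "iterations"), grid,
                        x_hat, laplacian = NULL, target = NULL,
                        config = crnmf_config()) {
  param <- match.arg(param)
  if (!length(grid)) stop_validation("empty sweep grid")
  if (!is.null(target) && isTRUE(config$scale_target)) {
    target <- scale_unit(target)
    config$scale_target <- FALSE  # already applied
  }
  all_cells <- as.matrix(expand.grid(row = seq_len(nrow(x_hat)),
                                     col = seq_len(ncol(x_hat))))
  out <- lapply(grid, function(v) {
    cfg <- config
    if (param == "r") cfg$r <- as.integer(v)
    if (param == "alpha_beta") { cfg$alpha <- v; cfg$beta <- v }
    if (param == "iterations") cfg$max_iter <- as.integer(v)
    fit <- crnmf_fit(x_hat, laplacian, target, cfg)
    recon <- predict(fit, clip = FALSE)
    clipped <- clip01(recon)
    data.frame(param = param, value = v,
               rss = eval_rss(x_hat, recon),
               mae = eval_mae(x_hat, clipped, all_cells),
               rmse = eval_rmse(x_hat, clipped, all_cells),
               objective = fit$objective[length(fit$objective)],
               iterations = fit$iterations, converged = fit$converged)
  })
  do.call(rbind, out)
}

#' Write an evaluation report as TSV files
#'
#' Emits `per_fold.tsv` (one row per fold x repeat) and `summary.tsv`
#' (aggregate accuracy) into a directory.
#'
#' @param report A `crnmf_eval`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "crnmf_eval"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$per_fold, file.path(dir, "per_fold.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  a <- report$aggregate
  utils::write.table(
    data.frame(method = report$method, tau = report$tau,
               repeats = report$repeats, n_folds = a$n_folds,
               accuracy_mean = a$accuracy_mean, accuracy_sd = a$accuracy_sd,
               accuracy_pooled = a$accuracy_pooled),
    file.path(dir, "summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
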