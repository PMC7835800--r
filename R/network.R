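# Construction of the lincRNA co-expression network, the gene-lincRNA
# association matrix, and normalized graph Laplacians.

#' Build a co-expression network from an expression profile
#'
#' Computes absolute Pearson correlation between every pair of entity rows
#' and keeps edges whose `|r|` reaches `threshold`; edge weight is `|r|`
#' itself (non-negative, as the Laplacian regularizer requires), the
#' diagonal is zero. Rows with zero variance get no edges.
#'
#' @param expr Numeric matrix, entities x samples, with dimnames; at least
#'   two samples.
#' @param threshold Correlation cutoff in `[0, 1]`; default 0.5.
#' @param kind Entity kind of the rows.
#' @return A [weighted_network()] over the rows of `expr`.
#' @export
build_coexpression_network <- function(expr, threshold = 0.5,
                                       kind = "lincRNA") {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2L) stop_validation("co-expression needs >= 2 samples")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop_validation("threshold must be a single value in [0, 1]")
  }
  check_matrix_finite(expr, "expression matrix")
  r <- suppressWarnings(stats::cor(t(expr)))  # zero-variance rows give NA
  w <- abs(r)
  w[is.na(w)] <- 0
  w[w < threshold] <- 0
  diag(w) <- 0
  w <- (w + t(w)) / 2  # kill asymmetry at machine precision
  dimnames(w) <- list(rownames(expr), rownames(expr))
  weighted_network(w, kind = kind)
}

#' Derive gene-lincRNA associations from shared diseases
#'
#' A gene and a lincRNA are associated (`z[i, j] = 1`) when both are
#' associated with at least one common disease: `z = 1(Y %*% t(X) > 0)`.
#' Both inputs must carry identical disease columns (align first).
#'
#' @param y gene x disease binary association matrix.
#' @param x lincRNA x disease binary association matrix.
#' @return Binary gene x lincRNA matrix.
#' @export
build_gene_lincrna_associations <- function(y, x) {
  if (!identical(colnames(y), colnames(x))) {
    stop_validation("disease columns of y and x must be identical (run align_matrices)")
  }
  z <- (y %*% t(x) > 0) * 1
  dimnames(z) <- list(rownames(y), rownames(x))
  z
}

#' Build the normalized graph Laplacian
#'
#' For adjacency `W` with degrees `d`, the normalized Laplacian is
#' `L = I - D^{-1/2} W D^{-1/2}`. It is stored as its two non-negative
#' parts — `identity_part` (1 on the diagonal exactly for nonzero-degree
#' nodes) and `adjacency_part` (`D^{-1/2} W D^{-1/2}`) — because the
#' multiplicative update must route the positive and negative gradient
#' contributions of the Laplacian to opposite sides of the ratio. Zero
#' degrees use the pseudo-inverse convention `d^{-1/2} = 0`, so isolated
#' nodes contribute nothing to the regularizer.
#'
#' @param net A [weighted_network()].
#' @return A `normalized_laplacian` object: list with `identity_part`,
#'   `adjacency_part` (both square, ids as dimnames).
#' @export
build_normalized_laplacian <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  d <- net$degree
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  adjacency <- net$weights * outer(dinv, dinv)
  identity <- diag(as.numeric(d > 0), nrow = length(d))
  dimnames(adjacency) <- dimnames(identity) <- dimnames(net$weights)
  structure(list(identity_part = identity, adjacency_part = adjacency),
            class = "normalized_laplacian")
}

#' @export
print.normalized_laplacian <- function(x, ...) {
  cat(sprintf("normalized_laplacian: %d nodes (%d isolated)\n",
              nrow(x$identity_part), sum(diag(x$identity_part) == 0)))
  invisible(x)
}

# Dense L = identity_part - adjacency_part (internal).
laplacian_matrix <- function(lap) lap$identity_part - lap$adjacency_part
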