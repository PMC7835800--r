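# Labeled-matrix data model and TSV readers/writers.
#
# Conventions used throughout the package:
#   * association matrices are base matrices with entity ids as dimnames
#     (rows = one entity kind, columns = another); known associations are
#     binary, predictions real-valued in [0, 1];
#   * weighted networks are `weighted_network` objects (symmetric
#     non-negative adjacency, zero diagonal, cached degrees);
#   * files carry string ids only, never positions; all internal indices
#     are positional and stable within a run.

read_data_lines <- function(path) {
  if (!file.exists(path)) stop_file("file not found: %s", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  if (!any(keep)) stop_parse("%s: empty file (no data lines)", path)
  list(lines = raw[keep], lineno = which(keep))
}

#' Read a binary association pair list
#'
#' Parses a TSV pair list (one association per line: `rowId<TAB>colId`, with
#' an optional third weight column that is ignored for the binary role) into
#' a binary association matrix over the union of observed identifiers, with
#' ids sorted lexicographically. Duplicate pairs collapse to a single 1.
#' Lines starting with `#` are comments.
#'
#' @param path Path to a TSV file.
#' @param row_kind,col_kind Entity kinds (`"lincRNA"`, `"gene"`,
#'   `"disease"`); used only for error messages and documentation of intent.
#' @return A binary matrix with row/column ids as dimnames.
#' @export
read_association_pairs <- function(path, row_kind = "lincRNA",
                                   col_kind = "disease") {
  dat <- read_data_lines(path)
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop_parse("%s: line %d: expected 2-3 tab-separated fields, got %d",
               path, dat$lineno[bad[1]], nf[bad[1]])
  }
  rows_id <- vapply(fields, `[[`, "", 1L)
  cols_id <- vapply(fields, `[[`, "", 2L)
  if (any(rows_id == "" | cols_id == "")) {
    i <- which(rows_id == "" | cols_id == "")[1]
    stop_parse("%s: line %d: empty identifier", path, dat$lineno[i])
  }
  rids <- sort_ids(rows_id)
  cids <- sort_ids(cols_id)
  m <- matrix(0, length(rids), length(cids), dimnames = list(rids, cids))
  m[cbind(match(rows_id, rids), match(cols_id, cids))] <- 1
  m
}

#' Write an association matrix as a pair list
#'
#' Emits one `rowId<TAB>colId` line per nonzero cell, in row-major order of
#' the (lexicographically sorted) ids.
#'
#' @param x Association matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_association_pairs <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  idx <- which(x != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  writeLines(paste(rownames(x)[idx[, 1]], colnames(x)[idx[, 2]], sep = "\t"),
             path)
  invisible(path)
}

#' Construct a weighted network
#'
#' Validates and wraps a symmetric non-negative adjacency matrix with zero
#' diagonal, caching node degrees (row sums of weights).
#'
#' @param weights Square numeric matrix with ids as dimnames; symmetric
#'   within `1e-10`, all entries `>= 0`, zero diagonal.
#' @param kind Entity kind of the nodes.
#' @return A `weighted_network` object (list with `kind`, `weights`,
#'   `degree`).
#' @export
weighted_network <- function(weights, kind = "lincRNA") {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights)) {
    stop_validation("weights must be a square matrix")
  }
  if (is.null(rownames(weights))) {
    rownames(weights) <- colnames(weights) <- sprintf("n%d", seq_len(nrow(weights)))
  }
  if (!identical(rownames(weights), colnames(weights))) {
    stop_validation("row and column ids of a network must match")
  }
  check_matrix_finite(weights, "network weights")
  if (any(weights < 0)) stop_validation("network weights must be non-negative")
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop_validation("network weights must be symmetric (tolerance 1e-10)")
  }
  if (any(diag(weights) != 0)) stop_validation("network diagonal must be zero")
  structure(list(kind = kind, weights = weights, degree = rowSums(weights)),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network<%s>: %d nodes, %d edges, mean degree %.3f\n",
              x$kind, nrow(x$weights), sum(x$weights[upper.tri(x$weights)] > 0),
              mean(x$degree)))
  invisible(x)
}

#' Read a weighted edge list
#'
#' Parses a TSV edge list (`idA<TAB>idB<TAB>weight`) into a symmetric
#' [weighted_network()]. An edge listed once is mirrored; conflicting
#' duplicate weights resolve to the maximum; self-loops are dropped.
#'
#' @param path Path to a TSV file.
#' @param kind Entity kind of the nodes.
#' @return A `weighted_network`.
#' @export
read_edge_list <- function(path, kind = "gene") {
  dat <- read_data_lines(path)
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 3L)
  if (length(bad)) {
    stop_parse("%s: line %d: expected 3 tab-separated fields, got %d",
               path, dat$lineno[bad[1]], nf[bad[1]])
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(w)) {
    stop_parse("%s: line %d: non-numeric weight", path, dat$lineno[which(is.na(w))[1]])
  }
  if (any(w < 0)) {
    stop_validation("%s: line %d: negative weight", path, dat$lineno[which(w < 0)[1]])
  }
  ids <- sort_ids(c(a, b))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ia <- match(a, ids); ib <- match(b, ids)
  for (k in seq_along(ia)) {
    if (ia[k] == ib[k]) next  # self-loop dropped
    cur <- m[ia[k], ib[k]]
    m[ia[k], ib[k]] <- m[ib[k], ia[k]] <- max(cur, w[k])
  }
  weighted_network(m, kind = kind)
}

#' Write a network as an edge list
#'
#' One line per nonzero upper-triangle edge: `idA<TAB>idB<TAB>weight`.
#' Weights are printed with full precision (`format(..., digits = 17)`) so a
#' write/read round trip reproduces values exactly.
#'
#' @param net A `weighted_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  writeLines(paste(rownames(w)[idx[, 1]], colnames(w)[idx[, 2]],
                   format(w[idx], digits = 17, scientific = FALSE, trim = TRUE),
                   sep = "\t"),
             path)
  invisible(path)
}

#' Read a labeled real-valued matrix (expression profile)
#'
#' Parses a TSV with sample names in the first row and entity ids in the
#' first column; remaining cells must be real-valued. Entity order is
#' preserved from the file.
#'
#' @param path Path to a TSV file.
#' @param kind Entity kind of the rows.
#' @return A numeric matrix (entities x samples) with dimnames.
#' @export
read_expression_matrix <- function(path, kind = "lincRNA") {
  dat <- read_data_lines(path)
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  if (!length(body)) stop_parse("%s: no data rows", path)
  nf <- lengths(body)
  # header may or may not carry a corner label for the id column
  n_samp <- if (length(header) == nf[1]) length(header) - 1L else length(header)
  samples <- utils::tail(header, n_samp)
  bad <- which(nf != n_samp + 1L)
  if (length(bad)) {
    stop_parse("%s: line %d: ragged row (%d fields, expected %d)",
               path, dat$lineno[bad[1] + 1L], nf[bad[1]], n_samp + 1L)
  }
  ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop_parse("%s: duplicate entity id '%s'", path, ids[duplicated(ids)][1])
  }
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(n_samp))
  )
  vals <- if (n_samp == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(vals)) {
    i <- which(apply(is.na(vals), 1, any))[1]
    stop_parse("%s: line %d: missing or non-numeric cell in row '%s'",
               path, dat$lineno[i + 1L], ids[i])
  }
  dimnames(vals) <- list(ids, samples)
  vals
}

#' Write a labeled matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: sample/column names in the first
#' row (with an `id` corner cell), entity ids in the first column, cells at
#' full precision.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labeled_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  lines <- c(paste(c("id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i],
                       format(m[i, ], digits = 17, scientific = FALSE,
                              trim = TRUE)),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

subset_network <- function(net, ids) {
  weighted_network(net$weights[ids, ids, drop = FALSE], kind = net$kind)
}

#' Align the heterogeneous-network inputs to shared entity sets
#'
#' Reindexes the five inputs to the lexicographically sorted intersections
#' of their entity sets: lincRNAs = rows of `x` intersected with the
#' lincRNA-network nodes and the columns of `z`; genes = rows of `y`
#' intersected with the gene-network nodes and the rows of `z`; diseases =
#' columns of `x` intersected with columns of `y`. After alignment the
#' products `t(Z) %*% W %*% Y` and `B %*% F` are conformable. Alignment is
#' idempotent.
#'
#' @param x lincRNA x disease association matrix.
#' @param y gene x disease association matrix.
#' @param z gene x lincRNA association matrix.
#' @param gene_net `weighted_network` over genes.
#' @param lincrna_net `weighted_network` over lincRNAs.
#' @return A list with the five aligned objects, named as the arguments.
#' @export
align_matrices <- function(x, y, z, gene_net, lincrna_net) {
  lincs <- sort_ids(intersect(intersect(rownames(x), rownames(lincrna_net$weights)),
                              colnames(z)))
  genes <- sort_ids(intersect(intersect(rownames(y), rownames(gene_net$weights)),
                              rownames(z)))
  diseases <- sort_ids(intersect(colnames(x), colnames(y)))
  if (!length(lincs)) stop_validation("alignment failed: empty lincRNA intersection")
  if (!length(genes)) stop_validation("alignment failed: empty gene intersection")
  if (!length(diseases)) stop_validation("alignment failed: empty disease intersection")
  list(
    x = x[lincs, diseases, drop = FALSE],
    y = y[genes, diseases, drop = FALSE],
    z = z[genes, lincs, drop = FALSE],
    gene_net = subset_network(gene_net, genes),
    lincrna_net = subset_network(lincrna_net, lincs)
  )
}
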