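# Brute-force oracles, coded independently of the package internals:
# explicit element-wise loops only, no shared helpers with R/.

# Pearson correlation of two vectors from the raw sum formula.
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# Thresholded absolute-correlation adjacency by pairwise loop.
oracle_coexpression <- function(expr, threshold) {
  n <- nrow(expr)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- abs(oracle_pearson(expr[i, ], expr[j, ]))
    if (!is.na(r) && r >= threshold) w[i, j] <- r
  }
  w
}

# z[i, j] = 1 iff gene i and lincRNA j share a disease; triple loop.
oracle_gene_lincrna <- function(y, x) {
  z <- matrix(0, nrow(y), nrow(x))
  for (i in seq_len(nrow(y))) for (j in seq_len(nrow(x))) {
    for (k in seq_len(ncol(y))) {
      if (y[i, k] == 1 && x[j, k] == 1) { z[i, j] <- 1; break }
    }
  }
  z
}

# Path-target entry t[j, d] by enumerating lincRNA -> gene -> gene ->
# disease paths.
oracle_path_target <- function(z, w, y) {
  n_l <- ncol(z); n_d <- ncol(y); n_g <- nrow(z)
  tt <- matrix(0, n_l, n_d)
  for (j in seq_len(n_l)) for (d in seq_len(n_d)) {
    acc <- 0
    for (g in seq_len(n_g)) for (h in seq_len(n_g)) {
      acc <- acc + z[g, j] * w[g, h] * y[h, d]
    }
    tt[j, d] <- acc
  }
  tt
}

# Objective by element-wise loops.
oracle_objective <- function(x, B, F, L, target, alpha, beta) {
  n_l <- nrow(x); n_d <- ncol(x); r <- ncol(B)
  recon <- matrix(0, n_l, n_d)
  for (i in seq_len(n_l)) for (j in seq_len(n_d)) {
    for (k in seq_len(r)) recon[i, j] <- recon[i, j] + B[i, k] * F[k, j]
  }
  fit_term <- 0
  for (i in seq_len(n_l)) for (j in seq_len(n_d)) {
    fit_term <- fit_term + (x[i, j] - recon[i, j])^2
  }
  lap_term <- 0
  if (alpha > 0) {
    for (k in seq_len(r)) for (i in seq_len(n_l)) for (j in seq_len(n_l)) {
      lap_term <- lap_term + B[i, k] * L[i, j] * B[j, k]
    }
  }
  path_term <- 0
  if (beta > 0) {
    for (i in seq_len(n_l)) for (j in seq_len(n_d)) {
      path_term <- path_term + (recon[i, j] - target[i, j])^2
    }
  }
  0.5 * fit_term + alpha * lap_term + 0.5 * beta * path_term
}

oracle_mae <- function(observed, predicted, mask) {
  acc <- 0
  for (k in seq_len(nrow(mask))) {
    acc <- acc + abs(observed[mask[k, 1], mask[k, 2]] -
                       predicted[mask[k, 1], mask[k, 2]])
  }
  acc / nrow(mask)
}

oracle_rmse <- function(observed, predicted, mask) {
  acc <- 0
  for (k in seq_len(nrow(mask))) {
    acc <- acc + (observed[mask[k, 1], mask[k, 2]] -
                    predicted[mask[k, 1], mask[k, 2]])^2
  }
  sqrt(acc / nrow(mask))
}

oracle_rss <- function(observed, predicted) {
  acc <- 0
  for (i in seq_len(nrow(observed))) for (j in seq_len(ncol(observed))) {
    acc <- acc + (observed[i, j] - predicted[i, j])^2
  }
  acc
}

# Directly coded classical Lee-Seung NMF with the package's documented
# initialization contract (uniform(0,1) entries scaled by
# sqrt(mean(x) / r), B drawn before F) and guarded denominators.
lee_seung_reference <- function(x, r, seed, max_iter, epsilon = 1e-12) {
  n <- nrow(x); m <- ncol(x)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  s <- sqrt(max(mean(x), epsilon) / r)
  B <- matrix(runif(n * r), n, r) * s
  F <- matrix(runif(r * m), r, m) * s
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  obj <- 0.5 * sum((x - B %*% F)^2)
  for (t in seq_len(max_iter)) {
    B <- B * (x %*% t(F)) / (B %*% (F %*% t(F)) + epsilon)
    F <- F * (t(B) %*% x) / ((t(B) %*% B) %*% F + epsilon)
    obj <- c(obj, 0.5 * sum((x - B %*% F)^2))
  }
  list(B = B, F = F, objective = obj)
}

# Random labeled binary association matrix.
rand_assoc <- function(n, m, density = 0.3, prefix = c("l", "d")) {
  m_ <- matrix(as.double(rbinom(n * m, 1, density)), n, m,
               dimnames = list(sprintf("%s%02d", prefix[1], seq_len(n)),
                               sprintf("%s%02d", prefix[2], seq_len(m))))
  m_
}

# Random weighted network over n nodes with given edge density.
rand_network <- function(n, density = 0.4, kind = "gene", prefix = "g") {
  w <- matrix(0, n, n, dimnames = list(sprintf("%s%02d", prefix, seq_len(n)),
                                       sprintf("%s%02d", prefix, seq_len(n))))
  up <- which(upper.tri(w))
  pick <- up[runif(length(up)) < density]
  w[pick] <- runif(length(pick))
  w <- w + t(w)
  weighted_network(w, kind = kind)
}

# Random small problem (x, laplacian, target) for optimizer tests.
rand_problem <- function(n_l = 10, n_d = 8, n_g = 6) {
  x <- rand_assoc(n_l, n_d)
  lnet <- rand_network(n_l, density = 0.4, kind = "lincRNA", prefix = "l")
  lap <- build_normalized_laplacian(lnet)
  y <- rand_assoc(n_g, n_d, prefix = c("g", "d"))
  gnet <- rand_network(n_g)
  z <- matrix(rbinom(n_g * n_l, 1, 0.4), n_g, n_l,
              dimnames = list(rownames(y), rownames(x)))
  tgt <- path_target(z, gnet, y)
  if (max(tgt) > 0) tgt <- tgt / max(tgt)
  list(x = x, lap = lap, target = tgt)
}
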