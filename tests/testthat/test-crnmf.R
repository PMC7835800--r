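# The Cr-NMF objective, multiplicative updates, and optimizer.

test_that("path target matches hand expansion and the path-enumeration oracle", {
  # 2 genes, single edge weight w; z, y all ones -> every entry 2w
  w <- 0.7
  gw <- matrix(c(0, w, w, 0), 2, 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))
  gnet <- weighted_network(gw, "gene")
  z <- matrix(1, 2, 3, dimnames = list(c("g1", "g2"), c("l1", "l2", "l3")))
  y <- matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("d1", "d2")))
  tt <- path_target(z, gnet, y)
  expect_equal(unname(tt), matrix(2 * w, 3, 2))

  # all-zero gene network annihilates the target
  gnet0 <- weighted_network(gw * 0, "gene")
  expect_true(all(path_target(z, gnet0, y) == 0))

  set.seed(41)
  y2 <- rand_assoc(4, 2, density = 0.5, prefix = c("g", "d"))
  gnet2 <- rand_network(4)
  z2 <- matrix(rbinom(4 * 3, 1, 0.5), 4, 3,
               dimnames = list(rownames(y2), sprintf("l%02d", 1:3)))
  expect_lt(max(abs(path_target(z2, gnet2, y2) -
                      oracle_path_target(z2, gnet2$weights, y2))), 1e-10)
})

test_that("objective matches hand values and the element-wise loop oracle", {
  # exact factorization, alpha = beta = 0 -> 0
  B <- matrix(c(1, 0), 2, 1); F <- matrix(c(1, 0), 1, 2)
  expect_equal(crnmf_objective(B %*% F, B, F), 0)
  # single-entry Frobenius: 0.5 * 1
  expect_equal(crnmf_objective(matrix(1), matrix(1), matrix(0)), 0.5)

  set.seed(42)
  prob <- rand_problem(5, 4, 6)
  B <- matrix(runif(5 * 2), 5, 2); F <- matrix(runif(2 * 4), 2, 4)
  L <- prob$lap$identity_part - prob$lap$adjacency_part
  got <- crnmf_objective(prob$x, B, F, prob$lap, prob$target,
                         alpha = 0.3, beta = 0.7)
  want <- oracle_objective(prob$x, B, F, L, prob$target, 0.3, 0.7)
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(crnmf_objective(matrix(NaN), matrix(1), matrix(1)),
               "non-finite")
})

test_that("updates fix points where numerator equals denominator and reduce
           to Lee-Seung at alpha = beta = 0", {
  set.seed(43)
  # multiplicative fixed point: at an exact factorization with alpha=beta=0
  # the epsilon-free ratio is 1; with the guard the change is O(epsilon)
  B <- matrix(runif(6 * 2), 6, 2); F <- matrix(runif(2 * 4), 2, 4)
  x <- B %*% F
  B2 <- crnmf_update_b(B, F, x)
  F2 <- crnmf_update_f(B, F, x)
  expect_equal(B2, B, tolerance = 1e-10)
  expect_equal(F2, F, tolerance = 1e-10)

  # one step equals the directly coded classical rule on a random instance
  x <- matrix(runif(6 * 3), 6, 3)
  B <- matrix(runif(6 * 2), 6, 2); F <- matrix(runif(2 * 3), 2, 3)
  B_ls <- B * (x %*% t(F)) / (B %*% (F %*% t(F)) + 1e-12)
  F_ls <- F * (t(B) %*% x) / ((t(B) %*% B) %*% F + 1e-12)
  expect_identical(crnmf_update_b(B, F, x), B_ls)
  expect_identical(crnmf_update_f(B, F, x), F_ls)
})

test_that("single regularized updates keep factors non-negative and never
           increase the objective", {
  set.seed(44)
  prob <- rand_problem(8, 5)
  cfgs <- expand.grid(alpha = c(0, 0.5), beta = c(0, 0.5, 2))
  for (i in seq_len(nrow(cfgs))) {
    a <- cfgs$alpha[i]; b <- cfgs$beta[i]
    B <- matrix(runif(8 * 2), 8, 2); F <- matrix(runif(2 * 5), 2, 5)
    o0 <- crnmf_objective(prob$x, B, F, prob$lap, prob$target, a, b)
    B1 <- crnmf_update_b(B, F, prob$x, prob$lap, prob$target, a, b)
    o1 <- crnmf_objective(prob$x, B1, F, prob$lap, prob$target, a, b)
    F1 <- crnmf_update_f(B1, F, prob$x, prob$target, b)
    o2 <- crnmf_objective(prob$x, B1, F1, prob$lap, prob$target, a, b)
    expect_true(all(B1 >= 0) && all(F1 >= 0))
    expect_lte(o1, o0 + 1e-9)
    expect_lte(o2, o1 + 1e-9)
  }
})

test_that("fit trajectory is monotone, deterministic, and respects max_iter = 0", {
  set.seed(45)
  prob <- rand_problem()
  cfg <- crnmf_config(r = 3, alpha = 0.5, beta = 0.5, max_iter = 60, seed = 7)
  fit <- crnmf_fit(prob$x, prob$lap, prob$target, cfg)
  expect_true(all(diff(fit$objective) <= 1e-9))
  expect_identical(crnmf_fit(prob$x, prob$lap, prob$target, cfg), fit)

  cfg0 <- crnmf_config(r = 3, alpha = 0.5, beta = 0.5, max_iter = 0, seed = 7)
  fit0 <- crnmf_fit(prob$x, prob$lap, prob$target, cfg0)
  expect_length(fit0$objective, 1)
  expect_false(fit0$converged)
  expect_identical(fit0$iterations, 0L)
  expect_identical(dim(fit0$B), dim(fit$B))
  expect_equal(fit0$objective[1], fit$objective[1])  # same init
})

test_that("whole trajectories reduce bit-identically to classical NMF at
           alpha = beta = 0", {
  set.seed(46)
  x <- matrix(runif(6 * 3), 6, 3)
  ref <- lee_seung_reference(x, r = 2, seed = 5, max_iter = 40)
  fit <- crnmf_fit(x, config = crnmf_config(r = 2, alpha = 0, beta = 0,
                                            max_iter = 40, tol = 1e-300,
                                            seed = 5))
  expect_identical(unname(fit$B), ref$B)
  expect_identical(unname(fit$F), ref$F)
  expect_identical(fit$objective, ref$objective)
})

test_that("exact-rank instances are recovered given a sufficient iteration
           budget", {
  # multiplicative updates converge slowly near an exact factorization;
  # recovery to 1e-3 needs a few thousand iterations (rank 1 is immediate)
  set.seed(47)
  x1 <- matrix(runif(12), 12, 1) %*% matrix(runif(8), 1, 8)
  f1 <- crnmf_fit(x1, config = crnmf_config(r = 1, alpha = 0, beta = 0,
                                            max_iter = 500, tol = 1e-300, seed = 1))
  expect_lt(norm(x1 - f1$B %*% f1$F, "F") / norm(x1, "F"), 1e-6)

  for (s in 1:3) {
    set.seed(1000 + s)
    x <- matrix(runif(20 * 2), 20, 2) %*% matrix(runif(2 * 12), 2, 12)
    f <- crnmf_fit(x, config = crnmf_config(r = 2, alpha = 0, beta = 0,
                                            max_iter = 2500, tol = 1e-300,
                                            seed = s))
    expect_lt(norm(x - f$B %*% f$F, "F") / norm(x, "F"), 1e-3)
  }
})

test_that("KKT residuals vanish at convergence on well-conditioned toys", {
  kkt_residuals <- function(prob, alpha, beta, iters) {
    cfg <- crnmf_config(r = 2, alpha = alpha, beta = beta, max_iter = iters,
                        tol = 1e-300, seed = 2)
    fit <- crnmf_fit(prob$x, prob$lap, prob$target, cfg)
    B <- fit$B; F <- fit$F
    L <- prob$lap$identity_part - prob$lap$adjacency_part
    grad_b <- (1 + beta) * B %*% (F %*% t(F)) - prob$x %*% t(F) -
      beta * prob$target %*% t(F) + 2 * alpha * (L %*% B)
    grad_f <- (1 + beta) * (t(B) %*% B) %*% F - t(B) %*% prob$x -
      beta * t(B) %*% prob$target
    c(b = max(abs(pmin(B, grad_b))), f = max(abs(pmin(F, grad_f))))
  }
  set.seed(52)
  prob <- rand_problem(6, 4)
  # interior optima (no Laplacian boundary activity): residuals vanish
  r00 <- kkt_residuals(prob, alpha = 0, beta = 0, iters = 5000)
  r0b <- kkt_residuals(prob, alpha = 0, beta = 0.5, iters = 5000)
  expect_lt(max(r00), 1e-3)
  expect_lt(max(r0b), 1e-3)
  # with the Laplacian on, entries pushed onto the B >= 0 boundary decay
  # only ~1/t under multiplicative updates, so the B-side residual is
  # reported at a coarser level; the F side still vanishes
  rab <- kkt_residuals(prob, alpha = 0.5, beta = 0.5, iters = 10000)
  expect_lt(rab["f"], 1e-3)
  expect_lt(rab["b"], 2e-2)
})

test_that("objective scales quadratically in the data at alpha = 0", {
  set.seed(49)
  x <- matrix(runif(12), 4, 3); tgt <- matrix(runif(12), 4, 3)
  B <- matrix(runif(8), 4, 2); F <- matrix(runif(6), 2, 3)
  o1 <- crnmf_objective(x, B, F, target = tgt, beta = 0.7)
  c_ <- 3.5
  o2 <- crnmf_objective(c_ * x, c_ * B, F, target = c_ * tgt, beta = 0.7)
  expect_equal(o2, c_^2 * o1, tolerance = 1e-10)
})

test_that("prediction returns BF with labels, clipped to [0, 1] by default", {
  B <- matrix(c(1, 0), 2, 1); F <- matrix(c(1, 0), 1, 2)
  fit <- structure(list(B = B, F = F,
                        config = crnmf_config(r = 1),
                        dimnames = list(c("l1", "l2"), c("d1", "d2"))),
                   class = "crnmf_fit")
  expect_equal(unname(predict(fit)), matrix(c(1, 0, 0, 0), 2, 2))

  set.seed(50)
  B2 <- matrix(runif(6, 0, 3), 3, 2); F2 <- matrix(runif(8, 0, 3), 2, 4)
  fit2 <- structure(list(B = B2, F = F2, config = crnmf_config(r = 2),
                         dimnames = list(sprintf("l%d", 1:3), sprintf("d%d", 1:4))),
                    class = "crnmf_fit")
  p <- predict(fit2)
  expect_true(min(p) >= 0 && max(p) <= 1)
  expect_equal(unname(predict(fit2, clip = FALSE)), B2 %*% F2)
})

test_that("config validation and the overcomplete-rank warning fire", {
  expect_error(crnmf_config(r = 0), "positive integer")
  expect_error(crnmf_config(alpha = -1), ">= 0")
  expect_error(crnmf_config(tol = 0), "tol")
  set.seed(51)
  x <- rand_assoc(3, 2)
  expect_warning(crnmf_fit(x, config = crnmf_config(r = 3, alpha = 0, beta = 0,
                                                    max_iter = 1)),
                 "overcomplete")
})
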