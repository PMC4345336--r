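test_that("factor and model representations are mutually inverse", {
  # single community of five degree-4 nodes
  m <- nlc_model(cbind(rep(4, 5)))
  X <- model_to_factor(m)
  expect_equal(X[, 1], rep(4 / sqrt(20), 5), tolerance = 1e-12)
  expect_equal(factor_to_model(X)$D, m$D, tolerance = 1e-12)
  expect_equal(model_to_factor(nlc_model(matrix(0, 4, 2))),
               matrix(0, 4, 2))
  for (seed in 1:5) {
    set.seed(seed)
    net <- rand_gnp(8, 0.4, seed = seed)
    mm <- init_params(net, 3, seed = seed)
    XX <- model_to_factor(mm)
    expect_equal(tcrossprod(XX), expected_matrix(mm), tolerance = 1e-12)
    expect_equal(factor_to_model(XX)$D, mm$D, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("penalized objective matches hand-evaluated cases", {
  # A = [[1,1],[1,1]] (self-loop of weight 1/2 on each node), X = (1,1):
  # exact factorization with the constraint satisfied
  net <- nlc_network(data.frame(a = c("a", "a", "b"), b = c("a", "b", "b"),
                                w = c(0.5, 1, 0.5)))
  expect_equal(weight_matrix(net), matrix(1, 2, 2), ignore_attr = TRUE)
  expect_equal(nmf_objective(net, cbind(c(1, 1)), 7), 0)
  # X = 0 with lambda = 0 leaves the squared norm of A
  expect_equal(nmf_objective(net, cbind(c(0, 0)), 0), 4)
  # K2 with X = (1,0), lambda = 1: reconstruction error 3, penalty 1
  expect_equal(nmf_objective(k2_net(), cbind(c(1, 0)), 1), 4)
})

test_that("multiplicative update is a fixed point at exact solutions", {
  net <- nlc_network(data.frame(a = c("a", "a", "b"), b = c("a", "b", "b"),
                                w = c(0.5, 1, 0.5)))
  X <- cbind(c(1, 1))
  expect_equal(nmf_update(net, X, 5), X, tolerance = 1e-12)
})

test_that("one update strictly decreases the objective from random factors", {
  for (seed in 1:5) {
    net <- rand_gnp(4, 0.9, seed = 30 + seed)
    set.seed(seed)
    X <- matrix(stats::rgamma(net$n * 2, 1), net$n, 2)
    for (lam in c(0, 1000)) {
      o0 <- nmf_objective(net, X, lam)
      o1 <- nmf_objective(net, nmf_update(net, X, lam), lam)
      expect_lt(o1, o0)
    }
  }
})

test_that("lambda = 0 reduces to the plain symmetric-NMF update", {
  net <- rand_gnp(5, 0.7, seed = 40)
  set.seed(1)
  X <- matrix(stats::rgamma(10, 1), 5, 2)
  A <- weight_matrix(net)
  plain <- pmax(X, 1e-12) *
    ((A %*% pmax(X, 1e-12)) /
       pmax(pmax(X, 1e-12) %*% crossprod(pmax(X, 1e-12)), 1e-300))^0.5
  expect_equal(nmf_update(net, X, 0), unname(pmax(plain, 1e-12)),
               tolerance = 1e-12)
})

test_that("two-phase NMF fit recovers blocks and meets the soft constraint", {
  net <- two_triangles()
  fit <- fit_nmf(net, 2, restarts = 5, seed = 2)
  D <- fit$model$D
  blocks <- list(match(c("a", "b", "c"), net$labels),
                 match(c("d", "e", "f"), net$labels))
  k1 <- which.max(colSums(D[blocks[[1]], , drop = FALSE]))
  expect_equal(unname(D[blocks[[1]], k1]), rep(2, 3), tolerance = 1e-2)
  expect_equal(unname(D[blocks[[2]], 3 - k1]), rep(2, 3), tolerance = 1e-2)
  expect_true(allocation_ok(net, fit$model, tol = 1e-3))
  # residual of the degree constraint under the large penalty
  X <- model_to_factor(fit$model)
  r <- as.vector(tcrossprod(X) %*% rep(1, net$n)) - net$deg
  expect_lt(sqrt(sum(r^2)) / sqrt(sum(net$deg^2)), 1e-2)
})

test_that("c = 1 NMF reproduces the degree sequence approximately", {
  net <- rand_gnp(6, 0.5, seed = 9)
  fit <- fit_nmf(net, 1, restarts = 2, seed = 1)
  expect_equal(fit$model$D[, 1], net$deg, tolerance = 1e-2,
               ignore_attr = TRUE)
})
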