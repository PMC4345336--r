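test_that("random initialization satisfies the allocation constraint exactly", {
  net <- rand_gnp(8, 0.4, seed = 2)
  m1 <- init_params(net, 1, seed = 7)
  expect_equal(m1$D[, 1], net$deg, ignore_attr = TRUE)  # simplex is a point
  m3 <- init_params(net, 3, seed = 7)
  expect_true(all(m3$D >= 0))
  expect_equal(rowSums(m3$D), net$deg, ignore_attr = TRUE)
  expect_equal(init_params(net, 3, seed = 7)$D, m3$D)   # determinism
  expect_false(isTRUE(all.equal(init_params(net, 3, seed = 8)$D, m3$D)))
  expect_error(init_params(net, 0), "c")
})

test_that("E-step responsibilities normalize and respect zero allocations", {
  net <- path3_net()
  r1 <- e_step(net, init_params(net, 1, seed = 1))
  expect_equal(unname(r1$q[, 1]), c(1, 1))
  D <- matrix(c(1, 2, 1, 0, 0, 0), 3, 2)  # second community dead for all
  r2 <- e_step(net, nlc_model(D))
  expect_equal(unname(r2$q[, 2]), c(0, 0))
  # exactly symmetric communities split every edge responsibility in half
  net2 <- two_triangles()
  Dsym <- cbind(net2$deg / 2, net2$deg / 2)
  rs <- e_step(net2, nlc_model(Dsym))
  expect_equal(unname(rs$q), matrix(0.5, 6, 2))
  expect_error(e_step(net, nlc_model(matrix(0, 3, 2))), "degenerate")
})

test_that("M-step is the closed-form constrained maximizer", {
  # hand case: path a-b-c with one community per edge
  net <- path3_net()
  resp <- structure(list(q = rbind(c(1, 0), c(0, 1)),
                         ei = net$ei, ej = net$ej), class = "nlc_resp")
  m <- m_step(net, resp)
  b <- which(net$labels == "b")
  expect_equal(m$D[b, ], c(1, 1), ignore_attr = TRUE)
  expect_equal(rowSums(m$D), net$deg, ignore_attr = TRUE)

  # c = 1 returns the degree sequence
  net4 <- rand_gnp(4, 0.8, seed = 5)
  r1 <- e_step(net4, init_params(net4, 1, seed = 1))
  expect_equal(m_step(net4, r1)$D[, 1], net4$deg, ignore_attr = TRUE)

  # oracle: numerical maximization of the auxiliary objective agrees
  for (seed in c(11, 12)) {
    net4 <- rand_gnp(4, 0.9, seed = seed)
    set.seed(seed)
    q <- matrix(stats::rgamma(length(net4$w) * 2, 1), ncol = 2)
    q <- q / rowSums(q)
    resp <- structure(list(q = q, ei = net4$ei, ej = net4$ej),
                      class = "nlc_resp")
    D_closed <- m_step(net4, resp)$D
    D_num <- aux_oracle(net4, resp, 2)
    expect_lt(max(abs(D_closed - D_num)), 1e-6)
    expect_equal(rowSums(D_closed), net4$deg, ignore_attr = TRUE)
  }
})

test_that("EM log-likelihood is non-decreasing and the constraint persists", {
  for (seed in 1:8) {
    net <- rand_gnp(10, 0.35, seed = 100 + seed)
    fit <- fit_em(net, 3, restarts = 2, max_iter = 120, seed = seed)
    expect_true(all(diff(fit$trace) >= -1e-10 * abs(fit$trace[-1])))
    expect_true(allocation_ok(net, fit$model, tol = 1e-9))
  }
})

test_that("EM separates two disjoint triangles into the two blocks", {
  net <- two_triangles()
  fit <- fit_em(net, 2, restarts = 10, seed = 4)
  D <- fit$model$D
  blocks <- list(match(c("a", "b", "c"), net$labels),
                 match(c("d", "e", "f"), net$labels))
  k1 <- which.max(colSums(D[blocks[[1]], , drop = FALSE]))
  expect_equal(unname(D[blocks[[1]], k1]), rep(2, 3), tolerance = 1e-6)
  expect_equal(unname(D[blocks[[2]], k1]), rep(0, 3), tolerance = 1e-6)
  expect_equal(unname(D[blocks[[2]], 3 - k1]), rep(2, 3), tolerance = 1e-6)
})

test_that("best-of-restarts EM attains the numerical optimum on small graphs", {
  for (seed in c(21, 22)) {
    net <- rand_gnp(5, 0.7, seed = seed)
    fit <- fit_em(net, 2, restarts = 25, max_iter = 3000, tol = 1e-14,
                  seed = seed)
    oracle <- loglik_oracle(net, 2, n_starts = 10, seed = seed)
    expect_equal(fit$loglik, oracle, tolerance = 1e-6)
  }
})

test_that("c = 1 EM converges to the degree sequence immediately", {
  net <- rand_gnp(6, 0.5, seed = 9)
  fit <- fit_em(net, 1, restarts = 1, seed = 1)
  expect_equal(fit$model$D[, 1], net$deg, ignore_attr = TRUE)
  expect_error(fit_em(nlc_network(data.frame(a = character(),
                                             b = character()),
                                  labels = "x"), 1), "no edges")
})
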