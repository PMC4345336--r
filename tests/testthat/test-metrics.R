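test_that("overlapping NMI is 1 on identical covers and symmetric", {
  a <- list(1:3, 3:6)
  b <- list(3:6, 1:3)
  expect_equal(overlapping_nmi(a, b, n = 6), 1)
  cc <- list(c(1, 2, 5), c(3, 4, 6))
  expect_equal(overlapping_nmi(a, cc, n = 6),
               overlapping_nmi(cc, a, n = 6), tolerance = 1e-12)
  expect_error(overlapping_nmi(list(), a, n = 6), "empty")
})

test_that("overlapping NMI matches the brute-force evaluation on 6 nodes", {
  covers <- list(
    list(1:3, 4:6),
    list(1:4, c(3, 4, 5, 6)),
    list(c(1, 2), c(2, 3, 4), c(4, 5, 6)),
    list(1:6),
    list(c(1, 3, 5), c(2, 4, 6))
  )
  for (i in seq_along(covers)) {
    for (j in seq_along(covers)) {
      expect_equal(overlapping_nmi(covers[[i]], covers[[j]], n = 6),
                   nmi_bruteforce(covers[[i]], covers[[j]], 6),
                   tolerance = 1e-12)
    }
  }
})

test_that("overlapping NMI is invariant to node relabeling", {
  set.seed(4)
  perm <- sample(10)
  a <- list(1:4, 4:7, 8:10)
  b <- list(1:5, 6:10)
  pa <- lapply(a, function(M) perm[M])
  pb <- lapply(b, function(M) perm[M])
  expect_equal(overlapping_nmi(a, b, n = 10),
               overlapping_nmi(pa, pb, n = 10), tolerance = 1e-12)
})

test_that("unrelated random covers score near zero on a large node set", {
  set.seed(8)
  n <- 400
  a <- split(1:n, rep(1:8, each = 50))
  b <- split(sample(n), rep(1:8, each = 50))
  expect_lt(overlapping_nmi(a, b, n = n), 0.05)
})

test_that("extended modularity reduces to standard modularity on partitions", {
  # whole network as one module: the null-model identity gives zero
  net <- rand_gnp(8, 0.5, seed = 5)
  expect_equal(extended_modularity(net, list(1:8)), 0, tolerance = 1e-12)
  # two triangles joined by a bridge, natural split: 2m = 14
  net2 <- make_net(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                         c("d", "e"), c("e", "f"), c("d", "f"),
                         c("c", "d")))
  q <- extended_modularity(net2, list(match(c("a", "b", "c"), net2$labels),
                                      match(c("d", "e", "f"), net2$labels)))
  expect_equal(q, 2 * (3 / 7 - (7 / 14)^2), tolerance = 1e-12)
  expect_equal(q, 0.357, tolerance = 1e-3)
  # arbitrary partitions agree with the independent igraph computation
  for (seed in 1:4) {
    net3 <- rand_gnp(12, 0.3, seed = 500 + seed)
    set.seed(seed)
    memb <- sample(1:3, 12, replace = TRUE)
    parts <- lapply(1:3, function(k) which(memb == k))
    parts <- parts[lengths(parts) > 0]
    expect_equal(extended_modularity(net3, parts),
                 igraph::modularity(to_igraph(net3), memb),
                 tolerance = 1e-12)
  }
})

test_that("overlap membership counts damp the extended modularity", {
  net <- two_triangles()
  full <- extended_modularity(net, list(1:3, 4:6))
  overl <- extended_modularity(net, list(1:3, 4:6, 1:3))
  expect_lt(overl, full)
})

test_that("enrichment pools within-community pairs against the global mean", {
  sim <- matrix(1, 6, 6)
  expect_equal(enrichment(list(1:3, 4:6), sim), 1)
  expect_equal(enrichment(list(1:6), sim), 1)
  # 3 similar pairs, all inside one 3-node community: (3/3)/(3/15) = 5
  sim2 <- matrix(0, 6, 6)
  sim2[1, 2] <- sim2[2, 1] <- 1
  sim2[1, 3] <- sim2[3, 1] <- 1
  sim2[2, 3] <- sim2[3, 2] <- 1
  expect_equal(enrichment(list(1:3), sim2), 5)
  expect_error(enrichment(list(1L), sim2, n = 6), "pair")
})

test_that("MDL rescaling is the stated linear map", {
  expect_equal(rescale_mdl(4.3, optimal = 4.3, baseline = 8.1), 1)
  expect_equal(rescale_mdl(8.1, optimal = 4.3, baseline = 8.1), 0)
  expect_equal(rescale_mdl(6.2, optimal = 4.3, baseline = 8.1), 0.5)
  expect_error(rescale_mdl(1, 2, 2), "degenerate")
})

test_that("the ego sampler filters trivial communities and is deterministic", {
  sim <- planted_benchmark(seed = 3)
  net <- sim$network
  truth <- sim$truth_cover
  s1 <- sample_subnetwork(net, truth, seed = 5)
  s2 <- sample_subnetwork(net, truth, seed = 5)
  expect_equal(s1$seed_node, s2$seed_node)
  expect_equal(weight_matrix(s1$network), weight_matrix(s2$network))
  expect_true(s1$accepted)
  expect_gte(s1$eq, 0.1)
  # the seed node shares a community with every sampled node
  expect_true(all(lengths(s1$cover$modules) > 0))

  # duplicates and tiny communities leave no eligible overlap node
  net2 <- two_triangles()
  expect_error(sample_subnetwork(net2, list(1:2, 1:2, c(3, 4)), seed = 1),
               "no community|no node")
  expect_error(sample_subnetwork(net2, list(1:3, 4:6), seed = 1),
               "two community memberships")
})
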