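test_that("soft memberships are degree shares and normalize", {
  toy <- toy_network()$network
  res <- detect_communities(toy, 3, scheme = "hybrid",
                            type_mode = "exhaustive", restarts = 10,
                            seed = 1)
  S <- res$S
  expect_equal(rowSums(S), rep(1, 14), ignore_attr = TRUE)
  expect_true(all(S >= 0 & S <= 1))
  # the shared node of the two cliques splits evenly between them
  s5 <- sort(S[5, ], decreasing = TRUE)
  expect_equal(unname(s5[1:2]), c(0.5, 0.5), tolerance = 1e-4)
  expect_lt(s5[3], 1e-4)
  # a clique-interior node is nearly pure
  expect_gt(max(S[12, ]), 0.999)
  R <- res$R
  expect_equal(rowSums(R), rep(1, length(toy$w)), ignore_attr = TRUE)
})

test_that("a node fully inside one community has a unit membership row", {
  net <- two_triangles()
  fit <- fit_em(net, 2, restarts = 8, seed = 3)
  S <- node_memberships(fit$model)
  expect_true(all(apply(S, 1, max) > 1 - 1e-6))
  # c = 1: every link membership is the unit vector
  R1 <- link_memberships(net, fit_em(net, 1, restarts = 1, seed = 1)$model)
  expect_equal(unname(R1[, 1]), rep(1, 6))
})

test_that("hardening assigns by argmax with type-respecting background", {
  net <- path3_net()
  m <- fit_em(net, 1, restarts = 1, seed = 1)$model
  st <- harden(net, m, "node")
  expect_equal(st$node_sets[[1]], 1:3)
  expect_length(st$background_nodes, 0L)

  # a link whose best community is node-typed becomes a background link
  toy <- toy_network()$network
  fit <- fit_em(toy, 3, restarts = 10, seed = 1)
  stn <- harden(toy, fit$model, rep("node", 3))
  expect_length(unlist(stn$link_sets), 0L)
  expect_equal(sort(unique(c(unlist(stn$node_sets)))), 1:14)
  expect_length(stn$background_links, length(toy$w))

  stl <- harden(toy, fit$model, rep("link", 3))
  expect_length(unlist(stl$node_sets), 0L)
  # hard link communities partition the links
  expect_equal(sort(unlist(stl$link_sets)), seq_along(toy$w))

  # zero-degree nodes are background
  net2 <- nlc_network(data.frame(a = "a", b = "b"), labels = c("a", "b", "z"))
  m2 <- fit_em(net2, 1, restarts = 1, seed = 1)$model
  st2 <- harden(net2, m2, "node")
  expect_equal(st2$background_nodes, 3L)
})

test_that("hard node communities are disjoint; ties break to the lowest index", {
  net <- two_triangles()
  Dsym <- cbind(net$deg / 2, net$deg / 2)  # exact ties everywhere
  st <- harden(net, nlc_model(Dsym), c("node", "node"))
  expect_equal(st$node_sets[[1]], 1:6)
  expect_length(st$node_sets[[2]], 0L)
})

test_that("greedy type search matches exhaustive enumeration on fixtures", {
  toy <- toy_network()$network
  fit <- fit_em(toy, 3, restarts = 10, seed = 2)
  ex <- search_types(toy, fit$model, mode = "exhaustive")
  gr <- search_types(toy, fit$model, mode = "greedy", seed = 5)
  expect_equal(gr$mdl, ex$mdl, tolerance = 1e-12)

  kar <- karate_network()
  fk <- fit_em(kar, 4, restarts = 10, seed = 2)
  exk <- search_types(kar, fk$model, mode = "exhaustive")
  grk <- search_types(kar, fk$model, mode = "greedy", seed = 5)
  expect_equal(grk$mdl, exk$mdl, tolerance = 1e-12)
  expect_gte(grk$mdl, exk$mdl - 1e-12)  # oracle bound
})

test_that("hybrid scheme never scores worse than pure node or link schemes", {
  for (seed in 1:4) {
    net <- rand_gnp(12, 0.3, seed = 200 + seed)
    fit <- fit_em(net, 3, restarts = 3, seed = seed)
    mdl_of <- function(types) {
      st <- harden(net, fit$model, types)
      map_equation_mdl(net, induced_cover(st, net))
    }
    hyb <- search_types(net, fit$model, mode = "exhaustive")$mdl
    expect_lte(hyb, mdl_of(rep("node", 3)) + 1e-12)
    expect_lte(hyb, mdl_of(rep("link", 3)) + 1e-12)
  }
})

test_that("forced schemes equal the corresponding restricted searches", {
  toy <- toy_network()$network
  rn <- detect_communities(toy, 3, scheme = "node", restarts = 10, seed = 6)
  st <- harden(toy, rn$model, rep("node", 3))
  expect_equal(rn$mdl, map_equation_mdl(toy, induced_cover(st, toy)))
  rh <- detect_communities(toy, 3, scheme = "hybrid",
                           type_mode = "exhaustive", restarts = 10, seed = 6)
  expect_lte(rh$mdl, rn$mdl + 1e-12)
})
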