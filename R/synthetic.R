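#' Fourteen-node worked-example network
#'
#' Three 5-cliques on nodes 1-5, 5-9 and 10-14 (the first two sharing
#' node 5) plus the bridge edge 9-10: 14 nodes and 31 edges with degree
#' sequence (4,4,4,4,8,4,4,4,5,5,4,4,4,4). Its planted structure is two
#' link communities (the two cliques overlapping in node 5) and one node
#' community (nodes 10-14), with the bridge edge as background.
#'
#' @return list with `network` ([nlc_network]), `truth_cover`
#'   ([nlc_cover] of the three planted groups) and `truth_types`.
#' @export
toy_network <- function() {
  clique <- function(nodes) t(utils::combn(nodes, 2L))
  el <- rbind(clique(1:5), clique(5:9), clique(10:14), c(9L, 10L))
  net <- nlc_network(data.frame(a = el[, 1L], b = el[, 2L]),
                     labels = as.character(1:14))
  list(network = net,
       truth_cover = nlc_cover(list(1:5, 5:9, 10:14), 14L),
       truth_types = c("link", "link", "node"))
}

#' Zachary karate-club network
#'
#' The classic 34-node, 78-edge social network, packaged as a plain-text
#' edge list. Node labels are "1".."34" with node 1 the instructor.
#'
#' @return an [nlc_network].
#' @export
karate_network <- function() {
  path <- system.file("extdata", "karate.tsv", package = "nlcomm",
                      mustWork = TRUE)
  net <- read_network(path, format = "edgelist")
  # keep numeric label order rather than lexicographic
  nlc_network(data.frame(a = net$labels[net$ei], b = net$labels[net$ej],
                         w = net$w),
              labels = as.character(1:34))
}

#' Les Miserables character co-appearance network
#'
#' The classic 77-node, 254-edge weighted network of character
#' co-appearances in scenes of Hugo's novel, packaged as a plain-text
#' edge list (weights are co-appearance counts).
#'
#' @return an [nlc_network].
#' @export
lesmis_network <- function() {
  path <- system.file("extdata", "lesmis.tsv", package = "nlcomm",
                      mustWork = TRUE)
  read_network(path, format = "edgelist")
}

#' Planted hybrid-structure benchmark generator
#'
#' Builds a network with known community structure from a block
#' specification. Two block types are supported: `"clique"` (a clique on
#' fresh nodes, planted as one node community) and `"chain"` (a chain of
#' cliques in which consecutive cliques share one node, planted as one
#' link community per clique; the shared nodes are the planted overlap).
#' Between-block noise edges are added independently with probability
#' `p_between`. The draw is rejected and resampled (up to `max_tries`)
#' unless every planted community keeps more internal than boundary
#' weight, so planted structure is always denser than its surroundings.
#'
#' @param blocks list of block specs: `list(type = "clique", size = s)`
#'   or `list(type = "chain", sizes = c(s1, s2, ...))`; all sizes >= 3.
#' @param p_between probability of a noise edge between nodes of
#'   different blocks (default 0.02, a sparse background typical of
#'   planted-partition benchmarks).
#' @param seed integer seed; the same seed reproduces the identical
#'   network.
#' @param max_tries resampling attempts before the spec is declared
#'   infeasible.
#' @return list with `network`, `truth_cover` (planted [nlc_cover]),
#'   `truth_types` (one entry per planted community), `blocks`.
#' @export
planted_hybrid_network <- function(blocks, p_between = 0.02, seed = NULL,
                                   max_tries = 50) {
  if (!is.null(seed)) set.seed(seed)
  sizes_of <- function(b) if (b$type == "clique") b$size else b$sizes
  if (any(unlist(lapply(blocks, sizes_of)) < 3L))
    stop("infeasible spec: all community sizes must be >= 3")
  # deterministic scaffold: nodes and planted communities
  nxt <- 0L
  groups <- list()   # planted communities: list(type, nodes)
  block_of <- integer(0)
  for (b_idx in seq_along(blocks)) {
    b <- blocks[[b_idx]]
    if (b$type == "clique") {
      nodes <- nxt + seq_len(b$size)
      nxt <- nxt + b$size
      groups <- c(groups, list(list(type = "node", nodes = nodes)))
      block_of[nodes] <- b_idx
    } else if (b$type == "chain") {
      prev_tail <- NA_integer_
      for (s in b$sizes) {
        fresh <- if (is.na(prev_tail)) s else s - 1L
        nodes <- c(if (!is.na(prev_tail)) prev_tail, nxt + seq_len(fresh))
        nxt <- nxt + fresh
        groups <- c(groups, list(list(type = "link", nodes = nodes)))
        block_of[nodes] <- b_idx
        prev_tail <- nodes[length(nodes)]
      }
    } else stop("unknown block type: ", b$type)
  }
  n <- nxt
  labels <- as.character(seq_len(n))
  clique_edges <- function(nodes) t(utils::combn(nodes, 2L))
  base_el <- do.call(rbind, lapply(groups, function(g) clique_edges(g$nodes)))
  base_el <- unique(base_el)
  for (try in seq_len(max_tries)) {
    noise <- which(upper.tri(matrix(0, n, n)) &
                     outer(block_of, block_of, "!=") &
                     matrix(stats::runif(n * n) < p_between, n, n),
                   arr.ind = TRUE)
    el <- rbind(base_el, unname(noise))
    net <- nlc_network(data.frame(a = labels[el[, 1L]], b = labels[el[, 2L]],
                                  w = 1),
                       labels = labels)
    W <- weight_matrix(net)
    ok <- all(vapply(groups, function(g) {
      M <- g$nodes
      sum(W[M, M]) > sum(W[M, -M, drop = FALSE])
    }, logical(1)))
    if (ok) {
      truth_cover <- nlc_cover(lapply(groups, `[[`, "nodes"), n)
      return(list(network = net, truth_cover = truth_cover,
                  truth_types = vapply(groups, `[[`, character(1), "type"),
                  blocks = blocks))
    }
  }
  stop("infeasible spec: planted communities not denser than their boundary ",
       "after ", max_tries, " draws")
}

#' Default eight-community planted benchmark
#'
#' The benchmark configuration used throughout the package's recovery
#' study: 100 nodes in eight planted communities - four node-community
#' cliques (sizes 12, 12, 12, 13) and two shared-node clique chains
#' (sizes 14+13 and 13+13, four link communities with two overlap
#' nodes) - with sparse between-block noise.
#'
#' @param seed integer seed.
#' @param p_between between-block noise edge probability.
#' @return as [planted_hybrid_network()].
#' @export
planted_benchmark <- function(seed = NULL, p_between = 0.02) {
  planted_hybrid_network(
    blocks = list(list(type = "clique", size = 12L),
                  list(type = "clique", size = 12L),
                  list(type = "clique", size = 12L),
                  list(type = "clique", size = 13L),
                  list(type = "chain", sizes = c(14L, 13L)),
                  list(type = "chain", sizes = c(13L, 13L))),
    p_between = p_between, seed = seed)
}
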