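#' Normalized mutual information for overlapping covers
#'
#' The extended NMI for covers: each module is a binary node-membership
#' variable; the conditional entropy of a module given the other cover is
#' the minimum over that cover's modules, kept only when the joint
#' distribution is closer to agreement than to disagreement (the
#' "no-match" guard, which stops unrelated modules from spuriously
#' explaining each other), otherwise the unconditional entropy is used.
#' The normalized conditional entropies of the two directions are
#' averaged and subtracted from one, so identical covers (up to module
#' order) score 1 and unrelated covers score near 0.
#'
#' @param cover_a,cover_b [nlc_cover] objects (or plain lists of node
#'   index vectors) over the same `n` nodes.
#' @param n node count; required when plain lists are given.
#' @return a value in `[0, 1]`, symmetric in its arguments.
#' @export
overlapping_nmi <- function(cover_a, cover_b, n = NULL) {
  as_mods <- function(cv) {
    if (inherits(cv, "nlc_cover")) {
      if (is.null(n)) n <<- cv$n
      cv$modules
    } else {
      cv
    }
  }
  A <- as_mods(cover_a)
  B <- as_mods(cover_b)
  if (is.null(n)) stop("`n` is required with plain list covers")
  if (length(A) == 0L || length(B) == 0L) stop("empty cover")
  h <- function(p) ifelse(p > 0, -p * log2(p), 0)
  memb <- function(mods) {
    M <- matrix(FALSE, n, length(mods))
    for (k in seq_along(mods)) M[mods[[k]], k] <- TRUE
    M
  }
  MA <- memb(A)
  MB <- memb(B)
  cond_norm <- function(MX, MY) {
    # mean over X's modules of H(X_k | Y) / H(X_k)
    vals <- vapply(seq_len(ncol(MX)), function(k) {
      x <- MX[, k]
      p1 <- mean(x)
      Hx <- h(p1) + h(1 - p1)
      if (Hx == 0) return(0)
      best <- Hx
      for (l in seq_len(ncol(MY))) {
        y <- MY[, l]
        p11 <- mean(x & y); p10 <- mean(x & !y)
        p01 <- mean(!x & y); p00 <- mean(!x & !y)
        if (h(p11) + h(p00) < h(p10) + h(p01)) next  # no-match guard
        Hy <- h(mean(y)) + h(1 - mean(y))
        Hxy <- h(p11) + h(p10) + h(p01) + h(p00) - Hy
        if (Hxy < best) best <- Hxy
      }
      best / Hx
    }, numeric(1))
    mean(vals)
  }
  1 - (cond_norm(MA, MB) + cond_norm(MB, MA)) / 2
}

#' Extended modularity of a (possibly overlapping) cover
#'
#' `EQ = (1/2m) sum_k sum_{i,j in C_k} (w_ij - d_i d_j / 2m) / (O_i O_j)`
#' where `O_i` counts the modules containing node `i`. On a disjoint
#' partition every `O_i` is 1 and EQ equals standard modularity; the
#' whole network as a single module scores 0 by the null-model identity.
#'
#' @param net an [nlc_network].
#' @param cover an [nlc_cover] or plain list of node index vectors.
#' @return a scalar (typically in `[-1, 1]`).
#' @export
extended_modularity <- function(net, cover) {
  stopifnot(inherits(net, "nlc_network"))
  if (!inherits(cover, "nlc_cover")) cover <- nlc_cover(cover, net$n)
  if (length(cover$modules) == 0L) stop("empty cover")
  O <- .cover_counts(cover)
  W <- weight_matrix(net)
  d <- net$deg
  m2 <- sum(d)
  total <- 0
  for (M in cover$modules) {
    o <- O[M]
    B <- W[M, M, drop = FALSE] - outer(d[M], d[M]) / m2
    total <- total + sum(B / outer(o, o))
  }
  total / m2
}

#' Similarity enrichment of a community structure
#'
#' Average pairwise similarity over all unordered within-community node
#' pairs (pooled across communities, counting a pair once per community
#' that contains both nodes) divided by the average similarity over all
#' unordered node pairs. Quantifies how much more similar co-community
#' nodes are than the network-wide baseline; 1 means no enrichment.
#'
#' @param cover an [nlc_cover] or plain list of node index vectors.
#' @param similarity symmetric `n` x `n` numeric (typically 0/1) matrix,
#'   or a vectorized function `f(i, j)` of index vectors.
#' @param n node count; required when `cover` is a plain list or
#'   `similarity` is a function.
#' @return a nonnegative ratio.
#' @export
enrichment <- function(cover, similarity, n = NULL) {
  if (inherits(cover, "nlc_cover")) {
    if (is.null(n)) n <- cover$n
    mods <- cover$modules
  } else {
    mods <- cover
  }
  if (is.matrix(similarity)) {
    if (is.null(n)) n <- nrow(similarity)
    simfun <- function(i, j) similarity[cbind(i, j)]
  } else {
    simfun <- similarity
  }
  if (is.null(n)) stop("`n` is required")
  pairs_of <- function(nodes) {
    if (length(nodes) < 2L) return(NULL)
    cb <- utils::combn(nodes, 2L)
    cbind(cb[1L, ], cb[2L, ])
  }
  within <- do.call(rbind, lapply(mods, pairs_of))
  if (is.null(within) || nrow(within) == 0L)
    stop("no within-community pair")
  all_pairs <- pairs_of(seq_len(n))
  mean(simfun(within[, 1L], within[, 2L])) /
    mean(simfun(all_pairs[, 1L], all_pairs[, 2L]))
}

#' Linear 0-1 rescaling of a description length
#'
#' Maps an MDL value onto a scale where a reference optimal value becomes
#' 1 and a reference baseline (e.g. the mean over random partitions)
#' becomes 0: `(baseline - value) / (baseline - optimal)`.
#'
#' @param value the MDL to rescale.
#' @param optimal reference mapped to 1.
#' @param baseline reference mapped to 0 (must differ from `optimal`).
#' @return rescaled value (can exceed the unit interval on either side).
#' @export
rescale_mdl <- function(value, optimal, baseline) {
  if (baseline == optimal) stop("degenerate rescaling: baseline == optimal")
  (baseline - value) / (baseline - optimal)
}

#' Sample an ego subnetwork around an overlap node
#'
#' Benchmark sampler for large covered networks: after combining
#' duplicate ground-truth communities and dropping communities with at
#' most two nodes, a random node `u` with at least two memberships is
#' chosen; the sample is the induced subgraph on all nodes sharing at
#' least one community with `u`, with the ground truth restricted to it.
#' Samples whose restricted cover has extended modularity below
#' `eps = 0.1` carry no well-defined community structure and are
#' rejected.
#'
#' @param net an [nlc_network].
#' @param truth an [nlc_cover] or plain list of node index vectors (the
#'   known communities).
#' @param seed integer seed.
#' @param eps rejection threshold on the extended modularity.
#' @return on acceptance a list with `network`, `cover` (restricted
#'   truth), `seed_node`, `eq`, `accepted = TRUE`; on rejection the same
#'   list with `accepted = FALSE` and `network`/`cover` of the rejected
#'   sample. Errors when no node has two memberships after filtering.
#' @export
sample_subnetwork <- function(net, truth, seed = NULL, eps = 0.1) {
  stopifnot(inherits(net, "nlc_network"))
  if (!inherits(truth, "nlc_cover")) truth <- nlc_cover(truth, net$n)
  if (!is.null(seed)) set.seed(seed)
  mods <- unique(truth$modules)
  mods <- mods[lengths(mods) > 2L]
  if (length(mods) == 0L) stop("no community left after preprocessing")
  O <- integer(net$n)
  for (M in mods) O[M] <- O[M] + 1L
  eligible <- which(O >= 2L)
  if (length(eligible) == 0L)
    stop("no node with at least two community memberships")
  u <- eligible[sample.int(length(eligible), 1L)]
  share <- unique(unlist(mods[vapply(mods, function(M) u %in% M, logical(1))]))
  subnet <- induced_subnetwork(net, share)
  remap <- match(seq_len(net$n), sort(share))
  sub_mods <- lapply(mods, function(M) remap[M][!is.na(remap[M])])
  sub_mods <- sub_mods[lengths(sub_mods) > 0L]
  sub_cover <- nlc_cover(sub_mods, subnet$n)
  eq <- extended_modularity(subnet, sub_cover)
  list(network = subnet, cover = sub_cover, seed_node = net$labels[u],
       eq = eq, accepted = eq >= eps)
}
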