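#' Node cover
#'
#' A possibly overlapping family of node sets (modules) over a network's
#' nodes, the object scored by the map equation and by all cover metrics.
#' Empty modules are dropped; module order never affects any score.
#'
#' @param modules list of integer index vectors (or character label
#'   vectors when `labels` is given).
#' @param n number of nodes in the underlying network.
#' @param labels optional node labels used to translate character modules.
#' @return an object of class `nlc_cover`: list of sorted unique integer
#'   vectors plus the node count `n`.
#' @export
nlc_cover <- function(modules, n, labels = NULL) {
  mods <- lapply(modules, function(M) {
    if (is.character(M)) {
      if (is.null(labels)) stop("character module but no `labels` given")
      M <- match(M, labels)
    }
    M <- sort(unique(as.integer(M)))
    if (anyNA(M) || any(M < 1L) || any(M > n)) stop("module node out of range")
    M
  })
  mods <- mods[lengths(mods) > 0L]
  structure(list(modules = mods, n = as.integer(n)), class = "nlc_cover")
}

#' @export
print.nlc_cover <- function(x, ...) {
  cat(sprintf("nlc_cover: %d modules over %d nodes (sizes: %s)\n",
              length(x$modules), x$n,
              paste(lengths(x$modules), collapse = " ")))
  invisible(x)
}

# membership count per node (0 for uncovered nodes)
.cover_counts <- function(cover) {
  o <- integer(cover$n)
  for (M in cover$modules) o[M] <- o[M] + 1L
  o
}

#' Node cover induced by a hybrid structure
#'
#' Every node-typed community contributes its node set as a module; every
#' link-typed community contributes the endpoint set of its links (a node
#' inherits the memberships of its adjacent links, which is how link
#' communities produce overlap). Positive-degree nodes covered by no
#' community become singleton modules, so the cover always spans all
#' positive-degree nodes.
#'
#' @param structure an `nlc_structure` from [harden()].
#' @param net the [nlc_network] the structure refers to.
#' @return an [nlc_cover].
#' @export
induced_cover <- function(structure, net) {
  stopifnot(inherits(structure, "nlc_structure"), inherits(net, "nlc_network"))
  mods <- list()
  for (k in seq_along(structure$types)) {
    if (structure$types[k] == "node") {
      M <- structure$node_sets[[k]]
    } else {
      es <- structure$link_sets[[k]]
      M <- unique(c(net$ei[es], net$ej[es]))
    }
    if (length(M)) mods <- c(mods, list(M))
  }
  covered <- logical(net$n)
  for (M in mods) covered[M] <- TRUE
  singles <- which(!covered & net$deg > 0)
  mods <- c(mods, as.list(singles))
  nlc_cover(mods, net$n)
}

#' Map-equation description length of a node cover
#'
#' Two-level minimum description length, in bits per step, of a random
#' walk on the network encoded with one codebook per module plus an index
#' codebook over module entries:
#' `L = q H(Q) + sum_k p_k H(P_k)`, where module `k` has exit rate `q_k`,
#' `q = sum_k q_k`, `H(Q)` is the entropy of the normalized exit rates,
#' and `P_k` is the normalized distribution over module `k`'s exit rate
#' and the visit rates of its member nodes. Stationary visit rates are
#' degree-proportional, `p_i = d_i / 2m` (undirected flow, no
#' teleportation). A node belonging to several modules splits its visit
#' rate across them: proportionally to its edge weight into each module
#' (`split = "proportional"`, the default, which on disjoint partitions
#' reduces exactly to the classic two-level map equation) or equally
#' (`split = "equal"`). A node's exit flow from module `k` is its split
#' rate times the fraction of its degree leaving the module.
#'
#' @param net an [nlc_network].
#' @param cover an [nlc_cover] (or plain list of index vectors). Uncovered
#'   positive-degree nodes are completed into singleton modules.
#' @param split how an overlap node's visit rate is divided among its
#'   modules.
#' @return description length in bits (>= 0).
#' @export
map_equation_mdl <- function(net, cover,
                             split = c("proportional", "equal")) {
  stopifnot(inherits(net, "nlc_network"))
  split <- match.arg(split)
  if (!inherits(cover, "nlc_cover")) cover <- nlc_cover(cover, net$n)
  if (length(cover$modules) == 0L && any(net$deg > 0))
    stop("empty cover on a network with edges")
  covered <- logical(net$n)
  for (M in cover$modules) covered[M] <- TRUE
  mods <- c(cover$modules, as.list(which(!covered & net$deg > 0)))
  K <- length(mods)
  d <- net$deg
  p <- d / sum(d)
  or <- .nlc_orient(net)
  # internal weight of node i wrt module k: sum of w_ij over j in the
  # module (self-loop weight counts as internal)
  internal <- function(M) {
    inM <- logical(net$n)
    inM[M] <- TRUE
    sel <- inM[or$i] & inM[or$j]
    wint <- numeric(net$n)
    if (any(sel)) {
      ag <- rowsum(or$w[sel], or$i[sel])
      wint[as.integer(rownames(ag))] <- ag[, 1L]
    }
    wint[M]
  }
  ints <- lapply(mods, internal)
  share <- matrix(0, net$n, K)
  for (k in seq_len(K)) {
    share[mods[[k]], k] <- if (split == "equal") 1 else ints[[k]]
  }
  rs <- rowSums(share)
  # nodes with no internal edge in any of their modules fall back to an
  # equal split (e.g. singleton modules)
  zero <- rs == 0
  for (k in seq_len(K)) {
    idx <- mods[[k]][zero[mods[[k]]]]
    share[idx, k] <- 1
  }
  rs <- rowSums(share)
  rs[rs == 0] <- 1
  share <- share / rs
  qk <- numeric(K)
  L <- 0
  pints <- vector("list", K)
  for (k in seq_len(K)) {
    M <- mods[[k]]
    out_frac <- ifelse(d[M] > 0, (d[M] - ints[[k]]) / d[M], 0)
    pk <- p[M] * share[M, k]
    qk[k] <- sum(pk * out_frac)
    pints[[k]] <- pk
  }
  q <- sum(qk)
  if (q > 0) L <- L + q * .entropy_bits(qk / q)
  for (k in seq_len(K)) {
    el <- c(qk[k], pints[[k]])
    pc <- sum(el)
    if (pc > 0) L <- L + pc * .entropy_bits(el / pc)
  }
  L
}

.entropy_bits <- function(pr) {
  pr <- pr[pr > 0]
  -sum(pr * log2(pr))
}
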