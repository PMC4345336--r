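#' Undirected weighted network
#'
#' Constructs the package's network representation: an undirected,
#' optionally weighted multigraph stored as a unique edge list over opaque
#' node labels. Parallel edges are summed into a single weighted edge.
#' Self-loops follow the multigraph convention that the diagonal of the
#' weight matrix holds twice the self-edge weight, so that the degree
#' identity `d_i = sum_j W_ij` and `sum_i d_i = 2m` hold exactly.
#'
#' @param edges a data frame (or matrix) whose first two columns are the
#'   endpoint labels of each edge and whose optional third column is a
#'   positive edge weight (default 1).
#' @param labels optional character vector fixing the node set and its
#'   order; defaults to the sorted set of labels appearing in `edges`.
#'   Labels absent from `edges` become isolated nodes.
#' @return an object of class `nlc_network`: a list with elements
#'   `labels`, parallel vectors `ei`, `ej` (1-based endpoint indices with
#'   `ei <= ej`), `w` (edge weights; for a self-loop this is the doubled
#'   diagonal entry), `n` (node count), `deg` (weighted degree sequence)
#'   and `m` (total edge weight).
#' @examples
#' net <- nlc_network(data.frame(a = c("a", "b", "a"), b = c("b", "c", "c")))
#' node_degrees(net)
#' @export
nlc_network <- function(edges, labels = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("`edges` needs at least two columns")
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  w <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, nrow(edges))
  if (anyNA(w) || any(w < 0)) stop("edge weights must be nonnegative numbers")
  if (is.null(labels)) {
    labels <- sort(unique(c(a, b)))
  } else {
    labels <- as.character(labels)
    if (anyDuplicated(labels)) stop("duplicated node labels")
    if (!all(c(a, b) %in% labels)) stop("edge endpoint not in `labels`")
  }
  i <- match(a, labels)
  j <- match(b, labels)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  # diagonal convention: a self-edge of weight v is stored as W_ii = 2v
  w <- ifelse(lo == hi, 2 * w, w)
  key <- paste(lo, hi)
  keep <- w > 0
  if (any(keep)) {
    agg <- rowsum(w[keep], key[keep])
    parts <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
    ei <- as.integer(parts[, 1L])
    ej <- as.integer(parts[, 2L])
    ww <- as.numeric(agg[, 1L])
  } else {
    ei <- ej <- integer(0)
    ww <- numeric(0)
  }
  ord <- order(ei, ej)
  net <- structure(
    list(labels = labels, ei = ei[ord], ej = ej[ord], w = ww[ord],
         n = length(labels)),
    class = "nlc_network"
  )
  net$deg <- .nlc_degrees(net)
  net$m <- sum(net$deg) / 2
  net
}

.nlc_degrees <- function(net) {
  d <- numeric(net$n)
  off <- net$ei != net$ej
  if (any(off)) {
    ag <- rowsum(c(net$w[off], net$w[off]), c(net$ei[off], net$ej[off]))
    d[as.integer(rownames(ag))] <- ag[, 1L]
  }
  if (any(!off)) {
    ag <- rowsum(net$w[!off], net$ei[!off])
    d[as.integer(rownames(ag))] <- d[as.integer(rownames(ag))] + ag[, 1L]
  }
  d
}

#' Weighted degree sequence
#'
#' Row sums of the symmetric weight matrix, `d_i = sum_j W_ij`. The sum of
#' all degrees equals twice the total edge weight.
#'
#' @param net an [nlc_network].
#' @return numeric vector of length `n`, named by node label.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "nlc_network"))
  stats::setNames(net$deg, net$labels)
}

#' Dense symmetric weight matrix of a network
#'
#' @param net an [nlc_network].
#' @return an `n` x `n` symmetric matrix with the doubled-diagonal
#'   self-loop convention.
#' @export
weight_matrix <- function(net) {
  stopifnot(inherits(net, "nlc_network"))
  W <- matrix(0, net$n, net$n, dimnames = list(net$labels, net$labels))
  off <- net$ei != net$ej
  W[cbind(net$ei[off], net$ej[off])] <- net$w[off]
  W[cbind(net$ej[off], net$ei[off])] <- net$w[off]
  W[cbind(net$ei[!off], net$ei[!off])] <- net$w[!off]
  W
}

#' @export
print.nlc_network <- function(x, ...) {
  cat(sprintf("nlc_network: %d nodes, %d edges, total weight %g\n",
              x$n, length(x$w), x$m))
  invisible(x)
}

# both-orientation expansion used by the EM sweep and the map equation:
# each off-diagonal edge appears as (i,j) and (j,i); a diagonal entry
# appears once. Sums over the expansion equal ordered-pair sums restricted
# to w > 0.
.nlc_orient <- function(net) {
  off <- net$ei != net$ej
  list(i = c(net$ei[off], net$ej[off], net$ei[!off]),
       j = c(net$ej[off], net$ei[off], net$ej[!off]),
       w = c(net$w[off], net$w[off], net$w[!off]))
}

#' Convert between igraph and nlc_network
#'
#' @param g an undirected [igraph::igraph] object. Edge weights are taken
#'   from the `weight` attribute, else from `value` (the convention of
#'   classic GML files), else 1.
#' @return an [nlc_network].
#' @export
from_igraph <- function(g) {
  if (igraph::is_directed(g)) stop("directed graph: symmetrize it first")
  el <- igraph::as_edgelist(g, names = FALSE)
  labs <- igraph::vertex_attr(g, "name")
  if (is.null(labs)) labs <- if (!is.null(igraph::vertex_attr(g, "id")))
    as.character(igraph::vertex_attr(g, "id")) else as.character(seq_len(igraph::vcount(g)))
  w <- igraph::edge_attr(g, "weight")
  if (is.null(w)) w <- igraph::edge_attr(g, "value")
  if (is.null(w)) w <- rep(1, nrow(el))
  if (nrow(el) == 0L) {
    return(nlc_network(data.frame(a = character(), b = character()), labels = labs))
  }
  nlc_network(data.frame(a = labs[el[, 1L]], b = labs[el[, 2L]], w = w),
              labels = labs)
}

#' @rdname from_igraph
#' @param net an [nlc_network].
#' @export
to_igraph <- function(net) {
  stopifnot(inherits(net, "nlc_network"))
  off <- net$ei != net$ej
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$labels[c(net$ei[off], net$ei[!off])],
               to = net$labels[c(net$ej[off], net$ej[!off])],
               weight = c(net$w[off], net$w[!off] / 2)),
    directed = FALSE,
    vertices = data.frame(name = net$labels)
  )
  g
}

#' Induced subnetwork on a node subset
#'
#' Keeps the selected nodes and the edges with both endpoints inside the
#' selection (internal edges only).
#'
#' @param net an [nlc_network].
#' @param nodes integer indices or character labels of the nodes to keep.
#' @return an [nlc_network] on the selected nodes.
#' @export
induced_subnetwork <- function(net, nodes) {
  stopifnot(inherits(net, "nlc_network"))
  if (is.character(nodes)) nodes <- match(nodes, net$labels)
  nodes <- sort(unique(as.integer(nodes)))
  if (anyNA(nodes) || any(nodes < 1L) || any(nodes > net$n))
    stop("unknown node in `nodes`")
  keep <- net$ei %in% nodes & net$ej %in% nodes
  sub <- data.frame(a = net$labels[net$ei[keep]],
                    b = net$labels[net$ej[keep]],
                    w = ifelse(net$ei[keep] == net$ej[keep],
                               net$w[keep] / 2, net$w[keep]))
  nlc_network(sub, labels = net$labels[nodes])
}
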