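#' Degree-allocation community model
#'
#' The generative model's only parameters: an `n` x `c` nonnegative matrix
#' `D` whose entry `d_ik` is the expected degree that node `i` spends in
#' community `k`. A community is modeled as a degree-corrected random
#' graph with no internal structure, so within community `k` the expected
#' edge weight between `i` and `j` is `d_ik * d_jk / D_k` with
#' `D_k = sum_i d_ik`, and the whole network is the superposition of the
#' `c` communities. A fitted model satisfies the defining allocation
#' constraint `sum_k d_ik = d_i` (each node's expected degrees across
#' communities add up to its observed degree).
#'
#' @param D numeric `n` x `c` matrix of nonnegative expected degrees.
#' @param labels optional node labels (length `n`).
#' @return an object of class `nlc_model`.
#' @export
nlc_model <- function(D, labels = NULL) {
  D <- as.matrix(D)
  if (any(D < 0) || anyNA(D)) stop("expected degrees d_ik must be nonnegative")
  if (!is.null(labels)) {
    if (length(labels) != nrow(D)) stop("labels/D dimension mismatch")
    rownames(D) <- labels
  }
  structure(list(D = D, c = ncol(D)), class = "nlc_model")
}

#' @export
print.nlc_model <- function(x, ...) {
  cat(sprintf("nlc_model: %d nodes, %d communities, community sizes (sum d_ik): %s\n",
              nrow(x$D), x$c, paste(signif(colSums(x$D), 4), collapse = " ")))
  invisible(x)
}

.check_net_model <- function(net, model) {
  if (nrow(model$D) != net$n)
    stop("model has ", nrow(model$D), " nodes but network has ", net$n)
}

#' Expected edge weight inside one community
#'
#' The within-community null model: `d_ik * d_jk / D_k`, the expected
#' number of links (or link weight) between `i` and `j` contributed by
#' community `k`. An empty community (`D_k = 0`) contributes 0.
#'
#' @param model an [nlc_model].
#' @param i,j node indices.
#' @param k community index.
#' @return a nonnegative scalar rate.
#' @export
expected_weight <- function(model, i, j, k) {
  stopifnot(inherits(model, "nlc_model"))
  Dk <- sum(model$D[, k])
  if (Dk == 0) return(0)
  unname(model$D[i, k] * model$D[j, k] / Dk)
}

#' Expected weight matrix of the whole model
#'
#' Superposition over communities, `what_ij = sum_k d_ik d_jk / D_k`. When
#' the allocation constraint holds, its row sums reproduce the observed
#' degrees and the single-community case reduces exactly to the
#' configuration-model null of modularity, `d_i d_j / 2m`.
#'
#' @param model an [nlc_model].
#' @return symmetric nonnegative `n` x `n` matrix.
#' @export
expected_matrix <- function(model) {
  stopifnot(inherits(model, "nlc_model"))
  Dk <- colSums(model$D)
  pos <- Dk > 0
  if (!any(pos)) return(matrix(0, nrow(model$D), nrow(model$D)))
  X <- sweep(model$D[, pos, drop = FALSE], 2, sqrt(Dk[pos]), "/")
  tcrossprod(X)
}

#' Poisson log-likelihood of a network under a model
#'
#' Edge weights are treated as independent Poisson counts with mean
#' `what_ij`. Up to additive and multiplicative constants the log
#' likelihood is `sum_(i,j) [ w_ij log what_ij - what_ij ]`, summed over
#' ordered node pairs including self-pairs, with the convention
#' `0 log 0 = 0`. Since `sum_ij what_ij = sum_k D_k`, the subtracted mass
#' is computed in closed form. Returns `-Inf` when an observed edge has
#' zero expected weight.
#'
#' @param net an [nlc_network].
#' @param model an [nlc_model] with matching node count.
#' @return a scalar (possibly `-Inf`).
#' @export
log_likelihood <- function(net, model) {
  stopifnot(inherits(net, "nlc_network"))
  .check_net_model(net, model)
  or <- .nlc_orient(net)
  what <- .pair_rates_total(model, or$i, or$j)
  if (any(what == 0 & or$w > 0)) return(-Inf)
  pos <- or$w > 0
  sum(or$w[pos] * log(what[pos])) - sum(model$D)
}

# total expected weight for given index pairs, summed over communities
.pair_rates_total <- function(model, i, j) {
  Dk <- colSums(model$D)
  pos <- Dk > 0
  if (!any(pos)) return(numeric(length(i)))
  Dp <- model$D[, pos, drop = FALSE]
  R <- Dp[i, , drop = FALSE] * Dp[j, , drop = FALSE]
  R <- sweep(R, 2, Dk[pos], "/")
  rowSums(R)
}

# per-community expected weights for given index pairs (n_pairs x c)
.pair_rates <- function(model, i, j) {
  Dk <- colSums(model$D)
  R <- model$D[i, , drop = FALSE] * model$D[j, , drop = FALSE]
  R <- sweep(R, 2, ifelse(Dk > 0, Dk, 1), "/")
  R[, Dk == 0] <- 0
  R
}

#' Check the degree-allocation constraint of a model
#'
#' @param net an [nlc_network].
#' @param model an [nlc_model].
#' @param tol relative tolerance on `|sum_k d_ik - d_i|`.
#' @return logical; `TRUE` when every row of `D` sums to the node degree
#'   within `tol`.
#' @export
allocation_ok <- function(net, model, tol = 1e-6) {
  .check_net_model(net, model)
  d <- net$deg
  dev <- abs(rowSums(model$D) - d)
  all(dev <= tol * pmax(d, 1))
}
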