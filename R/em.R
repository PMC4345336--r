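#' Random initial model
#'
#' Draws, for every node, a uniform Dirichlet probability vector over the
#' `c` communities and scales it by the node degree, so the allocation
#' constraint `sum_k d_ik = d_i` holds exactly at initialization.
#' Deterministic under a fixed seed.
#'
#' @param net an [nlc_network].
#' @param c number of communities (>= 1).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return an [nlc_model].
#' @export
init_params <- function(net, c, seed = NULL) {
  stopifnot(inherits(net, "nlc_network"))
  if (c < 1) stop("c must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  P <- matrix(stats::rgamma(net$n * c, shape = 1), net$n, c)
  P <- P / rowSums(P)
  nlc_model(P * net$deg, labels = net$labels)
}

#' E-step: link responsibilities
#'
#' For every observed edge the posterior probability that it was generated
#' by community `k`: the community's expected weight for that pair,
#' normalized across communities. Rows sum to one.
#'
#' @param net an [nlc_network].
#' @param model an [nlc_model].
#' @return an object of class `nlc_resp`: matrix `q` (one row per stored
#'   edge of `net`, `c` columns) plus the endpoint indices `ei`, `ej`.
#' @export
e_step <- function(net, model) {
  stopifnot(inherits(net, "nlc_network"))
  .check_net_model(net, model)
  R <- .pair_rates(model, net$ei, net$ej)
  tot <- rowSums(R)
  if (any(tot == 0 & net$w > 0))
    stop("degenerate model: an observed edge has zero expected weight in every community")
  q <- R / ifelse(tot > 0, tot, 1)
  structure(list(q = q, ei = net$ei, ej = net$ej), class = "nlc_resp")
}

#' M-step: closed-form parameter update
#'
#' Given responsibilities, the maximizer of the expected complete-data
#' log-likelihood under the per-node allocation constraints is
#' `d_ik = sum_j w_ij q_ij,k`. Because each responsibility vector sums to
#' one, the constraint `sum_k d_ik = d_i` is satisfied automatically and
#' exactly.
#'
#' @param net an [nlc_network].
#' @param resp an `nlc_resp` from [e_step()].
#' @return an [nlc_model].
#' @export
m_step <- function(net, resp) {
  stopifnot(inherits(net, "nlc_network"), inherits(resp, "nlc_resp"))
  cc <- ncol(resp$q)
  off <- net$ei != net$ej
  gi <- c(net$ei[off], net$ej[off], net$ei[!off])
  qw <- rbind(resp$q[off, , drop = FALSE] * net$w[off],
              resp$q[off, , drop = FALSE] * net$w[off],
              resp$q[!off, , drop = FALSE] * net$w[!off])
  D <- matrix(0, net$n, cc)
  if (length(gi)) {
    ag <- rowsum(qw, gi)
    D[as.integer(rownames(ag)), ] <- ag
  }
  nlc_model(D, labels = net$labels)
}

#' Fit the model by expectation-maximization
#'
#' Alternates [e_step()] and [m_step()], which monotonically increases the
#' Poisson log-likelihood, over several random restarts and keeps the
#' restart with the highest final likelihood (first one wins a tie).
#' Communities whose total expected degree decays to zero are left dead
#' rather than re-seeded; surplus communities are pruned by the MDL-based
#' type/number selection downstream, not by the likelihood fit.
#'
#' @param net an [nlc_network] with at least one edge.
#' @param c number of communities.
#' @param restarts number of random initializations.
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood change declaring convergence.
#' @param seed integer seed driving all restarts.
#' @return an object of class `nlc_fit`: list with `model` ([nlc_model]),
#'   `loglik`, `trace` (per-iteration log-likelihood of the best restart),
#'   `resp` (converged responsibilities), `restart_logliks`, `method`.
#' @export
fit_em <- function(net, c, restarts = 10, max_iter = 500, tol = 1e-8,
                   seed = NULL) {
  stopifnot(inherits(net, "nlc_network"))
  if (c < 1) stop("c must be >= 1")
  if (length(net$w) == 0L) stop("cannot fit a model to a network with no edges")
  if (!is.null(seed)) set.seed(seed)
  or <- .nlc_orient(net)
  d <- net$deg
  n <- net$n
  finals <- numeric(restarts)
  models <- vector("list", restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    P <- matrix(stats::rgamma(n * c, shape = 1), n, c)
    D <- (P / rowSums(P)) * d
    trace <- numeric(0)
    L <- -Inf
    for (it in seq_len(max_iter)) {
      Dk <- colSums(D)
      pos <- Dk > 0
      R <- D[or$i, pos, drop = FALSE] * D[or$j, pos, drop = FALSE]
      R <- sweep(R, 2, Dk[pos], "/")
      tot <- rowSums(R)
      Lnew <- sum(or$w * log(tot)) - sum(Dk)
      trace <- c(trace, Lnew)
      q <- R / tot
      Dnew <- matrix(0, n, sum(pos))
      ag <- rowsum(q * or$w, or$i)
      Dnew[as.integer(rownames(ag)), ] <- ag
      D[, pos] <- Dnew
      D[, !pos] <- 0
      converged <- is.finite(Lnew) && is.finite(L) &&
        abs(Lnew - L) <= tol * abs(Lnew)
      L <- Lnew
      if (converged) break
    }
    finals[r] <- L
    models[[r]] <- D
    if (is.null(best) || L > best$loglik) {
      best <- list(D = D, loglik = L, trace = trace)
    }
  }
  model <- nlc_model(best$D, labels = net$labels)
  structure(list(model = model, loglik = best$loglik, trace = best$trace,
                 resp = e_step(net, model), restart_logliks = finals,
                 restart_models = lapply(models, nlc_model,
                                         labels = net$labels),
                 method = "em", c = c),
            class = "nlc_fit")
}

#' @export
print.nlc_fit <- function(x, ...) {
  cat(sprintf("nlc_fit (%s): c = %d, log-likelihood %.6g after %d iterations\n",
              x$method, x$c, x$loglik, length(x$trace)))
  invisible(x)
}
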