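#' Soft node memberships
#'
#' Probability that node `i` belongs to community `k`, taken as the share
#' of its degree the model allocates there: `S_ik = d_ik / d_i`. A node
#' joins the community to which it devotes most of its connectivity. Rows
#' of zero-degree nodes are zero (they are background).
#'
#' @param model an [nlc_model].
#' @return an `n` x `c` matrix with rows of positive-degree nodes summing
#'   to 1.
#' @export
node_memberships <- function(model) {
  stopifnot(inherits(model, "nlc_model"))
  rs <- rowSums(model$D)
  S <- model$D / ifelse(rs > 0, rs, 1)
  S[rs == 0, ] <- 0
  S
}

#' Soft link memberships
#'
#' Probability that an observed link was generated by community `k`: the
#' community's expected weight for that pair normalized across
#' communities. This coincides with the converged E-step responsibilities.
#'
#' @param net an [nlc_network].
#' @param model an [nlc_model].
#' @return matrix with one row per stored edge of `net` (rows sum to 1),
#'   with attributes `ei`, `ej` giving the endpoint indices.
#' @export
link_memberships <- function(net, model) {
  resp <- e_step(net, model)
  R <- resp$q
  attr(R, "ei") <- resp$ei
  attr(R, "ej") <- resp$ej
  R
}

# first-maximum argmax: ties broken toward the lowest community index
.argmax_rows <- function(M) max.col(M, ties.method = "first")

#' Harden soft memberships into a typed hybrid structure
#'
#' Given a community type vector, node-typed community `k` receives every
#' node whose best soft membership (argmax over `S_i`, ties to the lowest
#' index) is `k`; link-typed community `k` receives every link whose best
#' link membership is `k`. A node whose best community is link-typed joins
#' no node community (it may still be covered through adjacent links);
#' symmetrically a link whose best community is node-typed becomes a
#' background link. Zero-degree nodes are background.
#'
#' @param net an [nlc_network].
#' @param model an [nlc_model] fitted to `net`.
#' @param types character vector of length `c`, entries `"node"` or
#'   `"link"`.
#' @return an object of class `nlc_structure`: `types`, `node_sets`
#'   (list of node index vectors, `NULL`-length for link-typed entries),
#'   `link_sets` (edge index vectors into `net`'s edge list),
#'   `background_nodes`, `background_links`.
#' @export
harden <- function(net, model, types) {
  stopifnot(inherits(net, "nlc_network"))
  .check_net_model(net, model)
  types <- match.arg(types, c("node", "link"), several.ok = TRUE)
  if (length(types) != model$c) stop("`types` must have one entry per community")
  S <- node_memberships(model)
  R <- link_memberships(net, model)
  node_best <- .argmax_rows(S)
  link_best <- .argmax_rows(R)
  node_sets <- vector("list", model$c)
  link_sets <- vector("list", model$c)
  posdeg <- net$deg > 0
  for (k in seq_len(model$c)) {
    node_sets[[k]] <-
      if (types[k] == "node") which(node_best == k & posdeg) else integer(0)
    link_sets[[k]] <-
      if (types[k] == "link") which(link_best == k) else integer(0)
  }
  in_node_comm <- logical(net$n)
  for (M in node_sets) in_node_comm[M] <- TRUE
  touched <- logical(net$n)
  for (es in link_sets) touched[c(net$ei[es], net$ej[es])] <- TRUE
  structure(
    list(types = types, node_sets = node_sets, link_sets = link_sets,
         background_nodes = which(!posdeg | (!in_node_comm & !touched)),
         background_links = which(types[link_best] == "node"),
         n = net$n),
    class = "nlc_structure"
  )
}

#' @export
print.nlc_structure <- function(x, ...) {
  sz <- vapply(seq_along(x$types), function(k) {
    if (x$types[k] == "node") length(x$node_sets[[k]]) else length(x$link_sets[[k]])
  }, integer(1))
  cat(sprintf("nlc_structure: %d communities (%s)\n", length(x$types),
              paste(sprintf("%s:%d", x$types, sz), collapse = ", ")))
  cat(sprintf("  background: %d nodes, %d links\n",
              length(x$background_nodes), length(x$background_links)))
  invisible(x)
}

#' Search for the best community types
#'
#' Each of the `c` communities is independently node- or link-typed; the
#' best typing minimizes the map-equation description length of the
#' induced node cover. `mode = "exhaustive"` enumerates all `2^c`
#' combinations (the oracle, practical for `c <= 15`); `mode = "greedy"`
#' starts from random typings (plus the all-node and all-link typings, so
#' its result can never be worse than either pure scheme) and repeatedly
#' sweeps communities `1..c`, flipping a community's type whenever the
#' flip strictly lowers the description length, until a full sweep makes
#' no flip or `max_iter` sweeps have run.
#'
#' @param net an [nlc_network].
#' @param model a fitted [nlc_model].
#' @param mode `"greedy"` or `"exhaustive"`.
#' @param max_iter maximal number of greedy sweeps per start.
#' @param restarts random initial typings for the greedy search.
#' @param seed integer seed for the random initial typings.
#' @param split overlap flow split passed to [map_equation_mdl()].
#' @return list with `types`, `structure` ([harden()] result), `mdl`.
#' @export
search_types <- function(net, model, mode = c("greedy", "exhaustive"),
                         max_iter = 50, restarts = 5, seed = NULL,
                         split = "proportional") {
  stopifnot(inherits(net, "nlc_network"))
  .check_net_model(net, model)
  mode <- match.arg(mode)
  cc <- model$c
  # the hard node/link assignments do not depend on the typing, so compute
  # them once and rebuild only the cover when scoring a typing
  node_best <- .argmax_rows(node_memberships(model))
  link_best <- .argmax_rows(link_memberships(net, model))
  posdeg <- net$deg > 0
  score <- function(types) {
    mods <- vector("list", cc)
    for (k in seq_len(cc)) {
      mods[[k]] <- if (types[k] == "node") {
        which(node_best == k & posdeg)
      } else {
        es <- which(link_best == k)
        unique(c(net$ei[es], net$ej[es]))
      }
    }
    mods <- mods[lengths(mods) > 0L]
    covered <- logical(net$n)
    for (M in mods) covered[M] <- TRUE
    mods <- c(mods, as.list(which(!covered & posdeg)))
    map_equation_mdl(net, nlc_cover(mods, net$n), split = split)
  }
  if (mode == "exhaustive") {
    if (cc > 15) stop("exhaustive enumeration limited to c <= 15")
    best <- NULL
    for (mask in 0:(2^cc - 1)) {
      types <- ifelse(bitwAnd(mask, 2^(seq_len(cc) - 1)) > 0, "link", "node")
      v <- score(types)
      if (is.null(best) || v < best$mdl) best <- list(types = types, mdl = v)
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    starts <- c(list(rep("node", cc), rep("link", cc)),
                replicate(restarts,
                          sample(c("node", "link"), cc, replace = TRUE),
                          simplify = FALSE))
    best <- NULL
    for (types in starts) {
      v <- score(types)
      for (sweep_i in seq_len(max_iter)) {
        improved <- FALSE
        for (k in seq_len(cc)) {
          cand <- types
          cand[k] <- if (types[k] == "node") "link" else "node"
          vc <- score(cand)
          if (vc < v) {
            types <- cand
            v <- vc
            improved <- TRUE
          }
        }
        if (!improved) break
      }
      if (is.null(best) || v < best$mdl) best <- list(types = types, mdl = v)
    }
  }
  st <- harden(net, model, best$types)
  list(types = best$types, structure = st, mdl = best$mdl)
}

#' End-to-end community detection
#'
#' Fits the degree-allocation model (EM or NMF), derives soft node and
#' link memberships, hardens them under the requested scheme (`"node"`
#' types every community as a node community, `"link"` as a link
#' community, `"hybrid"` searches the typings), and scores the induced
#' cover by the map equation.
#'
#' @param net an [nlc_network].
#' @param c number of communities.
#' @param scheme `"hybrid"`, `"node"` or `"link"`.
#' @param method `"em"` or `"nmf"`.
#' @param restarts,max_iter,tol fitting controls, see [fit_em()] /
#'   [fit_nmf()].
#' @param type_mode `"greedy"` or `"exhaustive"` typing search for the
#'   hybrid scheme.
#' @param split overlap flow split of the map equation.
#' @param seed integer seed covering the fit and the typing search.
#' @return an object of class `nlc_result`: `network`, `fit`, `model`,
#'   `S`, `R`, `types`, `structure`, `cover`, `mdl`, `loglik`, `scheme`,
#'   `method`, `c`, `seed`.
#' @export
detect_communities <- function(net, c, scheme = c("hybrid", "node", "link"),
                               method = c("em", "nmf"), restarts = 10,
                               max_iter = NULL, tol = 1e-8,
                               type_mode = c("greedy", "exhaustive"),
                               split = "proportional", seed = NULL) {
  stopifnot(inherits(net, "nlc_network"))
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  type_mode <- match.arg(type_mode)
  if (!is.null(seed)) set.seed(seed)
  fit <- if (method == "em") {
    fit_em(net, c, restarts = restarts,
           max_iter = if (is.null(max_iter)) 500 else max_iter, tol = tol)
  } else {
    fit_nmf(net, c, restarts = restarts,
            max_iter = if (is.null(max_iter)) 1000 else max_iter, tol = tol)
  }
  infer <- function(model) {
    if (scheme == "hybrid") {
      sr <- search_types(net, model, mode = type_mode, split = split)
      list(model = model, types = sr$types, st = sr$structure, mdl = sr$mdl)
    } else {
      types <- rep(scheme, c)
      st <- harden(net, model, types)
      list(model = model, types = types, st = st,
           mdl = map_equation_mdl(net, induced_cover(st, net), split = split))
    }
  }
  # the fit objective can have exactly tied optima (e.g. an inter-community
  # edge explained equally well from either side of a bridge); restarts tied
  # in likelihood are resolved by the method's own structure criterion, the
  # description length of the inferred structure, in restart order on exact
  # ties
  scores <- fit$restart_logliks
  tied <- which(scores >= max(scores) - 1e-6 * max(abs(max(scores)), 1))
  keys <- vapply(fit$restart_models[tied], function(m) {
    D <- round(m$D, 4)  # column order is arbitrary: canonicalize it
    cols <- apply(D, 2, paste, collapse = ",")
    paste(cols[order(cols)], collapse = ";")
  }, character(1))
  cands <- fit$restart_models[tied][!duplicated(keys)]
  picks <- lapply(cands, infer)
  res <- picks[[which.min(vapply(picks, `[[`, numeric(1), "mdl"))]]
  model <- res$model
  types <- res$types
  st <- res$st
  mdl <- res$mdl
  structure(
    list(network = net, fit = fit, model = model,
         S = node_memberships(model), R = link_memberships(net, model),
         types = types, structure = st, cover = induced_cover(st, net),
         mdl = mdl, loglik = log_likelihood(net, model), scheme = scheme,
         method = method,
         c = c, seed = seed),
    class = "nlc_result"
  )
}

#' @export
print.nlc_result <- function(x, ...) {
  cat(sprintf("nlc_result: %s scheme, %s fit, c = %d\n",
              x$scheme, toupper(x$method), x$c))
  cat(sprintf("  log-likelihood %.6g, MDL %.4f bits\n", x$loglik, x$mdl))
  print(x$structure)
  invisible(x)
}
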