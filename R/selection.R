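#' Select the number of communities by MDL sweep
#'
#' Runs [detect_communities()] for every candidate community count and
#' returns the result with the shortest map-equation description length
#' together with the full MDL-versus-c curve. Ties go to the smallest
#' `c`.
#'
#' @param net an [nlc_network].
#' @param c_min,c_max inclusive sweep range (`1 <= c_min <= c_max`).
#' @param scheme,method,restarts,type_mode,split,seed passed to
#'   [detect_communities()]; each `c` uses the seed offset `seed + c` so
#'   runs are independent but reproducible.
#' @param ... further arguments to [detect_communities()].
#' @return list with `best` (an `nlc_result`), `best_c`, and `curve`
#'   (data frame with columns `c`, `mdl`, `loglik`).
#' @export
sweep_c <- function(net, c_min, c_max, scheme = "hybrid", method = "em",
                    restarts = 10, type_mode = "greedy",
                    split = "proportional", seed = NULL, ...) {
  stopifnot(inherits(net, "nlc_network"), c_min >= 1, c_min <= c_max)
  cs <- seq.int(c_min, c_max)
  results <- vector("list", length(cs))
  for (idx in seq_along(cs)) {
    results[[idx]] <- detect_communities(
      net, cs[idx], scheme = scheme, method = method, restarts = restarts,
      type_mode = type_mode, split = split,
      seed = if (is.null(seed)) NULL else seed + cs[idx], ...)
  }
  curve <- data.frame(c = cs,
                      mdl = vapply(results, function(r) r$mdl, numeric(1)),
                      loglik = vapply(results, function(r) r$loglik, numeric(1)))
  best_idx <- which.min(curve$mdl)
  list(best = results[[best_idx]], best_c = cs[best_idx], curve = curve)
}

#' Recursive bipartition for networks of unknown community count
#'
#' Hierarchically splits the network without fixing the number of
#' communities in advance: starting from one part holding all nodes, each
#' part is tentatively refit with `c = 2` on its induced subnetwork and
#' hardened into two node groups by best soft membership; the split is
#' accepted only if it lowers the global map-equation description length
#' of the assembled partition. Accepted parts are pushed back for further
#' splitting; parts smaller than `min_size` are never split. When the
#' recursion stops, community types are searched once over the final
#' parts using the degree allocation the partition itself induces
#' (`d_ik` = node `i`'s edge weight into part `k`, which satisfies the
#' allocation constraint exactly).
#'
#' @param net an [nlc_network].
#' @param method `"em"` or `"nmf"` for the per-part fits.
#' @param min_size parts below this size are final.
#' @param restarts restarts of each `c = 2` fit.
#' @param type_mode,split typing-search controls, see [search_types()].
#' @param seed integer seed.
#' @return list with `structure` (`nlc_structure` over the final
#'   communities), `types`, `cover`, `mdl`, `parts` (list of node index
#'   vectors), `model` (the partition-induced [nlc_model]).
#' @export
recursive_bipartition <- function(net, method = c("em", "nmf"), min_size = 3,
                                  restarts = 10,
                                  type_mode = c("greedy", "exhaustive"),
                                  split = "proportional", seed = NULL) {
  stopifnot(inherits(net, "nlc_network"))
  method <- match.arg(method)
  type_mode <- match.arg(type_mode)
  if (!is.null(seed)) set.seed(seed)
  fitfun <- function(subnet, cc) {
    if (method == "em") fit_em(subnet, cc, restarts = restarts)
    else fit_nmf(subnet, cc, restarts = restarts)
  }
  active <- which(net$deg > 0)
  final <- list()
  queue <- if (length(active)) list(active) else list()
  global_mdl <- function(parts) {
    map_equation_mdl(net, nlc_cover(parts, net$n), split = split)
  }
  while (length(queue)) {
    part <- queue[[1L]]
    queue <- queue[-1L]
    if (length(part) < 2L * min_size) {
      final <- c(final, list(part))
      next
    }
    subnet <- induced_subnetwork(net, part)
    if (length(subnet$w) == 0L) {
      final <- c(final, list(part))
      next
    }
    fit <- fitfun(subnet, 2L)
    grp <- .argmax_rows(node_memberships(fit$model))
    grp[subnet$deg == 0] <- 1L
    halves <- lapply(1:2, function(g) part[grp == g])
    if (any(lengths(halves) < min_size)) {
      final <- c(final, list(part))
      next
    }
    others <- c(final, queue)
    before <- global_mdl(c(others, list(part)))
    after <- global_mdl(c(others, halves))
    if (after < before) {
      queue <- c(queue, halves)
    } else {
      final <- c(final, list(part))
    }
  }
  if (length(final) == 0L) stop("network has no edges")
  # partition-induced degree allocation: d_ik = weight of i into part k
  or <- .nlc_orient(net)
  memb <- integer(net$n)
  for (k in seq_along(final)) memb[final[[k]]] <- k
  D <- matrix(0, net$n, length(final))
  sel <- memb[or$j] > 0
  if (any(sel)) {
    ag <- rowsum(or$w[sel], paste(or$i[sel], memb[or$j[sel]]))
    key <- do.call(rbind, strsplit(rownames(ag), " ", fixed = TRUE))
    D[cbind(as.integer(key[, 1L]), as.integer(key[, 2L]))] <- ag[, 1L]
  }
  model <- nlc_model(D, labels = net$labels)
  sr <- search_types(net, model, mode = type_mode, split = split)
  list(structure = sr$structure, types = sr$types,
       cover = induced_cover(sr$structure, net), mdl = sr$mdl,
       parts = final, model = model)
}
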