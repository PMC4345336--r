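# shared builders and oracles for the test suite

make_net <- function(el, labels = NULL, w = NULL) {
  el <- as.matrix(el)
  df <- data.frame(a = as.character(el[, 1L]), b = as.character(el[, 2L]))
  if (!is.null(w)) df$w <- w
  nlc_network(df, labels = labels)
}

k2_net <- function() make_net(rbind(c("a", "b")))

path3_net <- function() make_net(rbind(c("a", "b"), c("b", "c")))

two_triangles <- function() {
  make_net(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                 c("d", "e"), c("e", "f"), c("d", "f")))
}

# Erdos-Renyi graph with at least one edge, labels "1".."n"
rand_gnp <- function(n, p, seed, weighted = FALSE) {
  set.seed(seed)
  repeat {
    sel <- which(upper.tri(matrix(0, n, n)) &
                   matrix(stats::runif(n * n) < p, n, n), arr.ind = TRUE)
    if (nrow(sel) >= 1L) break
  }
  w <- if (weighted) sample(1:3, nrow(sel), replace = TRUE) else NULL
  make_net(cbind(as.character(sel[, 1L]), as.character(sel[, 2L])),
           labels = as.character(seq_len(n)), w = w)
}

# reference converged parameters of the 14-node worked example
# (three communities; columns are nodes 1..14); entries below 1e-3 are
# structural zeros for comparison purposes
toy14_reference <- function() {
  rbind(
    c(0, 0, 0, 0, 0, 0, 0, 0, 0.999991, 4.999991, 4, 4, 4, 4),
    c(3.999987, 3.999987, 3.999986, 3.999987, 3.999946, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 4.000054, 4, 4, 4, 4.000009, 0, 0, 0, 0, 0)
  )
}

# best column permutation of fitted D (n x c) against a reference (c x n);
# returns max abs deviation over reference entries >= 1e-3
align_deviation <- function(D, ref) {
  cc <- nrow(ref)
  stopifnot(ncol(D) == cc)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  best <- Inf
  mask <- ref >= 1e-3
  for (pp in perms(seq_len(cc))) {
    Dt <- t(D[, pp, drop = FALSE])
    dev <- max(abs(Dt - ref)[mask])
    # entries that should be ~0 must be small too
    dev <- max(dev, max(abs(Dt[!mask])))
    best <- min(best, dev)
  }
  best
}

# independent disjoint-partition map equation: the expanded closed form
# L = plogp(q) - 2 sum_k plogp(q_k) - sum_i plogp(p_i)
#     + sum_k plogp(q_k + sum_{i in k} p_i)
# (a different algebraic route than the per-module entropy computation)
mapeq_disjoint_oracle <- function(net, parts) {
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  W <- weight_matrix(net)
  d <- net$deg
  m2 <- sum(d)
  p <- d / m2
  qk <- vapply(parts, function(M) {
    sum(W[M, setdiff(seq_len(net$n), M), drop = FALSE]) / m2
  }, numeric(1))
  q <- sum(qk)
  pk <- vapply(parts, function(M) sum(p[M]), numeric(1))
  plogp(q) - 2 * sum(plogp(qk)) - sum(plogp(p)) + sum(plogp(qk + pk))
}

# direct evaluation of the overlapping-cover NMI via explicit loops over
# binary membership variables (oracle for the vectorized implementation)
nmi_bruteforce <- function(A, B, n) {
  h <- function(p) if (p > 0) -p * log2(p) else 0
  H2 <- function(p) h(p) + h(1 - p)
  cond <- function(X, Y) {
    tot <- 0
    for (xk in X) {
      x <- seq_len(n) %in% xk
      Hx <- H2(mean(x))
      if (Hx == 0) next
      best <- Hx
      for (yl in Y) {
        y <- seq_len(n) %in% yl
        a <- sum(!x & !y) / n; b <- sum(!x & y) / n
        cns <- sum(x & !y) / n; dns <- sum(x & y) / n
        if (h(dns) + h(a) < h(b) + h(cns)) next
        val <- h(a) + h(b) + h(cns) + h(dns) - H2(mean(y))
        if (val < best) best <- val
      }
      tot <- tot + best / Hx
    }
    tot / length(X)
  }
  1 - (cond(A, B) + cond(B, A)) / 2
}

# numerical maximization of the EM auxiliary objective in d (rows
# constrained to the degree sequence via softmax), used as the M-step oracle
aux_oracle <- function(net, resp, c, n_starts = 4, seed = 99) {
  set.seed(seed)
  or <- nlcomm:::.nlc_orient(net)
  # responsibilities for the both-orientation expansion
  qfull <- rbind(resp$q[net$ei != net$ej, , drop = FALSE],
                 resp$q[net$ei != net$ej, , drop = FALSE],
                 resp$q[net$ei == net$ej, , drop = FALSE])
  obj <- function(theta) {
    Z <- matrix(theta, net$n, c)
    P <- exp(Z - apply(Z, 1, max))
    D <- (P / rowSums(P)) * net$deg
    Dk <- colSums(D)
    lr <- log(pmax(D[or$i, , drop = FALSE], 1e-300)) +
      log(pmax(D[or$j, , drop = FALSE], 1e-300)) -
      rep(log(pmax(Dk, 1e-300)), each = length(or$i))
    -sum(or$w * qfull * lr)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- stats::rnorm(net$n * c, sd = if (s == 1) 0 else 1)
    fit <- stats::optim(th0, obj, method = "BFGS",
                        control = list(maxit = 10000, reltol = 1e-15))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  Z <- matrix(best$par, net$n, c)
  P <- exp(Z - apply(Z, 1, max))
  (P / rowSums(P)) * net$deg
}

# numerical maximization of the Poisson log-likelihood itself over
# degree-constrained models (oracle for best-of-restarts EM)
loglik_oracle <- function(net, c, n_starts = 8, seed = 17) {
  set.seed(seed)
  obj <- function(theta) {
    Z <- matrix(theta, net$n, c)
    P <- exp(Z - apply(Z, 1, max))
    D <- (P / rowSums(P)) * net$deg
    -log_likelihood(net, nlc_model(D))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    th0 <- stats::rnorm(net$n * c, sd = if (s == 1) 0.01 else 1.5)
    fit <- stats::optim(th0, obj, method = "BFGS",
                        control = list(maxit = 10000, reltol = 1e-15))
    best <- min(best, fit$value)
  }
  -best
}
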