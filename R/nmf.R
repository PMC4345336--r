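#' Convert between a degree model and its factor matrix
#'
#' The squared-loss fit works on the auxiliary nonnegative factor
#' `X_ik = d_ik / sqrt(D_k)` (zero column when the community is empty),
#' chosen so that `X %*% t(X)` equals the model's expected weight matrix.
#' The inverse uses the identity `sqrt(D_k) = sum_i X_ik`, giving
#' `d_ik = X_ik * sum_j X_jk`. The two maps are mutually inverse on any
#' valid model.
#'
#' @param model an [nlc_model].
#' @return `model_to_factor`: a nonnegative `n` x `c` matrix.
#' @export
model_to_factor <- function(model) {
  stopifnot(inherits(model, "nlc_model"))
  Dk <- colSums(model$D)
  X <- sweep(model$D, 2, ifelse(Dk > 0, sqrt(Dk), 1), "/")
  X[, Dk == 0] <- 0
  X
}

#' @rdname model_to_factor
#' @param X a nonnegative `n` x `c` factor matrix.
#' @param labels optional node labels.
#' @return `factor_to_model`: an [nlc_model] with `d_ik = X_ik * sum_j X_jk`.
#' @export
factor_to_model <- function(X, labels = NULL) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("factor matrix must be nonnegative")
  nlc_model(sweep(X, 2, colSums(X), "*"), labels = labels)
}

#' Penalized symmetric factorization objective
#'
#' `O = ||A - X X'||_F^2 + lambda * ||X X' 1 - d||^2`: squared
#' reconstruction error of the weight matrix plus a penalty on violating
#' the degree-allocation constraint (the row sums of the expected matrix
#' must equal the observed degrees). `lambda` weighs the hard constraint;
#' `lambda = 0` is plain symmetric NMF.
#'
#' @param net an [nlc_network].
#' @param X nonnegative `n` x `c` factor matrix.
#' @param lambda nonnegative penalty weight.
#' @return a nonnegative scalar.
#' @export
nmf_objective <- function(net, X, lambda = 0) {
  stopifnot(inherits(net, "nlc_network"), lambda >= 0)
  X <- as.matrix(X)
  if (nrow(X) != net$n) stop("X/network dimension mismatch")
  A <- weight_matrix(net)
  E <- A - tcrossprod(X)
  r <- as.vector(tcrossprod(X) %*% rep(1, net$n)) - net$deg
  sum(E^2) + lambda * sum(r^2)
}

#' One multiplicative update of the factor matrix
#'
#' Gradient-descent step in multiplicative form, splitting the gradient of
#' the penalized objective into its positive and negative parts:
#' numerator `A X + (lambda/2)(d 1' + 1 d') X`, denominator
#' `X X' X + (lambda/2)(w 1' + 1 w') X` with `w = X X' 1`, applied as
#' `X <- X * (num/den)^eta`. The damping exponent `eta = 1/2` keeps the
#' objective non-increasing (verified property, not assumed); entries are
#' floored at `1e-12` because a multiplicative rule cannot leave zero.
#'
#' @param net an [nlc_network].
#' @param X nonnegative factor matrix.
#' @param lambda penalty weight.
#' @param eta damping exponent of the multiplicative rule.
#' @return updated factor matrix of the same shape.
#' @export
nmf_update <- function(net, X, lambda = 0, eta = 0.5) {
  stopifnot(inherits(net, "nlc_network"))
  X <- pmax(as.matrix(X), 1e-12)
  A <- weight_matrix(net)
  d <- net$deg
  s <- colSums(X)
  AX <- A %*% X
  XtX <- crossprod(X)
  XXtX <- X %*% XtX
  w <- as.vector(X %*% (crossprod(X, rep(1, net$n))))
  num <- AX + (lambda / 2) * (outer(d, s) +
    matrix(as.vector(crossprod(X, d)), net$n, ncol(X), byrow = TRUE))
  den <- XXtX + (lambda / 2) * (outer(w, s) +
    matrix(as.vector(crossprod(X, w)), net$n, ncol(X), byrow = TRUE))
  Xn <- pmax(X * (num / pmax(den, 1e-300))^eta, 1e-12)
  dimnames(Xn) <- NULL
  Xn
}

#' Fit the model by penalized symmetric NMF
#'
#' Two-phase schedule: first minimize the unpenalized reconstruction error
#' (`lambda = 0`) to convergence to obtain a good starting factor, then
#' restart from it with a large penalty (`lambda = 1000`) so the
#' degree-allocation constraint is satisfied up to a small relative
#' residual. The multiplicative update keeps the objective non-increasing
#' in each phase. Several random restarts; the factor with the lowest
#' final penalized objective wins.
#'
#' @param net an [nlc_network] with at least one edge.
#' @param c number of communities.
#' @param restarts number of random initializations.
#' @param max_iter maximum updates per phase.
#' @param tol relative objective change declaring convergence.
#' @param lambda penalty weight of the second phase.
#' @param eta damping exponent, see [nmf_update()].
#' @param seed integer seed.
#' @return an `nlc_fit` (see [fit_em()]); `trace` holds the phase-2
#'   objective values and `objective` the final one. The returned model is
#'   `factor_to_model` of the best factor; `loglik` re-evaluates the
#'   Poisson log-likelihood of that model for comparability with EM fits.
#' @export
fit_nmf <- function(net, c, restarts = 10, max_iter = 1000, tol = 1e-8,
                    lambda = 1000, eta = 0.5, seed = NULL) {
  stopifnot(inherits(net, "nlc_network"))
  if (c < 1) stop("c must be >= 1")
  if (length(net$w) == 0L) stop("cannot fit a model to a network with no edges")
  if (!is.null(seed)) set.seed(seed)
  A <- weight_matrix(net)
  d <- net$deg
  n <- net$n
  run_phase <- function(X, lam) {
    obj <- nmf_objective(net, X, lam)
    trace <- obj
    for (it in seq_len(max_iter)) {
      X <- nmf_update(net, X, lam, eta)
      newobj <- nmf_objective(net, X, lam)
      trace <- c(trace, newobj)
      if (abs(obj - newobj) <= tol * max(abs(obj), 1)) {
        obj <- newobj
        break
      }
      obj <- newobj
    }
    list(X = X, obj = obj, trace = trace)
  }
  best <- NULL
  finals <- numeric(restarts)
  models <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    P <- matrix(stats::rgamma(n * c, shape = 1), n, c)
    X0 <- model_to_factor(nlc_model((P / rowSums(P)) * d))
    ph1 <- run_phase(pmax(X0, 1e-12), 0)
    ph2 <- run_phase(ph1$X, lambda)
    finals[r] <- ph2$obj
    models[[r]] <- factor_to_model(ph2$X, labels = net$labels)
    if (is.null(best) || ph2$obj < best$obj) {
      best <- list(X = ph2$X, obj = ph2$obj, trace = ph2$trace)
    }
  }
  model <- factor_to_model(best$X, labels = net$labels)
  structure(list(model = model, loglik = log_likelihood(net, model),
                 objective = best$obj, trace = best$trace,
                 resp = e_step(net, model), restart_logliks = -finals,
                 restart_models = models,
                 method = "nmf", c = c),
            class = "nlc_fit")
}
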