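# Gaussian-process binary classification internals: squared-exponential
# kernel over encoded TCR vectors, Bernoulli (logistic) likelihood, Laplace
# approximation of the posterior and of the marginal likelihood
# (Rasmussen & Williams-style mode finding with the stable sqrt(W)
# parameterization).

# pairwise squared Euclidean distances between rows of X and Y
sq_dists <- function(X, Y = X) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  d2
}

se_kernel <- function(D2, sigma_f, lengthscale) {
  sigma_f^2 * exp(-D2 / (2 * lengthscale^2))
}

# Laplace approximation at fixed kernel matrix K; y in {-1, +1}.
# Returns the posterior mode f, the gradient of the log-likelihood at the
# mode (used for predictive means), sqrt(W), the Cholesky factor of
# B = I + sqrt(W) K sqrt(W), and the approximate log marginal likelihood.
gp_laplace <- function(K, y, maxit = 60L, tol = 1e-8) {
  n <- length(y)
  f <- numeric(n)
  obj_old <- -Inf
  converged <- FALSE
  L <- NULL
  for (it in seq_len(maxit)) {
    p <- stats::plogis(f)
    W <- pmax(p * (1 - p), 1e-12)
    sW <- sqrt(W)
    B <- diag(n) + (sW %o% sW) * K
    L <- chol(B)
    grad <- (y + 1) / 2 - p
    b <- W * f + grad
    a <- b - sW * backsolve(L, forwardsolve(t(L), sW * (K %*% b)))
    f <- as.vector(K %*% a)
    loglik <- -sum(log1p(exp(-y * f)))
    obj <- -0.5 * sum(a * f) + loglik
    if (is.finite(obj) && abs(obj - obj_old) < tol) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  if (!converged) {
    warning("Laplace mode finding did not converge in ", maxit,
            " iterations; using best state")
  }
  # recompute the approximation quantities at the final mode
  p <- stats::plogis(f)
  W <- pmax(p * (1 - p), 1e-12)
  sW <- sqrt(W)
  L <- chol(diag(n) + (sW %o% sW) * K)
  grad <- (y + 1) / 2 - p
  loglik <- -sum(log1p(exp(-y * f)))
  # at the mode f = K grad, so the quadratic term -f' K^-1 f / 2 = -f'grad/2
  logZ <- -0.5 * sum(f * grad) + loglik - sum(log(diag(L)))
  list(f = f, grad = grad, sW = sW, L = L, logZ = logZ)
}

# predictive class probabilities for encoded rows Xs, with the MacKay
# probit-style correction for the logistic integral
gp_predict <- function(fit, Xtrain, Xs, sigma_f, lengthscale) {
  Ks <- se_kernel(sq_dists(Xs, Xtrain), sigma_f, lengthscale)
  fmean <- as.vector(Ks %*% fit$grad)
  v <- forwardsolve(t(fit$L), fit$sW * t(Ks))
  fvar <- pmax(sigma_f^2 - colSums(v^2), 1e-12)
  kappa <- 1 / sqrt(1 + pi * fvar / 8)
  stats::plogis(kappa * fmean)
}

# approximate negative log marginal likelihood as a function of
# theta = (log sigma_f, log lengthscale), at precomputed squared distances
gp_nlml <- function(theta, D2, y) {
  K <- se_kernel(D2, exp(theta[1]), exp(theta[2])) +
    diag(1e-6, nrow(D2))
  fit <- suppressWarnings(gp_laplace(K, y, maxit = 40L))
  if (!is.finite(fit$logZ)) 1e10 else -fit$logZ
}

# L-BFGS-B maximization of the approximate marginal likelihood on a seeded
# subsample; fixed initialization sigma_f = 1, lengthscale = median
# pairwise distance
gp_optimize_hypers <- function(X, y, subsample = 1000L, seed = 1L,
                               maxit = 15L) {
  n <- nrow(X)
  idx <- if (n > subsample) {
    withr::with_seed(seed, sample.int(n, subsample))
  } else {
    seq_len(n)
  }
  D2 <- sq_dists(X[idx, , drop = FALSE])
  med <- sqrt(stats::median(D2[upper.tri(D2)][D2[upper.tri(D2)] > 0]))
  if (!is.finite(med) || med <= 0) med <- 1
  init <- c(0, log(med))
  opt <- try(stats::optim(init, gp_nlml, D2 = D2, y = y[idx],
                          method = "L-BFGS-B",
                          lower = init + c(log(0.2), log(0.1)),
                          upper = init + c(log(20), log(10)),
                          control = list(maxit = maxit)),
             silent = TRUE)
  theta <- if (inherits(opt, "try-error")) init else opt$par
  list(sigma_f = exp(theta[1]), lengthscale = exp(theta[2]))
}
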