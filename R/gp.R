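# Gaussian-process surrogate for Bayesian optimization, on inputs scaled to
# the unit cube with standardized responses. Matern 5/2 covariance with
# per-dimension (ARD) lengthscales: an isotropic grid search by marginal
# likelihood, followed by one coordinate-descent pass over per-dimension
# multipliers. Robust, derivative-free, and cheap next to the cost of one
# simulation call.

matern52 <- function(d2) {
  a <- sqrt(5 * d2)
  (1 + a + a * a / 3) * exp(-a)
}

cross_dist2 <- function(A, B) {
  # squared Euclidean distances between rows of A and rows of B
  an <- rowSums(A * A)
  bn <- rowSums(B * B)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  pmax(d2, 0)
}

gp_loglik <- function(X, z, ls, noise) {
  Xs <- sweep(X, 2, ls, "/")
  K <- matern52(cross_dist2(Xs, Xs))
  diag(K) <- diag(K) + noise
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  alpha <- backsolve(L, forwardsolve(t(L), z))
  ll <- -0.5 * sum(z * alpha) - sum(log(diag(L))) -
    0.5 * length(z) * log(2 * pi)
  if (!is.finite(ll)) return(NULL)
  list(ll = ll, L = L, alpha = alpha)
}

gp_train <- function(X, y, ls_grid = c(0.1, 0.2, 0.4, 0.7, 1.2, 2),
                     noise_grid = c(1e-6, 1e-4, 1e-2, 0.1, 0.5),
                     hypers = NULL) {
  d <- ncol(X)
  ym <- mean(y)
  ys <- stats::sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  z <- (y - ym) / ys
  best <- NULL
  if (!is.null(hypers)) {
    fit <- gp_loglik(X, z, hypers$ls, hypers$noise)
    if (!is.null(fit))
      best <- c(fit, list(ls = hypers$ls, noise = hypers$noise))
  }
  if (is.null(best)) {
    for (ls in ls_grid) for (nv in noise_grid) {
      fit <- gp_loglik(X, z, rep(ls, d), nv)
      if (!is.null(fit) && (is.null(best) || fit$ll > best$ll))
        best <- c(fit, list(ls = rep(ls, d), noise = nv))
    }
    if (is.null(best)) stop("GP training failed: no valid Cholesky factor")
    # one coordinate-descent pass of per-dimension lengthscale multipliers
    for (j in seq_len(d)) {
      for (mult in c(0.3, 3)) {
        ls_try <- best$ls
        ls_try[j] <- ls_try[j] * mult
        fit <- gp_loglik(X, z, ls_try, best$noise)
        if (!is.null(fit) && fit$ll > best$ll)
          best <- c(fit, list(ls = ls_try, noise = best$noise))
      }
    }
  }
  list(X = X, Xs = sweep(X, 2, best$ls, "/"), ym = ym, ys = ys, L = best$L,
       alpha = best$alpha, ls = best$ls, noise = best$noise, ll = best$ll)
}

gp_predict <- function(gp, Xnew) {
  Xns <- sweep(Xnew, 2, gp$ls, "/")
  Ks <- matern52(cross_dist2(Xns, gp$Xs))
  mu <- as.vector(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$L), t(Ks))
  s2 <- pmax(1 - colSums(v * v), 1e-12)
  list(mean = mu, sd = sqrt(s2))  # standardized scale
}

# Acquisition scores for minimization on the standardized scale; larger is
# better for all three (LCB is negated).
acquisition_scores <- function(pred, best_z, kappa = 1.96, xi = 0.01) {
  mu <- pred$mean
  s <- pred$sd
  imp <- best_z - mu - xi
  z <- imp / s
  list(
    lcb = -(mu - kappa * s),
    ei = imp * stats::pnorm(z) + s * stats::dnorm(z),
    pi = stats::pnorm(z))
}
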