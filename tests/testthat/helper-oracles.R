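# Shared fixtures and independent oracles for the test suite.

# Random regression data frame (predictors x1..xp, response y)
rand_reg_df <- function(N, p, seed, xmean = 0, xsd = 1, noise = 1,
                        beta = NULL, intercept = 0) {
  set.seed(seed)
  X <- matrix(rnorm(N * p, xmean, xsd), N, p)
  beta <- beta %||% runif(p, -2, 2)
  y <- intercept + drop(X %*% beta) + noise * rnorm(N)
  d <- as.data.frame(X)
  names(d) <- paste0("x", seq_len(p))
  d$y <- y
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Penalty kappa(beta) under each metric, recomputed independently of the
# package's dual_norm (plain arithmetic)
kappa_oracle <- function(kind, beta, Minv = NULL) {
  switch(kind,
    l1 = max(max(abs(beta)), 1),
    l2 = sqrt(sum(beta^2) + 1),
    linf = sum(abs(beta)) + 1,
    weighted = { v <- c(-beta, 1); sqrt(drop(crossprod(v, Minv %*% v))) })
}

# Dense multi-stage grid search of the DRO objective over beta (p = 1 or 2,
# no intercept). Independent of the package solvers.
grid_min_wdro <- function(X, y, eps, kind, Minv = NULL, lim = 4) {
  p <- ncol(X)
  obj_at <- function(Bgrid) {
    # Bgrid: G x p matrix of candidate betas
    R <- matrix(y, nrow(X), nrow(Bgrid)) - X %*% t(Bgrid)
    loss <- colMeans(abs(R))
    pen <- apply(Bgrid, 1, function(b) kappa_oracle(kind, b, Minv))
    loss + eps * pen
  }
  centers <- rep(0, p); h <- if (p == 1) 0.02 else 0.05
  half <- lim
  best <- Inf
  for (stage in 1:4) {
    axes <- lapply(seq_len(p), function(j) {
      seq(centers[j] - half, centers[j] + half, by = h)
    })
    Bgrid <- as.matrix(expand.grid(axes))
    vals <- obj_at(Bgrid)
    i0 <- which.min(vals)
    best <- min(best, vals[i0])
    centers <- as.numeric(Bgrid[i0, ])
    half <- 3 * h
    h <- (2 * half) / 100
  }
  best
}

# Order-1 Wasserstein distance by the transportation LP (boot::simplex)
transport_lp_w1 <- function(P, Q) {
  a <- P$atoms; wa <- P$weights
  b <- Q$atoms; wb <- Q$weights
  n1 <- length(a); n2 <- length(b)
  cost <- as.vector(outer(a, b, function(u, v) abs(u - v)))  # column-major: pi[i,j]
  Arow <- matrix(0, n1, n1 * n2)
  for (i in seq_len(n1)) Arow[i, i + n1 * (seq_len(n2) - 1)] <- 1
  Acol <- matrix(0, n2, n1 * n2)
  for (j in seq_len(n2)) Acol[j, (j - 1) * n1 + seq_len(n1)] <- 1
  # the final column constraint is implied (masses both sum to 1): keep the
  # system full-rank for the simplex routine
  s <- boot::simplex(a = cost,
                     A3 = rbind(Arow, Acol[-n2, , drop = FALSE]),
                     b3 = c(wa, wb[-n2]),
                     maxi = FALSE, n.iter = 100 * n1 * n2)
  unname(s$value)
}

# Numerical dual norm: maximize theta'z over the primal-norm unit sphere by
# random directions plus a local polish of the scale-invariant ratio.
numeric_dual_norm <- function(kind, beta, M = NULL, n_dirs = 4000, seed = 42) {
  theta <- c(-beta, 1)
  m <- length(theta)
  pnorm_of <- function(z) switch(kind,
    l1 = sum(abs(z)), l2 = sqrt(sum(z^2)), linf = max(abs(z)),
    weighted = sqrt(drop(crossprod(z, M %*% z))))
  ratio <- function(z) { nz <- pnorm_of(z); if (nz == 0) -Inf else sum(theta * z) / nz }
  set.seed(seed)
  Z <- matrix(rnorm(n_dirs * m), n_dirs, m)
  vals <- apply(Z, 1, ratio)
  z0 <- Z[which.max(vals), ]
  o <- optim(z0, function(z) -ratio(z), method = "BFGS",
             control = list(maxit = 500, reltol = 1e-12))
  max(max(vals), -o$value)
}

# Strip the outlier-label column for fitting
drop_labels <- function(df) df[setdiff(names(df), "is_outlier")]
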