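# Smoothing-Newton solver for absolute-deviation regression with a smooth
# (conic) dual-norm penalty:
#
#   min_{beta, b0}  (1/N) sum_i sqrt(r_i^2 + mu^2) + eps * sqrt(beta'A beta - 2 b'beta + cc[mu])
#                   [+ nu * sum_j sqrt(beta_j^2 + mu^2)]
#
# with r = y - b0 - X beta. The first term is the standard hyperbolic
# smoothing of |r|; mu is driven to ~1e-10 * scale(y) by continuation, so the
# returned point is optimal for the nonsmooth objective to within O(mu).
# The penalty covers:
#   * l2-metric DRO:        A = I, b = 0, cc = 1            (smooth everywhere)
#   * M-weighted DRO:       A = W11, b = w12, cc = w22, W = M^-1
#   * l2-norm-penalised LAD: A = I, b = 0, cc = mu^2        (smoothed ||beta||_2)
# The optional nu-term is the smoothed l1 penalty used by the Lagrangian
# search that imposes an l1-ball constraint on the conic route.

smooth_lad_fit <- function(X, y, intercept = TRUE, eps = 0,
                           A = NULL, bvec = NULL, cc = 1, cc_smooth = FALSE,
                           nu = 0, beta0 = NULL, b0_init = NULL,
                           mu_min_factor = 1e-10, grad_tol = 1e-10) {
  X <- as.matrix(X); y <- as.numeric(y)
  N <- nrow(X); p <- ncol(X)
  if (eps > 0 && is.null(A)) { A <- diag(p); bvec <- rep(0, p) }
  if (eps > 0 && is.null(bvec)) bvec <- rep(0, p)

  scale_y <- max(1, sd(y), abs(mean(y)))
  mu0 <- scale_y
  mu_min <- mu_min_factor * scale_y
  mus <- 10^(seq(log10(mu0), log10(mu_min), by = -1))

  beta <- if (!is.null(beta0)) beta0 else rep(0, p)
  b0 <- if (!is.null(b0_init)) b0_init else if (intercept) median(y) else 0
  nit <- 0L

  objfun <- function(beta, b0, mu) {
    r <- y - drop(X %*% beta) - b0
    val <- mean(sqrt(r^2 + mu^2))
    if (eps > 0) {
      q <- drop(crossprod(beta, A %*% beta)) - 2 * sum(bvec * beta) +
        (if (cc_smooth) mu^2 else cc)
      val <- val + eps * sqrt(max(q, 0))
    }
    if (nu > 0) val <- val + nu * sum(sqrt(beta^2 + mu^2))
    val
  }

  for (mu in mus) {
    for (iter in seq_len(100L)) {
      nit <- nit + 1L
      r <- y - drop(X %*% beta) - b0
      w1 <- r / sqrt(r^2 + mu^2)             # d|r|/dr smoothed
      w2 <- mu^2 / (r^2 + mu^2)^1.5
      g_beta <- -drop(crossprod(X, w1)) / N
      H_bb <- crossprod(X, X * w2) / N
      if (intercept) {
        g_b0 <- -sum(w1) / N
        h_cross <- drop(crossprod(X, w2)) / N
        h_00 <- sum(w2) / N
      }
      if (eps > 0) {
        q <- drop(crossprod(beta, A %*% beta)) - 2 * sum(bvec * beta) +
          (if (cc_smooth) mu^2 else cc)
        phi <- sqrt(max(q, 1e-300))
        gq <- drop(A %*% beta) - bvec
        g_beta <- g_beta + eps * gq / phi
        H_bb <- H_bb + eps * (A / phi - tcrossprod(gq) / phi^3)
      }
      if (nu > 0) {
        sb <- sqrt(beta^2 + mu^2)
        g_beta <- g_beta + nu * beta / sb
        diag(H_bb) <- diag(H_bb) + nu * mu^2 / sb^3
      }

      if (intercept) {
        g <- c(g_beta, g_b0)
        H <- rbind(cbind(H_bb, h_cross), c(h_cross, h_00))
      } else {
        g <- g_beta; H <- H_bb
      }
      gnorm <- max(abs(g))
      tol_here <- grad_tol * (1 + 1 / scale_y) + 1e-13
      if (gnorm < max(tol_here, 1e-7 * mu / scale_y)) break

      tau <- 0
      repeat {
        ch <- tryCatch(chol(H + tau * diag(nrow(H))), error = function(e) NULL)
        if (!is.null(ch)) break
        tau <- if (tau == 0) 1e-12 * (1 + max(diag(H))) else tau * 100
      }
      dir <- -backsolve(ch, forwardsolve(t(ch), g))

      f0 <- objfun(beta, b0, mu)
      slope <- sum(g * dir)
      step <- 1; ok <- FALSE
      for (ls in 1:60) {
        bt <- beta + step * dir[seq_len(p)]
        b0t <- if (intercept) b0 + step * dir[p + 1L] else b0
        ft <- objfun(bt, b0t, mu)
        if (ft <= f0 + 1e-4 * step * slope) { ok <- TRUE; break }
        step <- step / 2
      }
      if (!ok) break
      beta <- bt; b0 <- b0t
      if (abs(f0 - ft) < 1e-16 * (1 + abs(f0)) && gnorm < 1e-6) break
    }
  }

  list(beta = beta, intercept = b0, iterations = nit,
       mu_final = mu_min, status = "optimal")
}
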