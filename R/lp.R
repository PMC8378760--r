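# Dense primal-dual interior-point solver for linear programs of the form
#
#   min c'x  s.t.  A x = b,  x_j >= 0 for j > nfree,  x_1..x_nfree free.
#
# Mehrotra predictor-corrector on the augmented (KKT) system, which keeps the
# regression coefficients as genuinely free variables instead of sign-splits
# (splitting them makes the normal equations catastrophically ill-conditioned
# once the split duals collapse). Sized for the absolute-deviation regression
# reformulations used here: a few hundred rows/columns, so a dense factor per
# iteration is cheap. Falls back to the simplex method (boot::simplex) on the
# rare numerical failure.

lp_solve <- function(A, b, c, nfree = 0L, tol = 1e-9, max_iter = 100L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(c) == n, nfree <= n)
  b <- as.numeric(b); c <- as.numeric(c)
  fr <- seq_len(nfree)
  po <- setdiff(seq_len(n), fr)
  np <- length(po)
  Fm <- A[, fr, drop = FALSE]; B <- A[, po, drop = FALSE]
  cf <- c[fr]; cx <- c[po]

  # starting point (least-squares heuristic)
  AAt <- tcrossprod(A)
  R0 <- chol(AAt + (1e-10 * (1 + max(diag(AAt)))) * diag(m))
  x_all <- drop(crossprod(A, backsolve(R0, forwardsolve(t(R0), b))))
  lam <- drop(backsolve(R0, forwardsolve(t(R0), A %*% c)))
  xf <- x_all[fr]
  x <- x_all[po]
  s <- cx - drop(crossprod(B, lam))
  dx <- max(-1.5 * min(x), 0); dsh <- max(-1.5 * min(s), 0)
  x <- x + dx + 0.1; s <- s + dsh + 0.1
  xs <- sum(x * s)
  x <- x + 0.5 * xs / sum(s)
  s <- s + 0.5 * xs / sum(x)

  bnorm <- 1 + max(abs(b)); cnorm <- 1 + max(abs(c))
  status <- "numerical_failure"
  stalls <- 0L; it <- 0L; reg <- NA_real_

  for (it in seq_len(max_iter)) {
    rp <- b - drop(Fm %*% xf) - drop(B %*% x)
    rdx <- cx - drop(crossprod(B, lam)) - s
    rdf <- if (nfree) cf - drop(crossprod(Fm, lam)) else numeric(0)
    mu <- sum(x * s) / np
    pobj <- sum(cx * x) + sum(cf * xf); dobj <- sum(b * lam)
    gap <- abs(pobj - dobj) / (1 + abs(pobj))
    if (max(abs(rp)) / bnorm < tol &&
        max(abs(rdx), if (nfree) abs(rdf) else 0) / cnorm < tol &&
        gap < tol) {
      status <- "optimal"
      break
    }
    if (!is.finite(mu) || mu <= 0 ||
        mu < 1e-14 * (1 + abs(pobj)) / np) break  # barrier exhausted, stalled

    d <- x / s
    M <- B %*% (d * t(B))
    # keep the regularization tiny relative to the CURRENT diagonal (diag(M)
    # diverges as the barrier vanishes); the refinement step below absorbs
    # the first-order bias, and the size is bumped only on rank deficiency
    if (is.na(reg)) reg <- 1e-11 * (1 + max(diag(M)))
    kq <- NULL
    for (reg_try in c(reg, 1e-13 * (1 + max(diag(M))), 1e-10 * (1 + max(diag(M))))) {
      K <- rbind(cbind(M + reg_try * diag(m), Fm),
                 if (nfree) cbind(t(Fm), -reg_try * diag(nfree)) else NULL)
      kq <- tryCatch(qr(K), error = function(e) NULL)
      if (!is.null(kq) && kq$rank == nrow(K)) break
      kq <- NULL
    }
    if (is.null(kq)) break
    kkt <- function(r1, r2) {
      rhs <- c(r1, r2)
      sol <- qr.coef(kq, rhs)
      sol <- sol + qr.coef(kq, rhs - drop(K %*% sol))  # one refinement step
      list(dlam = sol[seq_len(m)], dxf = if (nfree) sol[m + seq_len(nfree)] else numeric(0))
    }

    bad_dir <- function(...) any(!is.finite(unlist(list(...))))

    # predictor (affine-scaling): complementarity residual -x*s
    r1 <- rp + drop(B %*% (d * rdx + x))
    aff <- kkt(r1, rdf)
    ds_a <- rdx - drop(crossprod(B, aff$dlam))
    dx_a <- -x - d * ds_a
    if (bad_dir(ds_a, dx_a)) break
    ap <- step_len(x, dx_a); ad <- step_len(s, ds_a)
    mu_aff <- max(0, sum((x + ap * dx_a) * (s + ad * ds_a)) / np)
    sigma <- min(1, max(1e-8, (mu_aff / mu)^3))

    # corrector
    rxs <- sigma * mu - x * s - dx_a * ds_a
    r1 <- rp + drop(B %*% (d * rdx - rxs / s))
    cor <- kkt(r1, rdf)
    ds_ <- rdx - drop(crossprod(B, cor$dlam))
    dx <- rxs / s - d * ds_
    if (bad_dir(ds_, dx, cor$dxf)) break
    eta <- max(0.995, 1 - mu)
    ap <- min(1, eta * step_len(x, dx))
    ad <- min(1, eta * step_len(s, ds_))
    if (max(ap, ad) < 1e-4) stalls <- stalls + 1L else stalls <- 0L
    if (stalls >= 3L) break

    x <- x + ap * dx; s <- s + ad * ds_
    lam <- lam + ad * cor$dlam; xf <- xf + ap * cor$dxf
    if (min(x) <= 0 || min(s) <= 0) break
  }

  xout <- numeric(n); xout[fr] <- xf; xout[po] <- x
  list(x = xout, lambda = lam, status = status, iterations = it,
       objective = sum(c * xout))
}

step_len <- function(v, dv) {
  neg <- dv < 0
  if (!any(neg)) return(1)
  min(1, min(-v[neg] / dv[neg]))
}

# Simplex fallback (exact, slower): same LP with free variables sign-split.
lp_solve_simplex <- function(A, b, c, nfree = 0L) {
  fr <- seq_len(nfree)
  A2 <- if (nfree) cbind(A[, fr, drop = FALSE], -A[, fr, drop = FALSE],
                         A[, -fr, drop = FALSE]) else A
  c2 <- if (nfree) c(c[fr], -c[fr], c[-fr]) else c
  neg <- b < 0   # simplex() requires b3 >= 0
  A2[neg, ] <- -A2[neg, , drop = FALSE]
  s <- boot::simplex(a = c2, A3 = A2, b3 = abs(b), maxi = FALSE,
                     n.iter = 50 * (nrow(A2) + ncol(A2)))
  x2 <- s$soln
  x <- if (nfree) c(x2[fr] - x2[nfree + fr], x2[-seq_len(2 * nfree)]) else x2
  list(x = x, lambda = NULL,
       status = if (s$solved == 1) "optimal" else "numerical_failure",
       iterations = NA_integer_, objective = sum(c * x))
}

# LAD-family linear programs.
#
# min_{beta, b0} (1/N) sum |y - b0 - X beta| + pen(beta), with
#   pen = lambda_l1 * ||beta||_1      (l1-penalised LAD; the l-infinity-metric
#         DRO penalty eps*(||beta||_1 + 1) is this plus the constant eps)
#   pen = eps_a * max(||beta||_inf,1) (l1-metric DRO),
# optionally subject to ||beta||_1 <= l1_ball.
#
# Layout: free vars [beta (p), b0?]; nonneg vars [e+ (N), e- (N),
#   then for lambda_l1 > 0 or l1_ball: t_j >= |beta_j| (p),
#   then for eps_a: a, slacks u_j, v_j (2p), w,
#   then for l1_ball: ball slack].
lad_lp_fit <- function(X, y, intercept = TRUE, lambda_l1 = 0, eps_a = NULL,
                       l1_ball = NULL, tol = 1e-9) {
  X <- as.matrix(X); y <- as.numeric(y)
  N <- nrow(X); p <- ncol(X)
  nfree <- p + as.integer(intercept)
  need_t <- (lambda_l1 > 0) || !is.null(l1_ball)

  Afree <- cbind(X, if (intercept) rep(1, N) else NULL)
  A <- cbind(Afree, diag(N), -diag(N))
  b <- y
  cvec <- c(rep(0, nfree), rep(1 / N, 2 * N))

  add_cols <- function(A, k) cbind(A, matrix(0, nrow(A), k))
  add_rows <- function(A, k) rbind(A, matrix(0, k, ncol(A)))

  t_cols <- NULL
  if (need_t) {
    # t_j - beta_j >= 0 and t_j + beta_j >= 0 via slacks:
    # beta_j + t_j - u_j = 0 ; -beta_j + t_j - v_j = 0
    n0 <- ncol(A)
    A <- add_cols(A, 3 * p)
    t_cols <- n0 + seq_len(p)
    u_cols <- n0 + p + seq_len(p); v_cols <- n0 + 2 * p + seq_len(p)
    rows <- matrix(0, 2 * p, ncol(A))
    for (j in seq_len(p)) {
      rows[j, j] <- 1; rows[j, t_cols[j]] <- 1; rows[j, u_cols[j]] <- -1
      rows[p + j, j] <- -1; rows[p + j, t_cols[j]] <- 1; rows[p + j, v_cols[j]] <- -1
    }
    A <- rbind(A, rows)
    b <- c(b, rep(0, 2 * p))
    cvec <- c(cvec, rep(lambda_l1, p), rep(0, 2 * p))
  }

  if (!is.null(eps_a)) {
    # a >= |beta_j| (through a - beta_j - u_j = 0, a + beta_j - v_j = 0), a >= 1
    n0 <- ncol(A)
    A <- add_cols(A, 2 * p + 2)
    a_col <- n0 + 1L
    u2 <- n0 + 1L + seq_len(p); v2 <- n0 + 1L + p + seq_len(p)
    w_col <- n0 + 2L + 2L * p
    rows <- matrix(0, 2 * p + 1, ncol(A))
    for (j in seq_len(p)) {
      rows[j, j] <- -1; rows[j, a_col] <- 1; rows[j, u2[j]] <- -1
      rows[p + j, j] <- 1; rows[p + j, a_col] <- 1; rows[p + j, v2[j]] <- -1
    }
    rows[2 * p + 1, a_col] <- 1; rows[2 * p + 1, w_col] <- -1
    A <- rbind(A, rows)
    b <- c(b, rep(0, 2 * p), 1)
    cvec <- c(cvec, eps_a, rep(0, 2 * p + 1))
  }

  if (!is.null(l1_ball)) {
    n0 <- ncol(A)
    A <- add_cols(A, 1)
    row <- rep(0, ncol(A))
    row[t_cols] <- 1; row[n0 + 1L] <- 1
    A <- rbind(A, row)
    b <- c(b, l1_ball)
    cvec <- c(cvec, 0)
  }

  sol <- lp_solve(A, b, cvec, nfree = nfree, tol = tol)
  if (sol$status != "optimal") {
    sol <- lp_solve_simplex(A, b, cvec, nfree = nfree)
  }
  beta <- sol$x[seq_len(p)]
  b0 <- if (intercept) sol$x[p + 1L] else 0
  list(beta = beta, intercept = b0, status = sol$status,
       iterations = sol$iterations, lp_objective = sol$objective)
}
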