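# Independent brute-force oracles. These deliberately avoid the package's own
# code paths: direct normal equations, dense GLS via explicit inverses,
# full-dimensional likelihood optimization, literal BH step-up, eigen-clip
# nearest-PSD. They are the second route of every dual-route check.

# nearest-PSD by eigen clipping (no diagonal rescale; used where the package
# also skips it, plus a rescaled variant mirroring the correlation case)
oracle_psd_clip <- function(m, floor = 1e-8, rescale = TRUE) {
  e <- eigen(m, symmetric = TRUE)
  out <- e$vectors %*% diag(pmax(e$values, floor)) %*% t(e$vectors)
  if (rescale) {
    d <- sqrt(diag(out))
    out <- out / (d %o% d)
    diag(out) <- 1
  }
  (out + t(out)) / 2
}

# classical IVW: weighted regression through the origin, weights 1/byse^2
oracle_ivw_independent <- function(bx, by, byse) {
  w <- 1 / byse^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  list(theta = theta, se = 1 / sqrt(sum(w * bx^2)))
}

# GLS slope through the origin with dense explicit inverse
oracle_ivw_gls <- function(bx, by, byse, rho) {
  oi <- solve(diag(byse) %*% rho %*% diag(byse))
  theta <- solve(t(bx) %*% oi %*% bx, t(bx) %*% oi %*% by)[1]
  list(theta = theta, se = sqrt(solve(t(bx) %*% oi %*% bx)[1]))
}

# GLS with intercept (Egger) via explicit inverses
oracle_egger_gls <- function(bx, by, byse, rho) {
  oi <- solve(diag(byse) %*% rho %*% diag(byse))
  X <- cbind(1, bx)
  coef <- solve(t(X) %*% oi %*% X, t(X) %*% oi %*% by)
  covm <- solve(t(X) %*% oi %*% X)
  resid <- by - X %*% coef
  list(intercept = coef[1], slope = coef[2],
       se_slope = sqrt(covm[2, 2]), se_intercept = sqrt(covm[1, 1]),
       Q = as.numeric(t(resid) %*% oi %*% resid))
}

# full-dimensional joint likelihood maximization over (xi_1..xi_J, theta)
oracle_maxlik <- function(bx, bxse, by, byse, rho) {
  Sx <- diag(bxse) %*% rho %*% diag(bxse)
  Sy <- diag(byse) %*% rho %*% diag(byse)
  Sxi <- solve(Sx); Syi <- solve(Sy)
  J <- length(bx)
  nll <- function(par) {
    xi <- par[1:J]; theta <- par[J + 1]
    rx <- bx - xi; ry <- by - theta * xi
    0.5 * (t(rx) %*% Sxi %*% rx + t(ry) %*% Syi %*% ry)[1]
  }
  init <- c(bx, sum(bx * by / byse^2) / sum(bx^2 / byse^2))
  opt <- stats::optim(init, nll, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 2000))
  h <- stats::optimHess(opt$par, nll)
  list(theta = opt$par[J + 1], se = sqrt(solve(h)[J + 1, J + 1]))
}

# coordinate-ascent maximization of the same joint likelihood: exact block
# updates (xi given theta, theta given xi) iterated to a 1e-14 fixed point
oracle_maxlik_coord <- function(bx, bxse, by, byse, rho, tol = 1e-14,
                                maxit = 10000) {
  A <- solve(diag(bxse) %*% rho %*% diag(bxse))
  B <- solve(diag(byse) %*% rho %*% diag(byse))
  theta <- sum(bx * by / byse^2) / sum(bx^2 / byse^2)
  for (i in seq_len(maxit)) {
    xi <- solve(A + theta^2 * B, A %*% bx + theta * (B %*% by))
    theta_new <- (t(xi) %*% B %*% by / (t(xi) %*% B %*% xi))[1]
    if (abs(theta_new - theta) < tol) { theta <- theta_new; break }
    theta <- theta_new
  }
  list(theta = theta)
}

# literal BH step-up definition: adj p_(i) = min_{j >= i} min(1, n p_(j) / j)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- numeric(n)
  for (i in seq_len(n))
    adj_sorted[i] <- min(1, min(n * p[o][i:n] / (i:n)))
  adj <- numeric(n)
  adj[o] <- adj_sorted
  adj
}

# direct logistic likelihood maximization with optim (independent of IRLS)
oracle_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- X %*% b
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  h <- stats::optimHess(opt$par, nll)
  list(beta = opt$par, se = sqrt(diag(solve(h))))
}

# small instrument panels built in code
toy_panel <- function(J = 3, eaf = rep(0.3, J), beta = seq(0.06, by = 0.02,
                                                           length.out = J),
                      r2 = diag(1, J)) {
  new_panel(data.frame(
    rsid = paste0("rs", seq_len(J)), chrom = "1",
    pos = seq_len(J) * 1000L,
    effect_allele = rep("A", J), other_allele = rep("G", J),
    eaf = eaf, beta_sd = beta, se_sd = rep(0.01, J),
    locus = rep("TERC", J)), r2 = r2)
}

fixture_panel <- function() {
  load_panel(system.file("extdata", "panel_synthetic.tsv", package = "telomr"),
             system.file("extdata", "ld_r2_synthetic.tsv", package = "telomr"))
}

# simulate two-sample summary statistics from the MR model
sim_summaries <- function(J, theta, seed, bx_true = seq(0.05, 0.12,
                                                        length.out = J),
                          bxse = rep(0.01, J), byse = rep(0.02, J),
                          rho = diag(1, J), alpha = 0) {
  set.seed(seed)
  Lx <- chol(rho)
  bx <- bx_true + as.vector(t(Lx) %*% rnorm(J)) * bxse
  by <- alpha + theta * bx_true + as.vector(t(Lx) %*% rnorm(J)) * byse
  mr_input(bx, bxse, by, byse, rho = rho)
}
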