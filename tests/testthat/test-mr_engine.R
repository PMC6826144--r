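test_that("mr_input validates its contract", {
  expect_error(mr_input(c(0.1, 0.2), c(0.01, 0.01), c(0.1), c(0.01, 0.01)),
               class = "ValidationError")
  expect_error(mr_input(0.1, 0, 0.1, 0.01), class = "ValidationError")
  expect_error(mr_input(c(0.1, 0.2), c(0.01, 0.01), c(0.1, 0.2),
                        c(0.01, 0.01), rho = matrix(c(1, 0.2, 0.4, 1), 2)),
               class = "ValidationError")
})

test_that("single instrument reduces to the Wald ratio with delta-method SE", {
  inp <- mr_input(bx = 0.5, bxse = 0.05, by = 0.1, byse = 0.02)
  for (fit in list(mr_ivw(inp), mr_maxlik(inp))) {
    expect_equal(fit$theta, 0.2, tolerance = 1e-8)
    expect_equal(fit$se, sqrt(0.02^2 / 0.5^2 + 0.1^2 * 0.05^2 / 0.5^4),
                 tolerance = 1e-8)
  }
  expect_error(mr_egger(inp), class = "InsufficientData")
})

test_that("IVW equals brute-force oracles (independent and correlated)", {
  bx <- c(0.08, 0.11, 0.05)
  bxse <- c(0.01, 0.012, 0.009)
  by <- c(0.02, 0.025, 0.011)
  byse <- c(0.008, 0.01, 0.007)
  inp <- mr_input(bx, bxse, by, byse)
  orc <- oracle_ivw_independent(bx, by, byse)
  fit <- mr_ivw(inp, model = "fixed")
  expect_equal(fit$theta, orc$theta, tolerance = 1e-10)
  expect_equal(fit$se, orc$se, tolerance = 1e-10)

  rho <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.3, 0.2, 0.3, 1), 3)
  inp_c <- mr_input(bx, bxse, by, byse, rho = rho)
  orc_c <- oracle_ivw_gls(bx, by, byse, rho)
  fit_c <- mr_ivw(inp_c, model = "fixed")
  expect_equal(fit_c$theta, orc_c$theta, tolerance = 1e-10)
  expect_equal(fit_c$se, orc_c$se, tolerance = 1e-10)

  # random-effects SE never shrinks below the fixed-effect SE
  expect_gte(mr_ivw(inp_c)$se, fit_c$se)
})

test_that("maximum likelihood equals a full-dimensional optimization oracle", {
  set.seed(41)
  for (J in c(2, 4, 5)) {
    rho <- diag(1, J)
    if (J > 2) { rho[1, 2] <- rho[2, 1] <- 0.4 }
    inp <- sim_summaries(J, theta = 0.15, seed = 100 + J, rho = rho)
    fit <- mr_maxlik(inp)
    orc <- oracle_maxlik(inp$bx, inp$bxse, inp$by, inp$byse, rho)
    expect_equal(fit$theta, orc$theta, tolerance = 1e-6)
    expect_equal(fit$se, orc$se, tolerance = 1e-4)
  }
})

test_that("maxlik and IVW agree on homogeneous inputs (within one fixed SE)", {
  agree <- logical(100)
  for (i in 1:100) {
    inp <- sim_summaries(6, theta = log(1.2), seed = 200 + i)
    ml <- mr_maxlik(inp)
    ivw <- mr_ivw(inp, model = "fixed")
    agree[i] <- abs(ml$theta - ivw$theta) < ivw$se
  }
  expect_true(all(agree))
})

test_that("Egger recovers an exact line and equals the GLS oracle", {
  bx <- c(0.05, 0.08, 0.1, 0.13)
  by <- 0.05 + 0.2 * bx
  byse <- c(0.01, 0.012, 0.011, 0.009)
  inp <- mr_input(bx, rep(0.01, 4), by, byse)
  fit <- mr_egger(inp)
  expect_equal(fit$theta, 0.2, tolerance = 1e-10)
  expect_equal(fit$egger_intercept, 0.05, tolerance = 1e-10)
  expect_equal(fit$Q, 0, tolerance = 1e-10)

  rho <- matrix(0.3, 4, 4); diag(rho) <- 1
  inp_c <- sim_summaries(4, theta = 0.1, seed = 43, rho = rho, alpha = 0.02)
  fit_c <- mr_egger(inp_c, model = "fixed")
  orc <- oracle_egger_gls(inp_c$bx, inp_c$by, inp_c$byse, rho)
  expect_equal(fit_c$theta, orc$slope, tolerance = 1e-10)
  expect_equal(fit_c$egger_intercept, orc$intercept, tolerance = 1e-10)
  expect_equal(fit_c$se, orc$se_slope, tolerance = 1e-10)
  expect_equal(fit_c$Q, orc$Q, tolerance = 1e-10)
})

test_that("estimates are invariant to instrument permutation", {
  rho <- matrix(c(1, 0.4, 0.1, 0.4, 1, 0.25, 0.1, 0.25, 1), 3)
  inp <- sim_summaries(3, theta = 0.1, seed = 44, rho = rho)
  perm <- c(3, 1, 2)
  inp_p <- mr_input(inp$bx[perm], inp$bxse[perm], inp$by[perm],
                    inp$byse[perm], rho = rho[perm, perm])
  for (f in list(mr_ivw, mr_maxlik, mr_egger)) {
    a <- f(inp); b <- f(inp_p)
    expect_equal(a$theta, b$theta, tolerance = 1e-10)
    expect_equal(a$se, b$se, tolerance = 1e-8)
  }
})

test_that("scale equivariance: bx scaled by c rescales theta by 1/c", {
  inp <- sim_summaries(5, theta = 0.12, seed = 45)
  for (f in list(mr_ivw, mr_maxlik, mr_egger)) {
    a <- f(inp)
    b <- f(mr_input(3 * inp$bx, 3 * inp$bxse, inp$by, inp$byse))
    expect_equal(b$theta, a$theta / 3, tolerance = 1e-8)
  }
})

test_that("Q = 0 when by is an exact multiple of bx (fixed = random SE)", {
  bx <- c(0.06, 0.09, 0.12)
  inp <- mr_input(bx, rep(0.01, 3), 0.3 * bx, rep(0.01, 3))
  fix <- mr_ivw(inp, model = "fixed")
  ran <- mr_ivw(inp, model = "random")
  expect_equal(ran$Q, 0, tolerance = 1e-12)
  expect_equal(ran$se, fix$se, tolerance = 1e-12)
})

test_that("BH adjustment equals the literal step-up oracle", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  set.seed(46)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    expect_equal(fdr_bh(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(fdr_bh(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(fdr_bh(c(0.5, 1.2)), class = "ValidationError")
})

test_that("mr_finalize: rescaling, FDR family, power join", {
  results <- data.frame(
    outcome = rep(c("cancer", "chd"), each = 2),
    stratum = rep(c("60+/all", "all/all"), 2),
    method = "maxlik", kind = "binary", n = 261837,
    n_cases = c(44218, 44218, 28491, 28491),
    theta = c(log(1.2), log(1.2), log(0.88), log(0.88)),
    se = 0.02, p = c(0.001, 0.001, 0.04, 0.04),
    Q = NA, egger_intercept = NA, egger_p = NA)
  pow <- data.frame(outcome = c("cancer", "chd"), power = c(1, 0.98))
  fin <- mr_finalize(results, power = pow)
  expect_equal(fin$or_250bp, exp(fin$theta * 250 / 650))
  expect_equal(round(fin$or_250bp[1], 2), 1.07)
  # CI rescaled identically (deterministic transform of the per-SD CI)
  expect_equal(fin$ci_low_250bp, (fin$theta - 1.959964 * fin$se) * 250 / 650)
  # FDR only within the 60+ primary family
  expect_equal(is.na(fin$p_fdr), fin$stratum != "60+/all")
  expect_equal(fin$p_fdr[fin$stratum == "60+/all"], fdr_bh(c(0.001, 0.04)))
  expect_equal(fin$power, c(1, 1, 0.98, 0.98))

  # rescale then invert is the identity
  sc <- scaling_constants()
  down <- bp_rescale(0.37, 250, sc)
  expect_equal(bp_rescale(down, 650, scaling_constants(bp_per_sd = 250)),
               0.37, tolerance = 1e-12)
})

test_that("Egger intercept test is calibrated and detects pleiotropy", {
  # type-I under no pleiotropy: 500 summary-level replicates
  rho <- diag(1, 8); rho[1, 2] <- rho[2, 1] <- 0.4
  rej <- logical(500)
  for (i in 1:500) {
    inp <- sim_summaries(8, theta = log(1.2), seed = 3000 + i, rho = rho,
                         bx_true = seq(0.04, 0.12, length.out = 8))
    rej[i] <- mr_egger(inp)$egger_intercept_p < 0.05
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)

  # directional pleiotropy alpha = +0.02, theta = 0: intercept positive,
  # IVW biased, Egger slope still covers 0 in >= 90% of replicates
  nrep <- 200
  intercepts <- ivw_t <- numeric(nrep)
  covers <- logical(nrep)
  for (i in seq_len(nrep)) {
    inp <- sim_summaries(8, theta = 0, seed = 4000 + i, rho = rho,
                         bx_true = seq(0.04, 0.12, length.out = 8),
                         alpha = 0.02)
    eg <- mr_egger(inp)
    intercepts[i] <- eg$egger_intercept
    covers[i] <- eg$ci95[1] <= 0 && 0 <= eg$ci95[2]
    ivw_t[i] <- mr_ivw(inp)$theta
  }
  expect_gt(median(intercepts), 0)
  expect_gt(mean(ivw_t), 0.05)          # biased away from the true 0
  expect_gte(mean(covers), 0.90)
})

test_that("egger_scatter exports per-SNP points and the fitted line", {
  inp <- sim_summaries(5, theta = 0.1, seed = 47)
  eg <- mr_egger(inp)
  tmp <- tempfile(fileext = ".tsv")
  sc <- egger_scatter(inp, eg, path = tmp)
  expect_equal(nrow(sc), 5)
  expect_equal(sc$fitted, eg$egger_intercept + eg$theta * sc$bx)
  expect_true(file.exists(tmp))
})
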