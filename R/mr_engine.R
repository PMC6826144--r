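#' Assemble summary-statistic inputs for the MR estimators
#'
#' @param bx per-allele SNP-exposure effects (SD of telomere length).
#' @param bxse their standard errors (positive).
#' @param by per-allele SNP-outcome effects (log odds or SD of outcome).
#' @param byse their standard errors (positive).
#' @param rho J x J instrument correlation matrix (from `panel$r`);
#'   identity when omitted.
#' @param labels rsid labels.
#' @return an `mr_input` object.
#' @export
mr_input <- function(bx, bxse, by, byse, rho = NULL,
                     labels = paste0("snp", seq_along(bx))) {
  J <- length(bx)
  if (length(bxse) != J || length(by) != J || length(byse) != J ||
      length(labels) != J)
    abort("ValidationError", "mr_input vectors must have equal length")
  if (J == 0) abort("InsufficientData", "no instruments supplied")
  if (any(bxse <= 0) || any(byse <= 0))
    abort("ValidationError", "all standard errors must be positive")
  if (is.null(rho)) rho <- diag(1, J)
  rho <- as.matrix(rho)
  if (!all(dim(rho) == c(J, J)) || max(abs(rho - t(rho))) > 1e-8)
    abort("ValidationError", "rho must be a symmetric J x J matrix")
  rho <- psd_repair((rho + t(rho)) / 2)
  structure(list(bx = as.numeric(bx), bxse = as.numeric(bxse),
                 by = as.numeric(by), byse = as.numeric(byse),
                 rho = rho, labels = labels, J = J),
            class = "mr_input")
}

mr_result <- function(method, theta, se, J, Q = NA_real_,
                      egger_intercept = NA_real_, egger_intercept_se = NA_real_) {
  p <- 2 * stats::pnorm(-abs(theta / se))
  eg_p <- if (is.na(egger_intercept)) NA_real_ else
    2 * stats::pnorm(-abs(egger_intercept / egger_intercept_se))
  structure(list(method = method, theta = theta, se = se,
                 ci95 = c(theta - 1.959964 * se, theta + 1.959964 * se),
                 p = p, J = J, Q = Q,
                 egger_intercept = egger_intercept,
                 egger_intercept_se = egger_intercept_se,
                 egger_intercept_p = eg_p),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: theta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, J = %d\n",
              x$method, x$theta, x$se, x$ci95[1], x$ci95[2], x$p, x$J))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  Egger intercept %.4f (SE %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  invisible(x)
}

# GLS weight matrix for correlated instruments and its solve.
omega_solve <- function(byse, rho, B) {
  omega <- tcrossprod(byse) * rho
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) {
    omega <- tcrossprod(byse) * psd_repair(rho, floor = 1e-6)
    ch <- tryCatch(chol(omega + diag(1e-12 * mean(byse^2), length(byse))),
                   error = function(e)
                     abort("SingularWeightMatrix",
                           "outcome covariance is singular even after PSD repair"))
  }
  backsolve(ch, forwardsolve(t(ch), B))
}

#' Inverse-variance weighted estimate with correlated instruments
#'
#' Generalized-least-squares regression of the SNP-outcome effects on the
#' SNP-exposure effects through the origin, with weight matrix
#' `Omega_ij = byse_i byse_j rho_ij`. With `rho = I` this is the classical
#' IVW estimator. Under the random-effects model the standard error is
#' multiplied by `max(1, sqrt(Q / (J - 1)))` where `Q` is the GLS residual
#' sum of squares. A single instrument reduces to the Wald ratio with a
#' delta-method standard error.
#'
#' @param input an [mr_input()].
#' @param model `"random"` (default) or `"fixed"`.
#' @return an `mr_result` (causal effect per SD of telomere length).
#' @export
mr_ivw <- function(input, model = c("random", "fixed")) {
  model <- match.arg(model)
  J <- input$J
  if (J == 1) {
    theta <- input$by / input$bx
    se <- sqrt(input$byse^2 / input$bx^2 +
               input$by^2 * input$bxse^2 / input$bx^4)
    return(mr_result("ivw", theta, se, J, Q = 0))
  }
  oib <- omega_solve(input$byse, input$rho, cbind(input$bx, input$by))
  xox <- sum(input$bx * oib[, 1])
  theta <- sum(input$bx * oib[, 2]) / xox
  se <- sqrt(1 / xox)
  resid <- input$by - theta * input$bx
  Q <- sum(resid * omega_solve(input$byse, input$rho, resid))
  if (model == "random") se <- se * max(1, sqrt(Q / (J - 1)))
  mr_result("ivw", theta, se, J, Q = Q)
}

# Profile log-likelihood machinery for the likelihood-based estimator.
# Model: bx_j ~ N(xi_j, Sigma_x), by_j ~ N(theta * xi_j, Sigma_y), blocks
# correlated within via rho, cross-block correlation `overlap` (0 for
# non-overlapping exposure/outcome samples).
maxlik_profile <- function(input, overlap = 0) {
  A <- solve(tcrossprod(input$bxse) * input$rho)
  B <- solve(tcrossprod(input$byse) * input$rho)
  if (overlap != 0)
    warn("nonzero exposure-outcome overlap correlation is not supported; using 0")
  list(
    xi_hat = function(theta)
      solve(A + theta^2 * B, A %*% input$bx + theta * (B %*% input$by)),
    negll = function(theta, xi) {
      rx <- input$bx - xi
      ry <- input$by - theta * xi
      0.5 * (sum(rx * (A %*% rx)) + sum(ry * (B %*% ry)))
    },
    A = A, B = B)
}

#' Likelihood-based estimate with correlated instruments
#'
#' Maximizes the joint normal likelihood of the observed SNP-exposure and
#' SNP-outcome effects over the latent per-SNP exposure effects and the
#' causal slope, with within-block covariance built from the SEs and the
#' instrument correlation matrix and zero cross-block covariance (two-sample
#' setting). The slope is profiled (the latent effects solve a linear system
#' given the slope), initialized at the IVW solution, converged to 1e-10 on
#' the log-likelihood; the standard error comes from the full observed
#' information at the optimum.
#'
#' @param input an [mr_input()].
#' @param overlap exposure-outcome sample overlap correlation (0 by default).
#' @return an `mr_result`.
#' @export
mr_maxlik <- function(input, overlap = 0) {
  J <- input$J
  if (J == 1) {
    theta <- input$by / input$bx
    se <- sqrt(input$byse^2 / input$bx^2 +
               input$by^2 * input$bxse^2 / input$bx^4)
    return(mr_result("maxlik", theta, se, J, Q = 0))
  }
  prof <- maxlik_profile(input, overlap)
  f <- function(theta) prof$negll(theta, prof$xi_hat(theta))
  init <- mr_ivw(input, model = "fixed")$theta
  opt <- stats::optim(init, f, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  if (opt$convergence != 0)
    abort("ConvergenceFailure", "likelihood optimization did not converge")
  theta <- opt$par
  # fixed-point polish: exact alternating score updates sharpen theta well
  # past gradient-solver precision (the score equations are closed-form)
  B <- prof$B
  for (it in 1:200) {
    xi <- as.vector(prof$xi_hat(theta))
    theta_new <- sum(xi * (B %*% input$by)) / sum(xi * (B %*% xi))
    if (abs(theta_new - theta) < 1e-13) { theta <- theta_new; break }
    theta <- theta_new
  }
  xi <- as.vector(prof$xi_hat(theta))
  # observed information of (xi, theta) at the optimum (analytic blocks)
  A <- prof$A; B <- prof$B
  ry <- input$by - theta * xi
  I_xx <- A + theta^2 * B
  I_xt <- theta * (B %*% xi) - B %*% ry
  I_tt <- sum(xi * (B %*% xi))
  info <- rbind(cbind(I_xx, I_xt), c(I_xt, I_tt))
  cov <- tryCatch(solve(info), error = function(e)
    abort("ConvergenceFailure", "singular information matrix"))
  mr_result("maxlik", theta, sqrt(cov[J + 1, J + 1]), J)
}

#' MR-Egger regression with correlated instruments
#'
#' Generalized-least-squares regression of the SNP-outcome on the
#' SNP-exposure effects WITH a free intercept, instruments oriented to the
#' telomere-lengthening allele. The slope is a pleiotropy-robust causal
#' estimate; the intercept estimates average directional pleiotropy and is
#' tested against zero (normal test). Random-effects SE inflation uses
#' `max(1, sqrt(Q / (J - 2)))`.
#'
#' @param input an [mr_input()] with at least three instruments.
#' @param model `"random"` (default) or `"fixed"`.
#' @return an `mr_result` with `egger_intercept` fields.
#' @export
mr_egger <- function(input, model = c("random", "fixed")) {
  model <- match.arg(model)
  J <- input$J
  if (J < 3)
    abort("InsufficientData", "MR-Egger requires at least 3 instruments, got %d", J)
  X <- cbind(1, input$bx)
  oX <- omega_solve(input$byse, input$rho, cbind(X, input$by))
  XtOX <- crossprod(X, oX[, 1:2])
  XtOy <- crossprod(X, oX[, 3])
  coef <- solve(XtOX, XtOy)
  resid <- input$by - as.vector(X %*% coef)
  Q <- sum(resid * omega_solve(input$byse, input$rho, resid))
  cov <- solve(XtOX)
  infl <- if (model == "random") max(1, sqrt(Q / (J - 2))) else 1
  mr_result("egger", theta = coef[2], se = sqrt(cov[2, 2]) * infl, J = J,
            Q = Q, egger_intercept = coef[1],
            egger_intercept_se = sqrt(cov[1, 1]) * infl)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
fdr_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    abort("ValidationError", "p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj
}

#' Finalize MR results into a report table
#'
#' Attaches per-250-bp (and optional per-100-bp) rescaled estimates with
#' identically rescaled confidence intervals, FDR-adjusted p-values computed
#' within the stated analysis family (one p per outcome), and power columns
#' with the <80% low-power flag.
#'
#' @param results data.frame with one row per outcome/stratum/method and
#'   columns `outcome`, `stratum`, `method`, `kind` ("binary"/"continuous"),
#'   `theta`, `se`, `p`, `Q`, `egger_intercept`, `egger_p` (NA where absent).
#' @param scaling a [scaling_constants()] object.
#' @param power optional data.frame with columns `outcome`, `power`.
#' @param fdr_method method whose p-values define the FDR family
#'   (default `"maxlik"`, the headline estimator).
#' @param fdr_stratum stratum defining the FDR family (default `"60+/all"`).
#' @param target_bp increments to report (default 250 bp).
#' @return the augmented results data.frame.
#' @export
mr_finalize <- function(results, scaling = scaling_constants(), power = NULL,
                        fdr_method = "maxlik", fdr_stratum = "60+/all",
                        target_bp = 250) {
  f <- target_bp / scaling$bp_per_sd
  results$theta_250bp <- results$theta * f
  results$ci_low_250bp <- (results$theta - 1.959964 * results$se) * f
  results$ci_high_250bp <- (results$theta + 1.959964 * results$se) * f
  is_bin <- results$kind == "binary"
  results$or_250bp <- ifelse(is_bin, exp(results$theta_250bp), NA_real_)
  results$or_ci_low_250bp <- ifelse(is_bin, exp(results$ci_low_250bp), NA_real_)
  results$or_ci_high_250bp <- ifelse(is_bin, exp(results$ci_high_250bp), NA_real_)
  results$p_fdr <- NA_real_
  fam <- which(results$method == fdr_method & results$stratum == fdr_stratum)
  if (length(fam) > 0) results$p_fdr[fam] <- fdr_bh(results$p[fam])
  if (!is.null(power)) {
    i <- match(results$outcome, power$outcome)
    results$power <- power$power[i]
    results$low_power <- flag_low_power(results$power)
  }
  results
}

#' Per-SNP scatter export for MR-Egger plots
#'
#' @param input an [mr_input()].
#' @param egger an `mr_result` from [mr_egger()].
#' @param path optional tab-separated output path.
#' @return data.frame with per-SNP `bx`, `by`, SEs and the fitted line.
#' @export
egger_scatter <- function(input, egger = mr_egger(input), path = NULL) {
  out <- data.frame(rsid = input$labels, bx = input$bx, bxse = input$bxse,
                    by = input$by, byse = input$byse,
                    fitted = egger$egger_intercept + egger$theta * input$bx)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
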