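# Per-SNP association scan: the SNP-outcome inputs to the MR estimators.
# Linear fits are closed-form least squares on the design [1, g, covariates];
# logistic fits are plain maximum likelihood via IRLS with SEs from the
# observed information. Both avoid model-formula overhead so a 200-replicate
# full-chain simulation stays inside a test budget.

assoc_result <- function(rsid, outcome, beta, se, n, n_cases = NA_integer_,
                         converged = TRUE) {
  data.frame(rsid = rsid, outcome = outcome, beta = beta, se = se,
             n = as.integer(n), n_cases = as.integer(n_cases),
             converged = converged, stringsAsFactors = FALSE)
}

# Build the covariate design matrix (intercept + numeric/dummy-coded columns).
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  covariates <- as.data.frame(covariates)
  stats::model.matrix(~ ., data = covariates)
}

#' Linear per-SNP association
#'
#' Ordinary least squares of a standardized continuous outcome on a genotype
#' dosage with covariate adjustment; classical (model-based) standard error.
#' Rows with any missing value are dropped listwise.
#'
#' @param y continuous outcome (z-scored upstream).
#' @param g dosage vector (0-2 copies of the telomere-lengthening allele).
#' @param covariates optional data.frame of covariates (age, sex, centre,
#'   array, principal components).
#' @param rsid,outcome labels carried into the result.
#' @return one-row `assoc_result` data.frame with `beta`, `se`, `n`.
#' @export
linear_assoc <- function(y, g, covariates = NULL, rsid = "snp", outcome = "y") {
  keep <- !is.na(y) & !is.na(g)
  if (!is.null(covariates))
    keep <- keep & stats::complete.cases(as.data.frame(covariates))
  y <- y[keep]; g <- g[keep]
  n <- length(y)
  X <- cbind(covariate_design(
    if (is.null(covariates)) NULL else as.data.frame(covariates)[keep, , drop = FALSE],
    n), g = g)
  p <- ncol(X)
  if (n <= p) abort("InsufficientData", "n = %d <= p = %d", n, p)
  if (stats::sd(g) == 0)
    abort("DegenerateGenotype", "constant dosage for %s", rsid)
  qx <- qr(X)
  coef <- qr.coef(qx, y)
  res <- y - X %*% coef
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  XtXinv_gg <- chol2inv(qr.R(qx))[p, p]
  assoc_result(rsid, outcome, beta = unname(coef[p]),
               se = sqrt(sigma2 * XtXinv_gg), n = n)
}

# IRLS logistic maximum likelihood. Tolerance 1e-8 on the log-likelihood,
# at most `maxit` iterations; perfect separation is flagged non-converged.
logistic_irls <- function(X, y, tol = 1e-8, maxit = 50) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(mean(y))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-12)) w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    fit <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(fit)) break
    beta <- as.vector(fit)
    ll <- sum(y * eta - log1p(exp(eta)))
    # guard the log1p(exp()) overflow path
    if (!is.finite(ll)) ll <- sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                                         stats::plogis(-eta, log.p = TRUE)))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  sep <- all(abs(mu - y) < 1e-8) || max(abs(beta)) > 30
  info <- t(X * (mu * (1 - mu))) %*% X
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, se = sqrt(diag(cov)), converged = converged && !sep)
}

#' Logistic per-SNP association
#'
#' Maximum-likelihood logistic regression of a case/control outcome on a
#' genotype dosage with covariate adjustment (IRLS, tolerance 1e-8 on the
#' log-likelihood, at most 50 iterations). Standard errors come from the
#' observed information. Excluded codes (`NA`) are dropped; perfect
#' separation is flagged `converged = FALSE`.
#'
#' @inheritParams linear_assoc
#' @param y 0/1/NA coded outcome.
#' @return one-row `assoc_result` data.frame (log odds ratio per allele).
#' @export
logistic_assoc <- function(y, g, covariates = NULL, rsid = "snp", outcome = "y") {
  keep <- !is.na(y) & !is.na(g)
  if (!is.null(covariates))
    keep <- keep & stats::complete.cases(as.data.frame(covariates))
  y <- y[keep]; g <- g[keep]
  n <- length(y)
  if (length(unique(y)) < 2)
    abort("InsufficientData", "outcome '%s' has a single class", outcome)
  if (stats::sd(g) == 0)
    abort("DegenerateGenotype", "constant dosage for %s", rsid)
  X <- cbind(covariate_design(
    if (is.null(covariates)) NULL else as.data.frame(covariates)[keep, , drop = FALSE],
    n), g = g)
  if (n <= ncol(X)) abort("InsufficientData", "n = %d <= p = %d", n, ncol(X))
  fit <- logistic_irls(X, y)
  p <- ncol(X)
  assoc_result(rsid, outcome, beta = fit$beta[p], se = fit$se[p], n = n,
               n_cases = sum(y == 1), converged = fit$converged)
}

#' Association scan over a panel, outcomes and strata
#'
#' Runs [linear_assoc()] or [logistic_assoc()] for every instrument against
#' every registered outcome inside an age/sex stratum, adjusting for age, sex,
#' assessment centre, array type and five principal components (sex is
#' dropped from the design inside single-sex strata or sex-specific
#' outcomes). Continuous outcomes are z-scored within the stratum analysis
#' sample before fitting.
#'
#' @param panel an `snp_panel`.
#' @param cohort a `cohort_table`.
#' @param outcomes named list of `derived_outcome`s (or a registry data.frame
#'   with columns `name`, `kind`, `sex` in `all`/`male`/`female` naming
#'   columns of `cohort`).
#' @param age_stratum one of `"all"`, `"40-60"`, `"60+"`.
#' @param sex_stratum one of `"all"`, `"male"`, `"female"`.
#' @param registry optional data.frame with columns `name` and `sex`
#'   restricting outcomes to one sex (e.g. breast cancer, women only);
#'   mismatching strata are skipped with a message.
#' @return data.frame of `assoc_result` rows with `stratum` attached.
#' @export
assoc_scan <- function(panel, cohort, outcomes, age_stratum = "all",
                       sex_stratum = "all", registry = NULL) {
  stopifnot(age_stratum %in% c("all", "40-60", "60+"),
            sex_stratum %in% c("all", "male", "female"))
  sel <- rep(TRUE, nrow(cohort))
  if (age_stratum == "40-60") sel <- sel & cohort$age >= 40 & cohort$age < 60
  if (age_stratum == "60+") sel <- sel & cohort$age >= 60
  if (sex_stratum == "male") sel <- sel & cohort$sex == "M"
  if (sex_stratum == "female") sel <- sel & cohort$sex == "F"
  if (!any(sel)) abort("InsufficientData", "empty stratum %s/%s",
                       age_stratum, sex_stratum)
  stratum_label <- paste(age_stratum, sex_stratum, sep = "/")
  covar_cols <- c("age", "sex", "centre", "array", paste0("pc", 1:5))
  res <- list()
  for (nm in names(outcomes)) {
    oc <- outcomes[[nm]]
    oc_sex <- if (!is.null(registry) && nm %in% registry$name)
      registry$sex[match(nm, registry$name)] else "all"
    if (oc_sex != "all" && sex_stratum != "all" && oc_sex != sex_stratum) {
      message(sprintf("assoc_scan: skipping %s in %s stratum (%s-only outcome)",
                      nm, sex_stratum, oc_sex))
      next
    }
    sel_o <- sel
    if (oc_sex == "male") sel_o <- sel_o & cohort$sex == "M"
    if (oc_sex == "female") sel_o <- sel_o & cohort$sex == "F"
    y <- oc$values[sel_o]
    covs <- cohort[sel_o, covar_cols]
    # drop factors that are constant within the stratum (e.g. sex in a
    # single-sex stratum) so the design stays full rank
    keepc <- vapply(covs, function(v) length(unique(v[!is.na(v)])) > 1, TRUE)
    covs <- covs[, keepc, drop = FALSE]
    if (oc$kind == "continuous") {
      ok <- !is.na(y)
      if (sum(ok) > 2 && stats::sd(y[ok]) > 0) y[ok] <- zscore(y[ok])
    }
    for (j in seq_len(nrow(panel$snps))) {
      rsid <- panel$snps$rsid[j]
      g <- cohort[[rsid]][sel_o]
      r <- if (oc$kind == "binary")
        logistic_assoc(y, g, covs, rsid = rsid, outcome = nm)
      else
        linear_assoc(y, g, covs, rsid = rsid, outcome = nm)
      res[[length(res) + 1]] <- r
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) abort("InsufficientData", "no outcome analyzable in stratum")
  out$stratum <- stratum_label
  out
}

#' Write an association scan as a GWAS-summary-style table
#'
#' @param assoc data.frame from [assoc_scan()].
#' @param panel the `snp_panel` supplying allele columns.
#' @param path output path (tab-separated).
#' @export
write_assoc <- function(assoc, panel, path) {
  i <- match(assoc$rsid, panel$snps$rsid)
  out <- data.frame(rsid = assoc$rsid,
                    effect_allele = panel$snps$effect_allele[i],
                    other_allele = panel$snps$other_allele[i],
                    beta = assoc$beta, se = assoc$se, n = assoc$n,
                    n_cases = assoc$n_cases, outcome = assoc$outcome,
                    stratum = assoc$stratum)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
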