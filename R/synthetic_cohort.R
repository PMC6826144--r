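#' Specification for a synthetic biobank-style cohort
#'
#' Describes the stated world the simulator emulates: an instrument panel with
#' LD-structured genotype dosages under Hardy-Weinberg equilibrium, a latent
#' telomere-length exposure with a fixed fraction of variance explained by the
#' panel (2.23% by default), binary outcomes with calibrated marginal
#' prevalence and a causal log odds ratio per SD of telomere length,
#' continuous outcomes with an SD-per-SD causal effect, optional per-SNP
#' direct (pleiotropic) effects, and an optional shared confounder.
#'
#' @param n cohort size (>= 2).
#' @param seed master seed; per-stage streams are derived by fixed offsets.
#' @param panel an `snp_panel`.
#' @param target_r2 variance of telomere length explained by the panel.
#' @param causal_effects named list, outcome name -> causal effect of one SD
#'   of telomere length (log odds ratio for binary, SD change for continuous).
#' @param prevalences named list, binary outcome name -> marginal prevalence.
#' @param pleiotropy named list, outcome name -> length-J vector of per-allele
#'   direct effects bypassing telomere length (default all zero).
#' @param confounder_strength loading of a standard-normal confounder on both
#'   the exposure and every outcome (default 0, i.e. valid instruments).
#' @return a `simulation_spec` object.
#' @export
simulation_spec <- function(n, seed, panel, target_r2 = 0.0223,
                            causal_effects = list(), prevalences = list(),
                            pleiotropy = list(), confounder_strength = 0) {
  if (n < 2) abort("ValidationError", "n must be at least 2")
  if (target_r2 < 0 || target_r2 >= 1)
    abort("ValidationError", "target_r2 must lie in [0, 1)")
  for (nm in names(prevalences)) {
    k <- prevalences[[nm]]
    if (k <= 0 || k >= 1)
      abort("ValidationError", "prevalence for '%s' must lie in (0, 1)", nm)
  }
  binary <- names(prevalences)
  structure(list(n = as.integer(n), seed = as.integer(seed), panel = panel,
                 target_r2 = target_r2, causal_effects = causal_effects,
                 prevalences = prevalences, pleiotropy = pleiotropy,
                 confounder_strength = confounder_strength, binary = binary),
            class = "simulation_spec")
}

# P(Z1 < a, Z2 < b) for a standard bivariate normal with correlation rho,
# by one-dimensional quadrature (no external bivariate-CDF dependency).
bvn_cdf <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(z) stats::dnorm(z) * stats::pnorm((b - rho * z) / s),
                   -8, a, rel.tol = 1e-10)$value
}

# Latent normal correlation whose thresholded indicators have phi
# (product-moment) correlation `target` at allele frequencies p1, p2.
# Thresholding attenuates correlation, so the latent value is inflated by
# root-finding; unattainable targets are capped with a warning.
latent_correlation <- function(target, p1, p2) {
  if (target <= 0) return(0)
  a <- stats::qnorm(p1); b <- stats::qnorm(p2)
  denom <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  phi <- function(l) (bvn_cdf(a, b, l) - p1 * p2) / denom - target
  if (phi(0.99999) < 0) {
    warn("dosage correlation %.3f unattainable at eaf %.2f/%.2f; capped", target, p1, p2)
    return(0.99999)
  }
  stats::uniroot(phi, c(max(target - 0.05, 0), 0.99999), tol = 1e-9)$root
}

#' Simulate genotype dosages with the panel's allele frequencies and LD
#'
#' Gaussian-copula haplotype model: two independent latent multivariate-normal
#' draws are thresholded at the normal quantile of each effect-allele
#' frequency and summed, giving dosages in {0, 1, 2} that satisfy
#' Hardy-Weinberg per SNP. Latent correlations are calibrated by root-finding
#' on the bivariate-normal orthant probability so the realized pairwise
#' dosage correlations match `panel$r` in expectation (plain thresholding
#' would attenuate them).
#'
#' @param spec a [simulation_spec()].
#' @return an n x J matrix of dosages, columns named by rsid.
#' @export
simulate_genotypes <- function(spec) {
  panel <- spec$panel
  J <- nrow(panel$snps)
  set.seed(stage_seed(spec$seed, "genotypes"))
  p <- panel$snps$eaf
  lat <- diag(1, J)
  for (i in seq_len(J)) for (j in seq_len(J)) {
    if (j <= i) next
    lat[i, j] <- lat[j, i] <- latent_correlation(panel$r[i, j], p[i], p[j])
  }
  lat <- psd_repair(lat, quiet = TRUE)
  L <- chol(lat + diag(1e-10, J))
  thr <- stats::qnorm(p)
  hap <- function() {
    z <- matrix(stats::rnorm(spec$n * J), spec$n, J) %*% L
    sweep(z, 2, thr, "<") * 1
  }
  g <- hap() + hap()
  colnames(g) <- panel$snps$rsid
  g
}

# Population variance of the raw allele score sum(beta_j * g_j) under the
# copula model, using HWE variances 2p(1-p) and dosage correlation ~ r.
score_variance <- function(panel) {
  p <- panel$snps$eaf
  b <- panel$snps$beta_sd
  sdg <- sqrt(2 * p * (1 - p))
  sum((b * sdg) %o% (b * sdg) * panel$r)
}

#' Simulate the latent telomere-length exposure
#'
#' Telomere length (SD units) is the centered allele score scaled so its
#' population variance equals `target_r2`, plus independent Gaussian noise of
#' variance `1 - target_r2`, giving unit total variance and panel variance
#' explained equal to the target (2.23% by default).
#'
#' @param dosages matrix from [simulate_genotypes()].
#' @param spec a [simulation_spec()].
#' @return numeric vector of telomere length in SD units.
#' @export
simulate_telomere <- function(dosages, spec) {
  panel <- spec$panel
  b <- panel$snps$beta_sd
  raw <- as.vector(dosages %*% b) - sum(b * 2 * panel$snps$eaf)
  v <- score_variance(panel)
  if (v <= 0) abort("ValidationError",
                    "panel allele score has zero variance; target_r2 unreachable")
  set.seed(stage_seed(spec$seed, "telomere"))
  raw * sqrt(spec$target_r2 / v) +
    stats::rnorm(spec$n, 0, sqrt(1 - spec$target_r2))
}

# Solve the logistic intercept so that mean(plogis(a + eta)) == K, by
# root-finding to 1e-6 on the expected prevalence.
calibrate_intercept <- function(eta, K) {
  f <- function(a) mean(stats::plogis(a + eta)) - K
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    abort("ValidationError", "prevalence %g unreachable for this linear predictor", K)
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Simulate outcome fields under the assumed causal model
#'
#' Binary outcomes are Bernoulli with logistic mean
#' `plogis(a + theta * telomere + sum(alpha_j * dosage_j) + c * confounder)`,
#' the intercept `a` solved numerically so the marginal prevalence matches the
#' spec (tolerance 1e-6 on the expectation). Continuous outcomes are the same
#' linear predictor plus Gaussian noise topping total variance up to 1.
#'
#' @param cohort data.frame containing `telomere_sd`, dosage columns and
#'   (when `confounder_strength != 0`) `confounder`.
#' @param spec a [simulation_spec()].
#' @return `cohort` with one column per outcome appended.
#' @export
simulate_outcomes <- function(cohort, spec) {
  set.seed(stage_seed(spec$seed, "outcomes"))
  rsids <- spec$panel$snps$rsid
  G <- as.matrix(cohort[, rsids, drop = FALSE])
  conf <- if (!is.null(cohort$confounder)) cohort$confounder else 0
  for (nm in names(spec$causal_effects)) {
    theta <- spec$causal_effects[[nm]]
    alpha <- spec$pleiotropy[[nm]]
    direct <- if (is.null(alpha)) 0 else as.vector(G %*% alpha)
    eta <- theta * cohort$telomere_sd + direct + spec$confounder_strength * conf
    if (nm %in% spec$binary) {
      a <- calibrate_intercept(eta, spec$prevalences[[nm]])
      cohort[[nm]] <- stats::rbinom(spec$n, 1, stats::plogis(a + eta))
    } else {
      ve <- stats::var(eta)
      noise_sd <- if (ve < 1) sqrt(1 - ve) else 0
      cohort[[nm]] <- eta + stats::rnorm(spec$n, 0, noise_sd)
    }
  }
  cohort
}

#' Simulate parental attained ages and death status
#'
#' Ages at death are drawn from normal distributions matching the biobank
#' summary (father 72.22 +/- 11.05, mother 77.37 +/- 9.83 years), truncated at
#' 20, with an optional left mixture component of premature deaths for
#' exercising the early-death cutoff. A `survivorship` fraction of parents is
#' instead still alive, with attained age drawn uniformly between 60 and their
#' (unobserved) age at death.
#'
#' @param n number of participants.
#' @param seed integer seed.
#' @param father_mean,father_sd,mother_mean,mother_sd normal parameters.
#' @param survivorship fraction of parents still alive (0 = all dead).
#' @param premature_frac,premature_mean,premature_sd optional early-death
#'   mixture component (fraction 0 disables it).
#' @return data.frame with `father_age`, `mother_age`, `father_dead`,
#'   `mother_dead`.
#' @export
simulate_parental_ages <- function(n, seed, father_mean = 72.22,
                                   father_sd = 11.05, mother_mean = 77.37,
                                   mother_sd = 9.83, survivorship = 0.25,
                                   premature_frac = 0, premature_mean = 45,
                                   premature_sd = 5) {
  set.seed(stage_seed(seed, "parental"))
  draw <- function(mu, sd) {
    x <- stats::rnorm(n, mu, sd)
    prem <- stats::runif(n) < premature_frac
    x[prem] <- stats::rnorm(sum(prem), premature_mean, premature_sd)
    pmax(x, 20)
  }
  fa <- draw(father_mean, father_sd)
  mo <- draw(mother_mean, mother_sd)
  f_dead <- stats::runif(n) >= survivorship
  m_dead <- stats::runif(n) >= survivorship
  # attained age of living parents: somewhere short of their would-be lifespan
  fa[!f_dead] <- pmax(60, fa[!f_dead] - stats::runif(sum(!f_dead), 0, 15))
  mo[!m_dead] <- pmax(60, mo[!m_dead] - stats::runif(sum(!m_dead), 0, 15))
  data.frame(father_age = fa, mother_age = mo,
             father_dead = f_dead, mother_dead = m_dead)
}

#' Simulate a complete cohort table
#'
#' Assembles genotypes, the latent exposure, designed outcomes, covariates
#' (age 40-70, sex, 10 assessment centres, two array types, five genetic
#' principal components), parental fields, and raw phenotype fields for the
#' derivation module: 49 frailty deficit items (age-dependent Bernoulli rates
#' so the expected deficit count is ~6.3 at 60+ and ~1.7 below 60), sex-
#' specific grip strength and skeletal muscle mass index, log-normal reaction
#' time, Poisson visual memory errors, Fried frailty components and the
#' categorical survey fields (depression, pains, falls).
#'
#' @param spec a [simulation_spec()].
#' @param confounded if `TRUE` a standard-normal confounder is added to the
#'   exposure before outcomes are generated.
#' @return a `cohort_table` (data.frame).
#' @export
simulate_cohort <- function(spec, confounded = spec$confounder_strength != 0) {
  n <- spec$n
  g <- simulate_genotypes(spec)
  set.seed(stage_seed(spec$seed, "covariates"))
  cohort <- data.frame(
    id = seq_len(n),
    age = stats::runif(n, 40, 70),
    sex = sample(c("M", "F"), n, replace = TRUE),
    centre = factor(sample(paste0("c", 1:10), n, replace = TRUE)),
    array = factor(sample(c("axiom", "bileve"), n, replace = TRUE,
                          prob = c(0.9, 0.1))),
    stringsAsFactors = FALSE)
  for (k in 1:5) cohort[[paste0("pc", k)]] <- stats::rnorm(n)
  cohort <- cbind(cohort, as.data.frame(g))
  cohort$confounder <- stats::rnorm(n)
  cohort$telomere_sd <- simulate_telomere(g, spec)
  if (confounded)
    cohort$telomere_sd <- cohort$telomere_sd +
      spec$confounder_strength * cohort$confounder
  cohort <- simulate_outcomes(cohort, spec)
  cohort <- cbind(cohort, simulate_parental_ages(n, spec$seed))

  set.seed(stage_seed(spec$seed, "phenotypes"))
  old <- cohort$age >= 60
  lambda <- ifelse(old, 6.3, 1.7)
  items <- matrix(stats::rbinom(n * 49, 1, rep(lambda / 49, 49)), n, 49)
  colnames(items) <- sprintf("deficit_%02d", 1:49)
  cohort <- cbind(cohort, as.data.frame(items))
  male <- cohort$sex == "M"
  cohort$grip_max_kg <- pmax(0, stats::rnorm(n, ifelse(male, 40, 24),
                                             ifelse(male, 8, 6)))
  cohort$smi_kg_m2 <- pmax(3, stats::rnorm(n, ifelse(male, 9.6, 7.1),
                                           ifelse(male, 1.1, 0.9)))
  cohort$reaction_time_ms <- exp(stats::rnorm(n, log(556) - 0.02, 0.2))
  cohort$visual_memory_errors <- stats::rpois(n, 4.1)
  cohort$weight_loss <- stats::runif(n) < 0.08
  cohort$exhaustion <- stats::runif(n) < 0.12
  cohort$slow_pace <- stats::runif(n) < 0.07
  cohort$activity <- pmax(0, stats::rnorm(n, 2000, 900))
  cohort$depression_response <- sample(
    c("Not at all", "Several days", "More than half the days",
      "Nearly every day", "Do not know"), n, replace = TRUE,
    prob = c(0.70, 0.18, 0.04, 0.03, 0.05))
  for (p in c("back_pain_response", "hip_pain_response", "knee_pain_response"))
    cohort[[p]] <- sample(c("Yes", "No", "Do not know", "Prefer not to answer"),
                          n, replace = TRUE, prob = c(0.15, 0.82, 0.02, 0.01))
  cohort$falls_response <- sample(
    c("No falls", "Only one fall", "More than one fall", "Prefer not to answer"),
    n, replace = TRUE, prob = c(0.79, 0.13, 0.07, 0.01))
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Write / read a cohort table as tab-separated text
#'
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  x$centre <- factor(x$centre)
  x$array <- factor(x$array)
  class(x) <- c("cohort_table", "data.frame")
  x
}
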