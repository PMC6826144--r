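#' @keywords internal
"_PACKAGE"

# Classed conditions: every user-facing failure carries a class named after the
# contract it violates (DuplicateInstrument, SchemaError, ValidationError, ...)
# so callers can test with expect_error(..., class = "...").
abort <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "telomr_error")))
}

warn <- function(msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = "telomr_warning"))
}

#' Derive a per-stage random seed from a master seed
#'
#' All stochastic stages draw from streams derived from one master seed by
#' fixed offsets, so a pipeline run is reproducible end to end while stages
#' remain independently re-runnable.
#'
#' @param seed master integer seed.
#' @param stage character stage label (fixed offset per label).
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  offsets <- c(genotypes = 11L, telomere = 29L, outcomes = 47L,
               parental = 71L, covariates = 101L, phenotypes = 131L)
  off <- offsets[[stage]]
  if (is.null(off)) abort("ValidationError", "unknown stage '%s'", stage)
  as.integer((as.numeric(seed) * 1000 + off) %% 2147483647)
}

# Eigen-clip PSD repair: clip eigenvalues at `floor`, reconstruct, rescale to
# unit diagonal. Used for both the sqrt(r2) instrument correlation matrix and
# the GLS weight matrix when numerically indefinite.
psd_repair <- function(m, floor = 1e-8, quiet = FALSE) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -1e-10) return(m)
  if (!quiet) warn("matrix not positive semi-definite (min eigenvalue %.3e); eigenvalues clipped at %.0e", min(e$values), floor)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

is_psd <- function(m, tol = -1e-10) {
  min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) >= tol
}

# z-score over non-missing entries; degenerate (zero-variance) input errors.
zscore <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    abort("DegenerateDistribution", "cannot z-transform a constant vector")
  (x - mu) / s
}
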