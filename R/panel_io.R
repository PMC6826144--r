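#' Scaling constants between SD of telomere length, base pairs and years
#'
#' One standard deviation of mean leukocyte telomere length corresponds to
#' approximately 650 base pairs; adult attrition runs at about 25 bp per year,
#' so 250 bp is roughly the loss over a decade. These constants drive every
#' unit conversion in the package.
#'
#' @param bp_per_sd base pairs per SD of telomere length (default 650).
#' @param bp_per_year attrition rate in bp per year (default 25).
#' @param bp_per_decade bp per decade (default 250).
#' @return an object of class `scaling_constants`.
#' @export
scaling_constants <- function(bp_per_sd = 650, bp_per_year = 25,
                              bp_per_decade = 250) {
  if (bp_per_sd <= 0 || bp_per_year <= 0 || bp_per_decade <= 0)
    abort("ValidationError", "scaling constants must be positive")
  structure(list(bp_per_sd = bp_per_sd, bp_per_year = bp_per_year,
                 bp_per_decade = bp_per_decade),
            class = "scaling_constants")
}

PANEL_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta_sd", "se_sd", "locus")

#' Load and validate a telomere-length instrument panel
#'
#' Reads a tab-separated instrument table (one row per SNP) and an optional
#' tab-separated square matrix of pairwise r-squared values, validates the
#' records, and orients every SNP so the effect allele is the one associated
#' with longer telomeres (negative effects are flipped: alleles swapped, beta
#' negated, effect-allele frequency complemented).
#'
#' Rows with effect-allele frequency outside [0.05, 0.95] are rejected: the
#' panel construction excluded variants with minor allele frequency below 5%.
#'
#' @param path instrument table, columns
#'   `rsid chrom pos effect_allele other_allele eaf beta_sd se_sd locus`.
#' @param ld_path optional square r-squared matrix with rsid header row and
#'   first column; identity assumed when omitted.
#' @param scaling a [scaling_constants()] object, stored on the panel.
#' @return an object of class `snp_panel` with elements `snps` (data.frame),
#'   `r2`, `r` (J x J matrices) and `scaling`.
#' @export
load_panel <- function(path, ld_path = NULL, scaling = scaling_constants()) {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) abort("SchemaError", "cannot read panel file '%s': %s",
                              path, conditionMessage(e)))
  if (nrow(tab) == 0) abort("SchemaError", "panel file '%s' has no rows", path)
  r2 <- NULL
  if (!is.null(ld_path)) {
    m <- utils::read.table(ld_path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
    r2 <- as.matrix(m)
    r2 <- r2[tab$rsid, tab$rsid, drop = FALSE]
  }
  new_panel(tab, r2 = r2, scaling = scaling)
}

#' Construct a validated instrument panel from a data frame
#'
#' @param snps data.frame with the instrument columns (see [load_panel()]).
#' @param r2 optional J x J r-squared matrix (identity when `NULL`).
#' @param scaling a [scaling_constants()] object.
#' @return an `snp_panel`.
#' @export
new_panel <- function(snps, r2 = NULL, scaling = scaling_constants()) {
  missing_cols <- setdiff(PANEL_COLS, names(snps))
  if (length(missing_cols) > 0)
    abort("SchemaError", "panel is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  snps <- as.data.frame(snps)[, PANEL_COLS]
  if (anyDuplicated(snps$rsid))
    abort("DuplicateInstrument", "duplicate rsid(s): %s",
          paste(unique(snps$rsid[duplicated(snps$rsid)]), collapse = ", "))
  ok_allele <- snps$effect_allele %in% c("A", "C", "G", "T") &
    snps$other_allele %in% c("A", "C", "G", "T")
  if (!all(ok_allele))
    abort("ValidationError", "non-ACGT allele code in rows: %s",
          paste(snps$rsid[!ok_allele], collapse = ", "))
  if (any(snps$effect_allele == snps$other_allele))
    abort("ValidationError", "effect and other allele identical for %s",
          paste(snps$rsid[snps$effect_allele == snps$other_allele], collapse = ", "))
  if (any(!is.finite(snps$se_sd) | snps$se_sd <= 0))
    abort("ValidationError", "non-positive standard error for %s",
          paste(snps$rsid[!is.finite(snps$se_sd) | snps$se_sd <= 0], collapse = ", "))
  bad_eaf <- !is.finite(snps$eaf) | snps$eaf < 0.05 | snps$eaf > 0.95
  if (any(bad_eaf))
    abort("ValidationError",
          "effect-allele frequency outside [0.05, 0.95] (MAF < 0.05 exclusion) for %s",
          paste(snps$rsid[bad_eaf], collapse = ", "))
  # Orient every instrument to the telomere-lengthening allele.
  flip <- snps$beta_sd < 0
  if (any(flip)) {
    ea <- snps$effect_allele[flip]
    snps$effect_allele[flip] <- snps$other_allele[flip]
    snps$other_allele[flip] <- ea
    snps$eaf[flip] <- 1 - snps$eaf[flip]
    snps$beta_sd[flip] <- -snps$beta_sd[flip]
  }
  J <- nrow(snps)
  if (is.null(r2)) r2 <- diag(1, J)
  r2 <- as.matrix(r2)
  if (!all(dim(r2) == c(J, J)))
    abort("ValidationError", "LD matrix is %d x %d but panel has %d SNPs",
          nrow(r2), ncol(r2), J)
  dimnames(r2) <- list(snps$rsid, snps$rsid)
  r <- ld_from_r2(r2)
  structure(list(snps = snps, r2 = r2, r = r, scaling = scaling),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("<snp_panel> %d instruments (%s), all oriented to the telomere-lengthening allele\n",
              nrow(x$snps), paste(unique(x$snps$locus), collapse = ", ")))
  print(x$snps, row.names = FALSE)
  invisible(x)
}

#' Write an instrument panel back to a tab-separated file
#'
#' Inverse of [load_panel()] for the instrument table; round-trips the fixture
#' file bit-identically.
#'
#' @param panel an `snp_panel`.
#' @param path output path for the instrument table.
#' @param ld_path optional output path for the r-squared matrix.
#' @export
write_panel <- function(panel, path, ld_path = NULL) {
  utils::write.table(panel$snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(ld_path)) {
    m <- format(panel$r2, trim = TRUE)
    utils::write.table(cbind(rsid = rownames(panel$r2), m), ld_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(panel)
}

#' Instrument correlation matrix from pairwise r-squared
#'
#' The inter-instrument correlation used by the correlated-instrument
#' estimators is the elementwise square root of the r-squared matrix (the sign
#' of D' is discarded; orientation to lengthening alleles makes nonnegative
#' correlation the coherent convention). If the square-root matrix is not
#' positive semi-definite it is repaired by clipping eigenvalues at 1e-8 and
#' rescaling to unit diagonal, with a warning.
#'
#' @param r2 symmetric matrix of squared correlations, unit diagonal,
#'   entries in [0, 1].
#' @return the (possibly repaired) correlation matrix r.
#' @export
ld_from_r2 <- function(r2) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2) || max(abs(r2 - t(r2))) > 1e-8)
    abort("ValidationError", "r2 matrix must be square and symmetric")
  if (any(r2 < -1e-12) || any(r2 > 1 + 1e-12))
    abort("ValidationError", "r2 entries must lie in [0, 1]")
  if (max(abs(diag(r2) - 1)) > 1e-8)
    abort("ValidationError", "r2 diagonal must be 1")
  r <- sqrt(pmin(pmax(r2, 0), 1))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  psd_repair(r)
}

#' Drop instruments in perfect linkage disequilibrium
#'
#' For each pair with r-squared equal to 1 (within 1e-12) the later-listed SNP
#' is dropped, mirroring the panel construction where one of two perfectly
#' correlated variants was removed. Idempotent.
#'
#' @param panel an `snp_panel`.
#' @return the pruned panel.
#' @export
prune_perfect_ld <- function(panel) {
  r2 <- panel$r2
  J <- nrow(r2)
  drop <- logical(J)
  for (i in seq_len(J)) {
    if (drop[i]) next
    for (j in seq_len(J)) {
      if (j <= i || drop[j]) next
      if (abs(r2[i, j] - 1) < 1e-12) {
        drop[j] <- TRUE
        message(sprintf("prune_perfect_ld: dropping %s (r2 = 1 with %s)",
                        panel$snps$rsid[j], panel$snps$rsid[i]))
      }
    }
  }
  if (!any(drop)) return(panel)
  keep <- !drop
  new_panel(panel$snps[keep, , drop = FALSE],
            r2 = panel$r2[keep, keep, drop = FALSE],
            scaling = panel$scaling)
}

#' Rescale an effect estimate to a different telomere-length increment
#'
#' Estimates are natively per one SD of telomere length (`bp_per_sd` base
#' pairs). Log-scale effects (log-odds, SD change in the outcome) scale
#' linearly with the increment; odds ratios exponentiate:
#' OR_target = OR^(target_bp / bp_per_sd). An OR of 1.2 per 650 bp is an OR of
#' 1.07 per 250 bp; a 0.1 SD change per 650 bp is 0.038 SD per 250 bp.
#'
#' @param effect effect estimate(s) per `scaling$bp_per_sd` base pairs.
#' @param target_bp base-pair increment to rescale to.
#' @param scaling a [scaling_constants()] object.
#' @param scale `"log"` for log-odds / SD-change effects, `"or"` for odds
#'   ratios.
#' @return the rescaled effect.
#' @export
bp_rescale <- function(effect, target_bp, scaling = scaling_constants(),
                       scale = c("log", "or")) {
  scale <- match.arg(scale)
  if (!is.numeric(target_bp) || target_bp <= 0)
    abort("ValidationError", "target_bp must be positive")
  f <- target_bp / scaling$bp_per_sd
  if (scale == "log") effect * f else effect^f
}

#' Years of age-related telomere attrition equivalent to a bp difference
#'
#' @param bp base pairs of telomere length.
#' @param scaling a [scaling_constants()] object.
#' @return years, `bp / bp_per_year` (650 bp is about 26 years).
#' @export
years_equivalent <- function(bp, scaling = scaling_constants()) {
  bp / scaling$bp_per_year
}
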