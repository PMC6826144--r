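#' Derived analysis outcomes
#'
#' A `derived_outcome` carries per-individual codes for one analysis outcome:
#' binary outcomes have exactly three states (1 = case, 0 = control,
#' NA = excluded), continuous outcomes are real-valued with NA for excluded or
#' missing, z-scored over the non-missing entries when standardized. The
#' derivation audit records each transform applied and the exclusion count.
#'
#' @param name outcome name.
#' @param kind `"binary"` or `"continuous"`.
#' @param values coded vector (see above).
#' @param transform_log character vector of applied steps.
#' @return a `derived_outcome`.
#' @export
derived_outcome <- function(name, kind = c("binary", "continuous"), values,
                            transform_log = character()) {
  kind <- match.arg(kind)
  if (kind == "binary" && !all(values %in% c(0, 1, NA)))
    abort("ValidationError", "binary outcome '%s' has codes outside {0, 1, NA}", name)
  structure(list(name = name, kind = kind, values = values,
                 transform_log = transform_log,
                 n_excluded = sum(is.na(values))),
            class = "derived_outcome")
}

#' @export
print.derived_outcome <- function(x, ...) {
  if (x$kind == "binary")
    cat(sprintf("<derived_outcome> %s (binary): %d cases / %d controls / %d excluded\n",
                x$name, sum(x$values == 1, na.rm = TRUE),
                sum(x$values == 0, na.rm = TRUE), x$n_excluded))
  else
    cat(sprintf("<derived_outcome> %s (continuous): %d observed / %d excluded [%s]\n",
                x$name, sum(!is.na(x$values)), x$n_excluded,
                paste(x$transform_log, collapse = " -> ")))
  invisible(x)
}

#' Early-death cutoff from a parental age-at-death distribution
#'
#' Premature parental deaths are excluded below a cutoff defined as the modal
#' age at death minus one standard deviation. The mode is the maximizer of a
#' Gaussian-kernel density (Silverman's bandwidth) on a 0.1-year grid. Because
#' real age-at-death distributions are left-skewed by premature deaths, the SD
#' is fitted to the right half only (ages above the mode, reflected about it)
#' by default; `method = "gaussian_ml"` instead uses the plain normal fit to
#' the full sample.
#'
#' @param ages ages at death (>= 100 non-missing values required).
#' @param method `"kde_halfnormal"` (default) or `"gaussian_ml"`.
#' @return a `cutoff_estimate` with `modal_age`, `sd` and
#'   `cutoff = modal_age - sd`.
#' @export
early_death_cutoff <- function(ages, method = c("kde_halfnormal", "gaussian_ml")) {
  method <- match.arg(method)
  ages <- ages[!is.na(ages)]
  if (length(ages) < 100)
    abort("InsufficientData", "need at least 100 ages, got %d", length(ages))
  if (stats::sd(ages) == 0)
    abort("DegenerateDistribution", "ages are constant; no cutoff can be fit")
  if (method == "gaussian_ml") {
    mode_est <- mean(ages)
    sd_est <- stats::sd(ages)
  } else {
    bw <- stats::bw.nrd0(ages)
    grid <- seq(min(ages), max(ages), by = 0.1)
    dens <- stats::density(ages, bw = bw, from = min(grid), to = max(grid),
                           n = length(grid))
    mode_est <- dens$x[which.max(dens$y)]
    upper <- ages[ages >= mode_est]
    # half-normal SD from the right tail reflected about the mode
    sd_est <- sqrt(mean((upper - mode_est)^2))
  }
  structure(list(modal_age = mode_est, sd = sd_est,
                 cutoff = mode_est - sd_est, method = method),
            class = "cutoff_estimate")
}

#' Apply early-death cutoffs to parental ages
#'
#' Ages at death below the parent-specific cutoff are set missing so premature
#' deaths do not enter lifespan outcomes. Living parents are untouched.
#'
#' @param age attained age / age at death.
#' @param dead logical death flag.
#' @param cutoff numeric cutoff in years (e.g. 46 for fathers, 57 for mothers).
#' @return age vector with premature deaths set to `NA`.
#' @export
apply_early_death_cutoff <- function(age, dead, cutoff) {
  age[dead & !is.na(age) & age < cutoff] <- NA
  age
}

#' Average parental lifespan as a z-score
#'
#' For participants where both parents died (with ages above the early-death
#' cutoffs), the outcome is the mean of the father's and mother's age at
#' death, each z-transformed within its own parent's gender. Everyone else is
#' excluded.
#'
#' @param father_age,mother_age ages at death (NA where premature/unknown).
#' @param father_dead,mother_dead logical death flags.
#' @return continuous `derived_outcome`.
#' @export
parental_lifespan_z <- function(father_age, mother_age, father_dead,
                                mother_dead) {
  eligible <- father_dead & mother_dead & !is.na(father_age) & !is.na(mother_age)
  fz <- mz <- rep(NA_real_, length(father_age))
  fz[eligible] <- zscore(father_age[eligible])
  mz[eligible] <- zscore(mother_age[eligible])
  derived_outcome("parents_age_at_death", "continuous", (fz + mz) / 2,
                  transform_log = c("z_by_parent_gender", "average"))
}

#' Both parents in the top decile of survival
#'
#' Case: father reached at least 87 years AND mother at least 90, regardless
#' of death status. Control: both parents dead before 80. All other
#' configurations are excluded.
#'
#' @inheritParams parental_lifespan_z
#' @return binary `derived_outcome`.
#' @export
top10_survival <- function(father_age, mother_age, father_dead, mother_dead) {
  case <- !is.na(father_age) & !is.na(mother_age) &
    father_age >= 87 & mother_age >= 90
  control <- father_dead & mother_dead & !is.na(father_age) &
    !is.na(mother_age) & father_age < 80 & mother_age < 80
  v <- rep(NA_real_, length(father_age))
  v[control] <- 0
  v[case] <- 1
  derived_outcome("both_parents_top10_survival", "binary", v)
}

#' Centenarian status of parents
#'
#' Case: father reached at least 96 years OR mother at least 100 (top 1% of
#' their birth cohort), regardless of death status. Control: father died
#' before 90 AND mother died before 95. Others excluded.
#'
#' @inheritParams parental_lifespan_z
#' @return binary `derived_outcome`.
#' @export
centenarian_status <- function(father_age, mother_age, father_dead,
                               mother_dead) {
  case <- (!is.na(father_age) & father_age >= 96) |
    (!is.na(mother_age) & mother_age >= 100)
  control <- father_dead & mother_dead & !is.na(father_age) &
    !is.na(mother_age) & father_age < 90 & mother_age < 95
  v <- rep(NA_real_, length(father_age))
  v[control] <- 0
  v[case] <- 1
  derived_outcome("centenarian_parents", "binary", v)
}

#' Deficit-accumulation frailty index
#'
#' Sums 49 binary deficit items (47 when the two cancer-related items are
#' excluded for the sensitivity version), applies the skew-correcting
#' log(x + 1) transform, and z-scores. Individuals missing any item are
#' excluded.
#'
#' @param items n x 49 matrix/data.frame of 0/1 deficit indicators.
#' @param exclude_cancer drop the two cancer items (columns `cancer_items`)
#'   to form the 47-item index.
#' @param cancer_items column indices of the two cancer-related items.
#' @param standardize z-score after the log transform (default TRUE).
#' @return continuous `derived_outcome`.
#' @export
frailty_index <- function(items, exclude_cancer = FALSE,
                          cancer_items = c(48L, 49L), standardize = TRUE) {
  items <- as.matrix(items)
  if (ncol(items) != 49)
    abort("SchemaError", "frailty index requires 49 items, got %d", ncol(items))
  if (exclude_cancer) items <- items[, -cancer_items, drop = FALSE]
  counts <- rowSums(items)          # NA if any item missing -> excluded
  x <- log(counts + 1)
  log_steps <- c(if (exclude_cancer) "drop_2_cancer_items", "sum", "log1p")
  if (standardize) {
    x <- zscore(x)
    log_steps <- c(log_steps, "zscore")
  }
  derived_outcome(if (exclude_cancer) "frailty_index_47" else "frailty_index_49",
                  "continuous", x, transform_log = log_steps)
}

#' Cognitive outcome transforms
#'
#' Reaction time is log-transformed; visual memory errors are log(x + 1)
#' transformed (both to correct right skew); both are then z-scored.
#'
#' @param reaction_time_ms mean reaction time, strictly positive.
#' @param visual_memory_errors nonnegative error counts.
#' @param standardize z-score after transform (default TRUE).
#' @return list of two continuous `derived_outcome`s
#'   (`reaction_time`, `visual_memory_errors`).
#' @export
cognitive_transforms <- function(reaction_time_ms, visual_memory_errors,
                                 standardize = TRUE) {
  if (any(reaction_time_ms <= 0, na.rm = TRUE))
    abort("ValidationError", "reaction time must be positive")
  if (any(visual_memory_errors < 0, na.rm = TRUE))
    abort("ValidationError", "visual memory errors must be nonnegative")
  rt <- log(reaction_time_ms)
  vm <- log(visual_memory_errors + 1)
  rt_log <- "log"; vm_log <- "log1p"
  if (standardize) {
    rt <- zscore(rt); vm <- zscore(vm)
    rt_log <- c(rt_log, "zscore"); vm_log <- c(vm_log, "zscore")
  }
  list(reaction_time = derived_outcome("reaction_time", "continuous", rt,
                                       transform_log = rt_log),
       visual_memory_errors = derived_outcome("visual_memory_errors",
                                              "continuous", vm,
                                              transform_log = vm_log))
}

#' EWGSOP sarcopenia and its components
#'
#' Low grip: maximal hand grip strength strictly below 30 kg (men) / 20 kg
#' (women). Low muscle mass: skeletal muscle mass index strictly below
#' 8.87 kg/m2 (men) / 6.42 kg/m2 (women). Sarcopenia requires both.
#'
#' @param grip_max_kg maximal hand grip strength, kg.
#' @param smi_kg_m2 skeletal muscle mass index, kg/m2.
#' @param sex `"M"`/`"F"` codes.
#' @return list of binary `derived_outcome`s: `sarcopenia`, `low_grip`,
#'   `low_muscle`.
#' @export
sarcopenia <- function(grip_max_kg, smi_kg_m2, sex) {
  if (!all(sex %in% c("M", "F", NA)))
    abort("ValidationError", "sex codes must be 'M' or 'F'")
  male <- sex == "M"
  grip_cut <- ifelse(male, 30, 20)
  smi_cut <- ifelse(male, 8.87, 6.42)
  low_grip <- as.numeric(grip_max_kg < grip_cut)
  low_muscle <- as.numeric(smi_kg_m2 < smi_cut)
  sarc <- as.numeric(low_grip == 1 & low_muscle == 1)
  list(sarcopenia = derived_outcome("sarcopenia", "binary", sarc),
       low_grip = derived_outcome("low_grip", "binary", low_grip),
       low_muscle = derived_outcome("low_muscle", "binary", low_muscle))
}

#' Fried frailty phenotype
#'
#' Frail if meeting three or more of five criteria: self-reported weight loss,
#' exhaustion, slow walking pace, low grip strength and low physical activity.
#' The grip and activity criteria are the lowest 20% by sex within the sample
#' analyzed (type-7 quantile). Any missing element excludes the individual.
#'
#' @param weight_loss,exhaustion,slow_pace logical self-report criteria.
#' @param grip_max_kg maximal hand grip strength, kg.
#' @param activity total physical activity score.
#' @param sex `"M"`/`"F"` codes.
#' @return binary `derived_outcome`.
#' @export
fried_frailty <- function(weight_loss, exhaustion, slow_pace, grip_max_kg,
                          activity, sex) {
  if (!all(sex %in% c("M", "F", NA)))
    abort("ValidationError", "sex codes must be 'M' or 'F'")
  low_by_sex <- function(x) {
    out <- rep(NA, length(x))
    for (s in c("M", "F")) {
      i <- which(sex == s & !is.na(x))
      if (length(i) > 0) {
        q <- stats::quantile(x[i], 0.20, type = 7, names = FALSE)
        out[i] <- x[i] <= q
      }
    }
    out
  }
  crit <- cbind(weight_loss, exhaustion, slow_pace,
                low_by_sex(grip_max_kg), low_by_sex(activity))
  score <- rowSums(crit)            # NA when any element missing -> excluded
  derived_outcome("fried_frailty", "binary", as.numeric(score >= 3))
}

#' Binary codings for categorical survey outcomes
#'
#' Depression over the last two weeks: any response other than "Not at all" is
#' a case; "Do not know" and no response are excluded. Chronic pains (3+
#' months): "Yes" is a case, "No" a control, "Do not know" / "Prefer not to
#' answer" / no response excluded. Falls in the last year: "Only one fall" and
#' "More than one fall" combine to the case group; "Prefer not to answer" and
#' no response are excluded.
#'
#' @param responses character vector of survey responses (`NA` = no response).
#' @param kind one of `"depression"`, `"pain"`, `"falls"`.
#' @param name outcome name for the result.
#' @return binary `derived_outcome`.
#' @export
categorical_coding <- function(responses,
                               kind = c("depression", "pain", "falls"),
                               name = kind) {
  kind <- match.arg(kind)
  levels_known <- switch(kind,
    depression = c("Not at all", "Several days", "More than half the days",
                   "Nearly every day", "Do not know"),
    pain = c("Yes", "No", "Do not know", "Prefer not to answer"),
    falls = c("No falls", "Only one fall", "More than one fall",
              "Prefer not to answer"))
  bad <- !is.na(responses) & !(responses %in% levels_known)
  if (any(bad))
    abort("ValidationError", "unknown %s response label(s): %s", kind,
          paste(unique(responses[bad]), collapse = ", "))
  v <- rep(NA_real_, length(responses))
  if (kind == "depression") {
    v[responses == "Not at all"] <- 0
    v[responses %in% c("Several days", "More than half the days",
                       "Nearly every day")] <- 1
  } else if (kind == "pain") {
    v[responses == "No"] <- 0
    v[responses == "Yes"] <- 1
  } else {
    v[responses == "No falls"] <- 0
    v[responses %in% c("Only one fall", "More than one fall")] <- 1
  }
  derived_outcome(name, "binary", v)
}

#' Derive the full outcome set from a simulated cohort
#'
#' Convenience wrapper running every derivation on a `cohort_table`, applying
#' the early-death cutoffs estimated from the dead parents first.
#'
#' @param cohort a `cohort_table` from [simulate_cohort()].
#' @return named list of `derived_outcome`s.
#' @export
derive_outcomes <- function(cohort) {
  f_cut <- early_death_cutoff(cohort$father_age[cohort$father_dead])
  m_cut <- early_death_cutoff(cohort$mother_age[cohort$mother_dead])
  fa <- apply_early_death_cutoff(cohort$father_age, cohort$father_dead, f_cut$cutoff)
  mo <- apply_early_death_cutoff(cohort$mother_age, cohort$mother_dead, m_cut$cutoff)
  items <- as.matrix(cohort[, sprintf("deficit_%02d", 1:49)])
  out <- c(
    list(
      parents_age_at_death = parental_lifespan_z(fa, mo, cohort$father_dead,
                                                 cohort$mother_dead),
      both_parents_top10_survival = top10_survival(fa, mo, cohort$father_dead,
                                                   cohort$mother_dead),
      centenarian_parents = centenarian_status(fa, mo, cohort$father_dead,
                                               cohort$mother_dead),
      frailty_index_49 = frailty_index(items, exclude_cancer = FALSE),
      frailty_index_47 = frailty_index(items, exclude_cancer = TRUE),
      fried_frailty = fried_frailty(cohort$weight_loss, cohort$exhaustion,
                                    cohort$slow_pace, cohort$grip_max_kg,
                                    cohort$activity, cohort$sex),
      depression = categorical_coding(cohort$depression_response, "depression"),
      back_pain = categorical_coding(cohort$back_pain_response, "pain", "back_pain"),
      hip_pain = categorical_coding(cohort$hip_pain_response, "pain", "hip_pain"),
      knee_pain = categorical_coding(cohort$knee_pain_response, "pain", "knee_pain"),
      falls = categorical_coding(cohort$falls_response, "falls", "falls")),
    cognitive_transforms(cohort$reaction_time_ms, cohort$visual_memory_errors),
    sarcopenia(cohort$grip_max_kg, cohort$smi_kg_m2, cohort$sex))
  out
}
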