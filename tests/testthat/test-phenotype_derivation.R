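test_that("early-death cutoff: mode - SD for a pure normal sample", {
  set.seed(101)
  ages <- rnorm(200000, 77.37, 9.83)
  cut <- early_death_cutoff(ages)
  expect_equal(cut$cutoff, 77.37 - 9.83, tolerance = 0.5)
  expect_lt(cut$cutoff, cut$modal_age)
  # plain Gaussian-ML variant agrees for symmetric input
  cut_ml <- early_death_cutoff(ages, method = "gaussian_ml")
  expect_equal(cut_ml$cutoff, cut$cutoff, tolerance = 0.5)
})

test_that("early-death cutoff is robust to a premature-death component", {
  set.seed(102)
  n <- 100000
  prem <- runif(n) < 0.05
  ages <- ifelse(prem, rnorm(n, 45, 5), rnorm(n, 75, 10))
  cut <- early_death_cutoff(ages)
  expect_equal(cut$modal_age, 75, tolerance = 1)
  expect_equal(cut$cutoff, 65, tolerance = 1.5)
  # the premature component falls below the cutoff and is excluded downstream
  flagged <- apply_early_death_cutoff(ages, rep(TRUE, n), cut$cutoff)
  expect_gt(mean(is.na(flagged[prem])), 0.95)

  expect_error(early_death_cutoff(rep(70, 500)),
               class = "DegenerateDistribution")
  expect_error(early_death_cutoff(rnorm(50)), class = "InsufficientData")
})

test_that("parental lifespan z-score: by-parent z-transform, both-dead rule", {
  fa <- c(60, 70, 80, 75, NA)
  mo <- c(70, 80, 90, 85, 80)
  f_dead <- c(TRUE, TRUE, TRUE, FALSE, TRUE)   # 4th: father alive -> excluded
  m_dead <- c(TRUE, TRUE, TRUE, TRUE, TRUE)
  out <- parental_lifespan_z(fa, mo, f_dead, m_dead)
  expect_equal(out$kind, "continuous")
  # eligible sample is rows 1:3; both parents at their sample mean -> 0
  expect_equal(out$values[2], 0)
  expect_equal(out$values[1], -1)   # both exactly 1 within-sample SD below
  expect_equal(out$values[3], 1)
  expect_true(is.na(out$values[4]))  # father alive
  expect_true(is.na(out$values[5]))  # father premature/missing
  expect_equal(out$n_excluded, 2)

  # symmetric under swapping the parents' z-scores
  swapped <- parental_lifespan_z(mo, fa, m_dead, f_dead)
  expect_equal(swapped$values, out$values)
})

test_that("top-10% survival truth table", {
  # exhaustive oracle over the two stated rules
  grid <- expand.grid(fa = c(75, 85, 88), fd = c(TRUE, FALSE),
                      ma = c(75, 85, 91), md = c(TRUE, FALSE))
  out <- top10_survival(grid$fa, grid$ma, grid$fd, grid$md)
  oracle <- ifelse(grid$fa >= 87 & grid$ma >= 90, 1,
                   ifelse(grid$fd & grid$md & grid$fa < 80 & grid$ma < 80,
                          0, NA))
  expect_equal(out$values, oracle)
  # the published example codings
  expect_equal(top10_survival(88, 91, FALSE, TRUE)$values, 1)  # alive father
  expect_equal(top10_survival(79, 78, TRUE, TRUE)$values, 0)
  expect_true(is.na(top10_survival(85, 92, TRUE, TRUE)$values))
})

test_that("centenarian status truth table", {
  grid <- expand.grid(fa = c(85, 92, 96), fd = c(TRUE, FALSE),
                      ma = c(85, 94, 101), md = c(TRUE, FALSE))
  out <- centenarian_status(grid$fa, grid$ma, grid$fd, grid$md)
  oracle <- ifelse(grid$fa >= 96 | grid$ma >= 100, 1,
                   ifelse(grid$fd & grid$md & grid$fa < 90 & grid$ma < 95,
                          0, NA))
  expect_equal(out$values, oracle)
  expect_equal(centenarian_status(96, 80, FALSE, TRUE)$values, 1)
  expect_equal(centenarian_status(89, 94, TRUE, TRUE)$values, 0)
  expect_true(is.na(centenarian_status(92, 94, TRUE, TRUE)$values))
})

test_that("frailty index: sum, log1p, z-score, missingness, cancer items", {
  items <- matrix(0, 4, 49)
  items[2, 1:6] <- 1
  items[3, c(1:3, 48:49)] <- 1   # includes both cancer items
  items[4, 10] <- NA             # one missing item -> excluded
  fi <- frailty_index(items, standardize = FALSE)
  expect_equal(fi$values[1], 0)            # log(0 + 1)
  expect_equal(fi$values[2], log(7))       # 6 deficits -> log 7 ~ 1.9459
  expect_true(is.na(fi$values[4]))
  expect_equal(fi$n_excluded, 1)

  fi47 <- frailty_index(items, exclude_cancer = TRUE, standardize = FALSE)
  expect_equal(fi47$values[3], log(4))     # two cancer items dropped
  # 47-item index never exceeds the 49-item index pre-transform
  set.seed(7)
  m <- matrix(rbinom(50 * 49, 1, 0.1), 50, 49)
  expect_true(all(frailty_index(m, TRUE, standardize = FALSE)$values <=
                  frailty_index(m, FALSE, standardize = FALSE)$values))
  # monotone: rank order preserved between counts and transformed values
  f <- frailty_index(m, standardize = TRUE)
  expect_equal(order(f$values), order(rowSums(m)))

  expect_error(frailty_index(m[, 1:48]), class = "SchemaError")
})

test_that("cognitive transforms: log and log1p then z-score", {
  ct <- cognitive_transforms(c(exp(3), 500, 556.08), c(0, 3, 10),
                             standardize = FALSE)
  expect_equal(ct$reaction_time$values[1], 3)
  expect_equal(ct$reaction_time$values[3], log(556.08))
  expect_equal(round(ct$reaction_time$values[3], 3), 6.321)
  expect_equal(ct$visual_memory_errors$values[1], 0)
  ct_z <- cognitive_transforms(c(exp(3), 500, 556.08), c(0, 3, 10))
  expect_equal(mean(ct_z$reaction_time$values), 0)
  expect_equal(sd(ct_z$visual_memory_errors$values), 1)
  expect_error(cognitive_transforms(c(-1, 2), c(0, 0)),
               class = "ValidationError")
})

test_that("sarcopenia codings: sex-specific strict cutoffs", {
  s <- sarcopenia(grip_max_kg = c(29, 20.0, 35, 19.9),
                  smi_kg_m2 = c(8.80, 6.0, 9.0, 6.42),
                  sex = c("M", "F", "M", "F"))
  expect_equal(s$sarcopenia$values, c(1, 0, 0, 0))
  expect_equal(s$low_grip$values, c(1, 0, 0, 1))   # F grip 20.0 not < 20
  expect_equal(s$low_muscle$values, c(1, 1, 0, 0)) # F SMI 6.42 not < 6.42
  expect_error(sarcopenia(30, 9, "X"), class = "ValidationError")

  # exhaustive truth table around both cutoffs, both sexes
  grid <- expand.grid(sex = c("M", "F"), lo_g = c(TRUE, FALSE),
                      lo_m = c(TRUE, FALSE), stringsAsFactors = FALSE)
  grip <- ifelse(grid$sex == "M", ifelse(grid$lo_g, 29.9, 30),
                 ifelse(grid$lo_g, 19.9, 20))
  smi <- ifelse(grid$sex == "M", ifelse(grid$lo_m, 8.86, 8.87),
                ifelse(grid$lo_m, 6.41, 6.42))
  st <- sarcopenia(grip, smi, grid$sex)
  expect_equal(st$sarcopenia$values, as.numeric(grid$lo_g & grid$lo_m))
})

test_that("Fried frailty: >= 3 of 5 criteria, sex-specific 20% cuts, missing", {
  set.seed(9)
  n <- 1000
  sex <- rep(c("M", "F"), n / 2)
  grip <- ifelse(sex == "M", rnorm(n, 40, 8), rnorm(n, 24, 6))
  act <- rnorm(n, 2000, 600)
  wl <- rep(FALSE, n); ex <- rep(FALSE, n); sp <- rep(FALSE, n)
  # force three criteria true for individual 1 (weight loss, exhaustion, pace)
  wl[1] <- ex[1] <- sp[1] <- TRUE
  grip[1] <- 60; act[1] <- 5000          # not in the low 20%
  wl[2] <- ex[2] <- TRUE                 # only two -> not frail
  grip[2] <- 60; act[2] <- 5000
  act[3] <- NA                           # missing element -> excluded
  out <- fried_frailty(wl, ex, sp, grip, act, sex)
  expect_equal(out$values[1], 1)
  expect_equal(out$values[2], 0)
  expect_true(is.na(out$values[3]))
  # the grip criterion flags ~20% within each sex
  low_m <- grip[sex == "M"] <= quantile(grip[sex == "M"], 0.2, type = 7)
  expect_equal(mean(low_m), 0.2, tolerance = 0.01)
})

test_that("categorical codings: grouping and exclusion rules", {
  dep <- categorical_coding(c("Not at all", "Several days", "Nearly every day",
                              "Do not know", NA), "depression")
  expect_equal(dep$values, c(0, 1, 1, NA, NA))
  pain <- categorical_coding(c("Yes", "No", "Prefer not to answer",
                               "Do not know", NA), "pain")
  expect_equal(pain$values, c(1, 0, NA, NA, NA))
  falls <- categorical_coding(c("No falls", "Only one fall",
                                "More than one fall", "Prefer not to answer"),
                              "falls")
  expect_equal(falls$values, c(0, 1, 1, NA))
  expect_error(categorical_coding("Sometimes", "pain"),
               class = "ValidationError")
})

test_that("every binary derivation partitions the cohort", {
  spec <- simulation_spec(n = 3000, seed = 13, panel = toy_panel(2))
  cohort <- simulate_cohort(spec)
  outs <- suppressWarnings(derive_outcomes(cohort))
  for (oc in outs) {
    expect_equal(length(oc$values), nrow(cohort))
    if (oc$kind == "binary") {
      n_case <- sum(oc$values == 1, na.rm = TRUE)
      n_ctrl <- sum(oc$values == 0, na.rm = TRUE)
      expect_equal(n_case + n_ctrl + oc$n_excluded, nrow(cohort))
    }
  }
  # standardized continuous outcomes are z-scored over non-missing entries
  fi <- outs$frailty_index_49
  expect_equal(mean(fi$values, na.rm = TRUE), 0, tolerance = 1e-10)
  expect_equal(sd(fi$values, na.rm = TRUE), 1, tolerance = 1e-10)
})
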