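test_that("responses code into exclusive indicators with unknown as missing", {
  responses <- data.frame(
    participant_id = "p1",
    descriptor_id = c("a", "b", "c", "d"),
    response = c("normal", "qualitatively_different", "odorless", "unknown"),
    stringsAsFactors = FALSE
  )
  coded <- code_responses(responses)
  expect_equal(as.numeric(coded$QD["p1", ]), c(0, 1, 0, 0))
  expect_equal(as.numeric(coded$OL["p1", ]), c(0, 0, 1, 0))
  expect_equal(as.numeric(coded$observed_mask["p1", ]), c(1, 1, 1, 0))

  all_unknown <- transform(responses, response = "unknown")
  coded2 <- code_responses(all_unknown)
  expect_true(all(coded2$observed_mask == 0))
  expect_true(all(coded2$QD == 0) && all(coded2$OL == 0))
})

test_that("indicator marginals respect exclusivity on random cohorts", {
  for (s in 1:10) {
    sim <- simulate_cohort(tiny_config(), seed = s)
    coded <- code_responses(sim$cohort)
    expect_true(all(coded$QD + coded$OL <= coded$observed_mask))
    expect_lte(sum(coded$QD) + sum(coded$OL), sum(coded$observed_mask))
    # cells coded in some indicator are exactly the non-normal observed ones
    resp <- sim$cohort$responses
    expect_equal(sum(coded$QD), sum(resp$response == "qualitatively_different"))
    expect_equal(sum(coded$OL), sum(resp$response == "odorless"))
  }
})

test_that("coded matrices follow descriptor-table order, not sort order", {
  t <- small_tables()
  t$descriptors <- t$descriptors[c(2, 3, 1), ]  # fish, rose, coffee
  cohort <- new_cohort(t$responses, t$descriptors, t$participants)
  coded <- code_responses(cohort)
  expect_identical(colnames(coded$QD), c("fish", "rose", "coffee"))
})

test_that("parosmia degree is the weighted sum of its three components", {
  expect_equal(compute_parosmia_degree(5, "daily", 1), 7)
  expect_equal(compute_parosmia_degree(0, "not_daily", 0), 0)
  expect_equal(compute_parosmia_degree(8, "daily", 0, weights = c(1, 2, 3)),
               10)
  expect_true(is.na(compute_parosmia_degree(5, NA, 1)))
  expect_true(is.na(compute_parosmia_degree(NA, "daily", 1)))
  expect_equal(compute_parosmia_degree(c(5, 0), c("daily", "not_daily"),
                                       c(1, 0)), c(7, 0))
  expect_error(compute_parosmia_degree(5, "weekly", 1),
               class = "parosim_validation_error")
  expect_error(compute_parosmia_degree(12, "daily", 1),
               class = "parosim_validation_error")
})

test_that("2-SD standardization matches the closed form and is invertible", {
  z <- standardize_2sd(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-0.5, 0, 0.5))

  # n = 2 closed form: (x - mean) / (2 * sd)
  x <- c(10, 30)
  z2 <- standardize_2sd(x)
  s <- sqrt(sum((x - 20)^2) / 1)
  expect_equal(as.numeric(z2), (x - 20) / (2 * s), tolerance = 1e-15)

  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(25, sd = runif(1, 0.1, 50))
    z <- standardize_2sd(x)
    expect_equal(sd(as.numeric(z)), 0.5, tolerance = 1e-12)
    expect_equal(unstandardize_2sd(z), x, tolerance = 1e-12)
  }

  expect_error(standardize_2sd(c(2, 2, 2), name = "flat"), "flat")
  expect_error(standardize_2sd(c(1, NA, NA), name = "short"), "short")
})

test_that("effect coding maps F/M to +1/-1 with a reversible flag", {
  expect_equal(effect_code(c("F", "M", "F")), c(1, -1, 1))
  expect_equal(effect_code(c("F", "M"), female_positive = FALSE), c(-1, 1))
  expect_warning(effect_code(c("F", "F")), "single level")
  expect_error(effect_code(c("F", "X")), class = "parosim_validation_error")
  # a 30F/18M cohort has mean code 12/48
  coded <- effect_code(rep(c("F", "M"), c(30, 18)))
  expect_equal(mean(coded), 12 / 48)
})

test_that("a complete table passes through imputation unchanged", {
  pp <- simulate_participants(
    sim_config(participant_missing_rates = c(bmi = 0)), seed = 1
  )$participants
  out <- impute_missing(pp, seed = 1)
  expect_identical(out$data, pp)
  expect_equal(nrow(out$report), 0)
})

test_that("an exact linear signal is recovered to numerical precision", {
  n <- 40
  set.seed(2)
  x <- seq(18, 32, length.out = n)
  pp <- data.frame(
    participant_id = sprintf("p%02d", 1:n),
    age = 40, sex = rep(c("F", "M"), n / 2), bmi = x,
    tdi = 2 * x - 20,  # exact linear function of bmi, range [16, 44]
    threshold = 5, duration_months = 12, parosmia_intensity = 5,
    parosmia_frequency = "daily", parosmia_consequences = 1,
    parosmia_valence = -2, subjective_impairment = 5,
    importance_olfaction = 20, depression_adsl = 10,
    stringsAsFactors = FALSE
  )
  miss <- sample(n, 8)
  truth <- pp$tdi[miss]
  pp$tdi[miss] <- NA
  out <- impute_missing(pp, seed = 3)
  expect_equal(out$data$tdi[miss], truth, tolerance = 1e-6)
  expect_equal(sort(out$report$participant_id),
               sort(pp$participant_id[miss]))
  # determinism: same input, same seed
  out2 <- impute_missing(pp, seed = 3)
  expect_identical(out$data, out2$data)
})

test_that("imputation never modifies observed cells", {
  for (s in 1:30) {
    pp <- simulate_participants(sim_config(n_participants = 200L),
                                seed = s)$participants
    out <- impute_missing(pp, seed = s)
    num <- c("age", "bmi", "tdi", "threshold", "duration_months",
             "parosmia_intensity", "parosmia_valence",
             "subjective_impairment", "importance_olfaction",
             "depression_adsl")
    for (v in num) {
      obs <- !is.na(pp[[v]])
      expect_identical(out$data[[v]][obs], pp[[v]][obs])
      expect_false(anyNA(out$data[[v]]))
    }
  }
})

test_that("imputation refuses all-missing variables and flags sparse ones", {
  pp <- simulate_participants(sim_config(), seed = 1)$participants
  pp$tdi <- NA_real_
  expect_error(impute_missing(pp, seed = 1), "tdi")
  pp2 <- simulate_participants(sim_config(), seed = 1)$participants
  pp2$bmi[1:24] <- NA
  expect_warning(out <- impute_missing(pp2, seed = 1), "60%")
  expect_false(anyNA(out$data$bmi))
})

test_that("regression imputation beats column-mean imputation on MCAR data", {
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  wins <- reg_err <- mean_err <- numeric(50)
  for (s in 1:50) {
    set.seed(100 + s)
    n <- 60
    x <- runif(n, 18, 32)
    y <- pmin(pmax(2 * x - 20 + rnorm(n, 0, 1.5), 0), 48)
    pp <- data.frame(
      participant_id = sprintf("p%02d", 1:n),
      age = runif(n, 25, 65), sex = rep(c("F", "M"), n / 2), bmi = x,
      tdi = y, threshold = runif(n, 2, 10), duration_months = 12,
      parosmia_intensity = runif(n, 0, 10), parosmia_frequency = "daily",
      parosmia_consequences = 1, parosmia_valence = -2,
      subjective_impairment = runif(n, 0, 10),
      importance_olfaction = runif(n, 10, 40),
      depression_adsl = runif(n, 0, 40),
      stringsAsFactors = FALSE
    )
    miss <- sample(n, 12)
    truth <- pp$tdi[miss]
    pp$tdi[miss] <- NA
    out <- impute_missing(pp, seed = s)
    reg_err[s] <- rmse(out$data$tdi[miss], truth)
    mean_err[s] <- rmse(mean(pp$tdi, na.rm = TRUE), truth)
  }
  expect_lt(mean(reg_err), mean(mean_err))
})

test_that("the design table standardizes, codes, and records transforms", {
  pp <- simulate_participants(sim_config(n_participants = 200L),
                              seed = 6)$participants
  design <- build_design(pp, seed = 6)
  expect_s3_class(design, "parosim_design")
  expect_equal(ncol(design$x), 10)
  expect_identical(rownames(design$x), pp$participant_id)
  cont <- setdiff(colnames(design$x), "sex")
  for (nm in cont) {
    expect_equal(sd(design$x[, nm]), 0.5, tolerance = 1e-12)
    expect_equal(mean(design$x[, nm]), 0, tolerance = 1e-12)
    tr <- design$transforms[[nm]]
    expect_equal(tr$type, "standardize_2sd")
  }
  expect_true(all(design$x[, "sex"] %in% c(-1, 1)))
  expect_false(anyNA(design$x))
})
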