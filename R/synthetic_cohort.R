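# Synthetic-cohort generator.
#
# Emulates a parosmia odor-classification study: descriptors carry six
# semantic variables with a published correlation structure; participants
# carry clinical covariates with study-level missingness; each (participant,
# descriptor) cell is classified normal / qualitatively_different / odorless
# through a trinomial logit whose linear predictors combine descriptor
# semantics, participant covariates, and a participant random intercept.
# The two published binary model coefficient sets are used as the default
# multinomial slopes — an acknowledged approximation that keeps the three
# categories mutually exclusive by construction.

#' Reference correlation matrix of the six semantic variables
#'
#' Pearson correlations between the olfactory association index (OAI),
#' olfactory specificity index (OSI), valence, arousal, and olfactory and
#' gustatory modality ratings of odor descriptors, as reported for the
#' descriptor set the questionnaire draws from. Used as the default target
#' correlation of [simulate_semantics()].
#'
#' @return a symmetric positive-definite 6 x 6 matrix with unit diagonal.
#' @export
semantic_correlation_reference <- function() {
  v <- c("oai", "osi", "valence", "arousal", "olfactory", "gustatory")
  m <- matrix(c(
     1.000,  0.009, -0.044, -0.233,  0.311, -0.283,
     0.009,  1.000, -0.327, -0.013, -0.246, -0.354,
    -0.044, -0.327,  1.000,  0.144, -0.072,  0.639,
    -0.233, -0.013,  0.144,  1.000, -0.027,  0.456,
     0.311, -0.246, -0.072, -0.027,  1.000, -0.361,
    -0.283, -0.354,  0.639,  0.456, -0.361,  1.000
  ), nrow = 6, byrow = TRUE, dimnames = list(v, v))
  m
}

.semantic_vars <- c("oai", "osi", "valence", "arousal", "olfactory",
                    "gustatory")
.participant_predictors <- c(
  "age", "bmi", "sex", "tdi", "duration_months", "parosmia_degree",
  "parosmia_intensity", "parosmia_valence", "subjective_impairment",
  "importance_olfaction"
)

.default_slopes_qd <- c(
  oai = -0.18, osi = 0.16, valence = -0.59, arousal = 0.12,
  olfactory = 0.95, gustatory = -0.79,
  age = 0.10, bmi = -1.41, sex = -0.83, tdi = 0.33,
  duration_months = -0.18, parosmia_degree = -0.83,
  parosmia_intensity = 1.84, parosmia_valence = -0.16,
  subjective_impairment = -0.16, importance_olfaction = 0.23
)

.default_slopes_ol <- c(
  oai = 0.22, osi = 0.41, valence = 0.17, arousal = 0.23,
  olfactory = -1.03, gustatory = 0.18,
  age = -0.13, bmi = 1.88, sex = -0.64, tdi = -3.13,
  duration_months = -0.14, parosmia_degree = 1.26,
  parosmia_intensity = -1.66, parosmia_valence = 1.39,
  subjective_impairment = 0.62, importance_olfaction = 1.02
)

.default_covariate_params <- list(
  bmi = c(mean = 26, sd = 4, lo = 16, hi = 45),
  tdi = c(mean = 20, sd = 8, lo = 1, hi = 48),
  threshold = c(mean = 4, sd = 2.5, lo = 1, hi = 16),
  duration_months = c(mean = 14, sd = 10, lo = 1, hi = 60),
  parosmia_intensity = c(mean = 6, sd = 2.5, lo = 0, hi = 10),
  parosmia_valence = c(mean = -2, sd = 2, lo = -5, hi = 5),
  importance_olfaction = c(mean = 30, sd = 8, lo = 0, hi = 60),
  depression_adsl = c(mean = 15, sd = 8, lo = 0, hi = 60)
)

#' Simulation configuration
#'
#' All study conditions of the emulated cohort in one object. Defaults match
#' the reported study: 48 participants (30 F / 18 M; age mean 45, SD 12,
#' range 21-70 years), 38 descriptors, the published semantic correlation
#' matrix, published logistic coefficient point estimates as multinomial
#' slopes, 30% missing subjective impairment, 12.5% missing BMI, and 5%
#' missingness elsewhere. Covariates whose distributions are not reported
#' (BMI, TDI, VAS items, ...) use clinical-range truncated normals, all
#' settable through `covariate_params`.
#'
#' @param n_participants,n_descriptors cohort dimensions.
#' @param semantic_correlation 6 x 6 symmetric PSD target correlation matrix
#'   of the semantic variables.
#' @param semantic_means,semantic_sds named affine map from the latent
#'   standard-normal draws onto each variable's rating scale.
#' @param repair_psd if the correlation matrix is not positive semidefinite,
#'   project it to the nearest PSD correlation matrix instead of erroring.
#' @param semantic_missing_rate named per-variable completely-at-random
#'   missingness probabilities for the descriptor table.
#' @param category_intercepts log-odds intercepts `c(qd = , ol = )` of the
#'   qualitatively-different and odorless categories against normal.
#' @param slopes_qd,slopes_ol named coefficient maps over the six semantic
#'   variables and the ten participant predictors, on the 2-SD-standardized
#'   scale.
#' @param random_intercept_sd SD of the participant random intercept shared
#'   by both non-normal categories.
#' @param unknown_rate probability that a response is replaced by `unknown`.
#' @param participant_missing_rates named completely-at-random missingness
#'   probabilities for participant covariates (age and sex stay complete).
#' @param age_mean,age_sd,age_range truncated-normal age distribution.
#' @param p_female,p_daily,p_consequences Bernoulli probabilities for sex,
#'   daily parosmia frequency, and significant consequences.
#' @param covariate_params named list of `c(mean, sd, lo, hi)` truncated
#'   normals for the remaining covariates.
#' @param impairment_severity_link coefficient tying subjective impairment to
#'   the latent severity factor that also scales the random intercept.
#' @return a `parosim_sim_config` list.
#' @export
sim_config <- function(n_participants = 48L,
                       n_descriptors = 38L,
                       semantic_correlation = semantic_correlation_reference(),
                       semantic_means = c(oai = 0, osi = 0, valence = 5,
                                          arousal = 4.5, olfactory = 2.5,
                                          gustatory = 2),
                       semantic_sds = c(oai = 1, osi = 1, valence = 1.5,
                                        arousal = 1.2, olfactory = 1,
                                        gustatory = 1.2),
                       repair_psd = FALSE,
                       semantic_missing_rate = c(oai = 0, osi = 0,
                                                 valence = 0.10,
                                                 arousal = 0.10,
                                                 olfactory = 0.05,
                                                 gustatory = 0.05),
                       category_intercepts = c(qd = 0.12, ol = -1.90),
                       slopes_qd = .default_slopes_qd,
                       slopes_ol = .default_slopes_ol,
                       random_intercept_sd = 0.8,
                       unknown_rate = 0.02,
                       participant_missing_rates = c(
                         subjective_impairment = 0.30, bmi = 0.125,
                         tdi = 0.05, threshold = 0.05,
                         duration_months = 0.05, parosmia_intensity = 0.05,
                         parosmia_frequency = 0.05,
                         parosmia_consequences = 0.05,
                         parosmia_valence = 0.05,
                         importance_olfaction = 0.05,
                         depression_adsl = 0.05),
                       age_mean = 45, age_sd = 12, age_range = c(21, 70),
                       p_female = 30 / 48, p_daily = 0.6,
                       p_consequences = 0.4,
                       covariate_params = .default_covariate_params,
                       impairment_severity_link = 2) {
  as_named_num <- function(x) {
    out <- unlist(x)
    storage.mode(out) <- "double"
    out
  }
  if (is.list(semantic_correlation)) {
    semantic_correlation <- do.call(rbind, lapply(semantic_correlation,
                                                  as.numeric))
    dimnames(semantic_correlation) <- list(.semantic_vars, .semantic_vars)
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_descriptors = as.integer(n_descriptors),
    semantic_correlation = semantic_correlation,
    semantic_means = as_named_num(semantic_means),
    semantic_sds = as_named_num(semantic_sds),
    repair_psd = isTRUE(repair_psd),
    semantic_missing_rate = as_named_num(semantic_missing_rate),
    category_intercepts = as_named_num(category_intercepts),
    slopes_qd = as_named_num(slopes_qd),
    slopes_ol = as_named_num(slopes_ol),
    random_intercept_sd = as.numeric(random_intercept_sd),
    unknown_rate = as.numeric(unknown_rate),
    participant_missing_rates = as_named_num(participant_missing_rates),
    age_mean = as.numeric(age_mean), age_sd = as.numeric(age_sd),
    age_range = as.numeric(unlist(age_range)),
    p_female = as.numeric(p_female), p_daily = as.numeric(p_daily),
    p_consequences = as.numeric(p_consequences),
    covariate_params = lapply(covariate_params, as_named_num),
    impairment_severity_link = as.numeric(impairment_severity_link)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "parosim_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1L, cfg$n_descriptors >= 1L)
  m <- cfg$semantic_correlation
  if (!is.matrix(m) || nrow(m) != length(.semantic_vars) ||
      !isTRUE(all.equal(m, t(m), tolerance = 1e-8)) ||
      !isTRUE(all.equal(unname(diag(m)), rep(1, nrow(m))))) {
    stop("semantic_correlation must be a symmetric 6 x 6 matrix with unit diagonal",
         call. = FALSE)
  }
  probs <- c(cfg$semantic_missing_rate, cfg$unknown_rate,
             cfg$participant_missing_rates, cfg$p_female, cfg$p_daily,
             cfg$p_consequences)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$random_intercept_sd < 0) {
    stop("random_intercept_sd must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

# Factor a correlation matrix for MVN sampling; eigen-based so PSD (but
# rank-deficient) targets are accepted. Negative eigenvalues beyond numerical
# noise error unless repair_psd, which clips them and renormalizes to unit
# diagonal.
correlation_factor <- function(m, repair_psd = FALSE) {
  e <- eigen(m, symmetric = TRUE)
  tol <- -1e-8 * max(abs(e$values))
  if (min(e$values) < tol) {
    if (!repair_psd) {
      stop(paste(
        "semantic_correlation is not positive semidefinite;",
        "set repair_psd = TRUE in sim_config() to project it onto the",
        "nearest PSD correlation matrix"
      ), call. = FALSE)
    }
    vals <- pmax(e$values, 0)
    m2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
    d <- sqrt(diag(m2))
    m2 <- m2 / tcrossprod(d)
    e <- eigen(m2, symmetric = TRUE)
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(m))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a descriptor table with a target semantic correlation structure
#'
#' Draws latent multivariate-normal semantic variables with the configured
#' correlation matrix, maps each column affinely onto its declared rating
#' scale (clipped to the scale bounds), then applies
#' completely-at-random missingness per variable. The complete (pre-missing)
#' matrix is attached as attribute `"latent"` for downstream response
#' simulation and recovery tests.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a validated descriptor data frame of `n_descriptors` rows.
#' @export
simulate_semantics <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  set.seed(seed)
  n <- cfg$n_descriptors
  L <- correlation_factor(cfg$semantic_correlation, cfg$repair_psd)
  z <- matrix(stats::rnorm(n * length(.semantic_vars)), nrow = n) %*% t(L)
  colnames(z) <- .semantic_vars
  vals <- z
  for (v in .semantic_vars) {
    vals[, v] <- cfg$semantic_means[[v]] + cfg$semantic_sds[[v]] * z[, v]
    rng <- .descriptor_ranges[[v]]
    vals[, v] <- pmin(pmax(vals[, v], rng[1]), rng[2])
  }
  ids <- sprintf("d%03d", seq_len(n))
  df <- data.frame(descriptor_id = ids, label = ids, stringsAsFactors = FALSE)
  latent <- vals
  for (v in .semantic_vars) {
    x <- vals[, v]
    r <- cfg$semantic_missing_rate[[v]]
    if (r > 0) x[stats::runif(n) < r] <- NA_real_
    df[[v]] <- x
  }
  df <- validate_descriptors(df)
  attr(df, "latent") <- latent
  df
}

#' Simulate a participant table and its generating parameters
#'
#' Age is truncated normal (mean 45, SD 12, range 21-70 by default); sex is
#' Bernoulli with the study's female share; the remaining covariates follow
#' the configured truncated normals. A latent severity factor `z_i ~ N(0,1)`
#' yields the random intercept `u_i = random_intercept_sd * z_i` and also
#' feeds subjective impairment through `impairment_severity_link`, so a more
#' severely affected patient both classifies more odors as affected and
#' reports higher impairment. Missingness is applied completely at random
#' AFTER the complete table is stored in the returned `true` element.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `participants` (validated data frame, with missingness)
#'   and `true` (complete latent table, severity factor `z`, random
#'   intercepts `u`, and the slope maps in force).
#' @export
simulate_participants <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  set.seed(seed)
  n <- cfg$n_participants
  ids <- sprintf("p%03d", seq_len(n))

  age <- rtrunc_norm(n, cfg$age_mean, cfg$age_sd, cfg$age_range[1],
                     cfg$age_range[2])
  sex <- ifelse(stats::runif(n) < cfg$p_female, "F", "M")
  cov <- lapply(cfg$covariate_params, function(p) {
    rtrunc_norm(n, p[["mean"]], p[["sd"]], p[["lo"]], p[["hi"]])
  })
  frequency <- ifelse(stats::runif(n) < cfg$p_daily, "daily", "not_daily")
  consequences <- as.numeric(stats::runif(n) < cfg$p_consequences)

  z <- stats::rnorm(n)
  u <- cfg$random_intercept_sd * z
  impair <- 5 + cfg$impairment_severity_link * z + stats::rnorm(n)
  impair <- pmin(pmax(impair, 0), 10)

  complete <- data.frame(
    participant_id = ids, age = age, sex = sex, bmi = cov$bmi,
    tdi = cov$tdi, threshold = cov$threshold,
    duration_months = cov$duration_months,
    parosmia_intensity = cov$parosmia_intensity,
    parosmia_frequency = frequency, parosmia_consequences = consequences,
    parosmia_valence = cov$parosmia_valence,
    subjective_impairment = impair,
    importance_olfaction = cov$importance_olfaction,
    depression_adsl = cov$depression_adsl,
    stringsAsFactors = FALSE
  )

  observed <- complete
  for (v in names(cfg$participant_missing_rates)) {
    r <- cfg$participant_missing_rates[[v]]
    if (r > 0 && v %in% names(observed)) {
      drop <- stats::runif(n) < r
      observed[[v]][drop] <- NA
    }
  }
  observed <- validate_participants(observed)

  true <- list(
    latent = complete, z_severity = z, u = u,
    slopes_qd = cfg$slopes_qd, slopes_ol = cfg$slopes_ol,
    category_intercepts = cfg$category_intercepts
  )
  list(participants = observed, true = true)
}

# 2-SD standardize the generator's latent predictors (constant columns -> 0).
scale_2sd_or_zero <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / (2 * s)
}

# Latent participant predictor matrix on the standardized scale the slope
# maps are expressed in.
latent_design <- function(latent) {
  degree <- compute_parosmia_degree(latent$parosmia_intensity,
                                    latent$parosmia_frequency,
                                    latent$parosmia_consequences)
  x <- cbind(
    age = scale_2sd_or_zero(latent$age),
    bmi = scale_2sd_or_zero(latent$bmi),
    sex = suppressWarnings(effect_code(latent$sex)),
    tdi = scale_2sd_or_zero(latent$tdi),
    duration_months = scale_2sd_or_zero(latent$duration_months),
    parosmia_degree = scale_2sd_or_zero(degree),
    parosmia_intensity = scale_2sd_or_zero(latent$parosmia_intensity),
    parosmia_valence = scale_2sd_or_zero(latent$parosmia_valence),
    subjective_impairment = scale_2sd_or_zero(latent$subjective_impairment),
    importance_olfaction = scale_2sd_or_zero(latent$importance_olfaction)
  )
  x
}

#' Simulate the odor-classification responses
#'
#' For each (participant, descriptor) cell the category is drawn from the
#' three-class softmax of `(0, eta_qd, eta_ol)` where
#' `eta_c = intercept_c + x' beta_c + u_i` over 2-SD-standardized semantic
#' and participant predictors; the drawn label is then replaced by
#' `unknown` with probability `unknown_rate`.
#'
#' @param descriptors descriptor table, ideally from [simulate_semantics()]
#'   (its `"latent"` attribute supplies complete semantic values; otherwise
#'   observed values are mean-filled).
#' @param participants participant table from [simulate_participants()].
#' @param true_params the `true` element of [simulate_participants()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return validated long-format response data frame with attribute `"eta"`
#'   (the realized linear predictor matrices).
#' @export
simulate_responses <- function(descriptors, participants, true_params,
                               config = sim_config(), seed = 1L) {
  cfg <- config
  set.seed(seed)
  n_i <- nrow(participants)
  n_d <- nrow(descriptors)

  sem <- attr(descriptors, "latent")
  if (is.null(sem)) {
    sem <- as.matrix(descriptors[.semantic_vars])
    for (j in seq_len(ncol(sem))) {
      m <- mean(sem[, j], na.rm = TRUE)
      sem[is.na(sem[, j]), j] <- if (is.finite(m)) m else 0
    }
  }
  sem_z <- apply(sem, 2, scale_2sd_or_zero)
  colnames(sem_z) <- .semantic_vars

  x_part <- latent_design(true_params$latent)
  u <- true_params$u

  eta_for <- function(slopes, intercept) {
    sem_part <- as.numeric(sem_z %*% slopes[.semantic_vars])       # by d
    part_part <- as.numeric(x_part %*% slopes[.participant_predictors]) # by i
    outer(part_part + u, sem_part, `+`) + intercept                # i x d
  }
  eta_qd <- eta_for(cfg$slopes_qd, cfg$category_intercepts[["qd"]])
  eta_ol <- eta_for(cfg$slopes_ol, cfg$category_intercepts[["ol"]])

  e_qd <- exp(eta_qd)
  e_ol <- exp(eta_ol)
  denom <- 1 + e_qd + e_ol
  p_norm <- 1 / denom
  p_qd <- e_qd / denom

  r <- matrix(stats::runif(n_i * n_d), n_i, n_d)
  cat_mat <- matrix("odorless", n_i, n_d)
  cat_mat[r < p_norm + p_qd] <- "qualitatively_different"
  cat_mat[r < p_norm] <- "normal"
  if (cfg$unknown_rate > 0) {
    unk <- matrix(stats::runif(n_i * n_d) < cfg$unknown_rate, n_i, n_d)
    cat_mat[unk] <- "unknown"
  }

  responses <- data.frame(
    participant_id = rep(participants$participant_id, times = n_d),
    descriptor_id = rep(descriptors$descriptor_id, each = n_i),
    response = as.vector(cat_mat),
    stringsAsFactors = FALSE
  )
  responses <- validate_responses(responses)
  attr(responses, "eta") <- list(qd = eta_qd, ol = eta_ol)
  responses
}

#' Simulate a complete cohort
#'
#' Composes [simulate_semantics()], [simulate_participants()], and
#' [simulate_responses()] with independent sub-seeds derived from the master
#' seed, so each stage is reproducible on its own.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @return list with `cohort` (a [new_cohort()] object) and `true_params`
#'   (latent covariates, severity factor, random intercepts, linear
#'   predictors, slope maps).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  descriptors <- simulate_semantics(cfg, derive_seed(seed, 1L))
  pp <- simulate_participants(cfg, derive_seed(seed, 2L))
  responses <- simulate_responses(descriptors, pp$participants, pp$true,
                                  cfg, derive_seed(seed, 3L))
  true <- pp$true
  true$eta <- attr(responses, "eta")
  true$latent_semantics <- attr(descriptors, "latent")
  attr(responses, "eta") <- NULL
  cohort <- new_cohort(responses, descriptors, pp$participants)
  list(cohort = cohort, true_params = true)
}
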