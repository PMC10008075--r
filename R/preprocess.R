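# Response coding, parosmia-degree construction, predictor transforms, and
# bootstrap multiple imputation of participant covariates.

#' Code responses into binary indicator matrices
#'
#' Builds two aligned participants x descriptors indicator matrices: `QD`
#' separates qualitatively-different responses from odorless and normal ones,
#' `OL` separates odorless responses from the rest. Unknown responses are
#' treated as missing: `observed_mask` is 1 only where the participant
#' classified the descriptor. Cells never contribute to both indicators.
#'
#' @param x a `parosim_cohort` (preferred: fixes row/column order to first
#'   appearance in the participant/descriptor tables) or a validated
#'   long-format response data frame.
#' @return object of class `parosim_coded`: list with matrices `QD`, `OL`,
#'   `observed_mask`, all with participant/descriptor dimnames.
#' @export
code_responses <- function(x) {
  if (inherits(x, "parosim_cohort")) {
    responses <- x$responses
    pids <- x$participants$participant_id
    dids <- x$descriptors$descriptor_id
  } else {
    responses <- validate_responses(x)
    pids <- unique(responses$participant_id)
    dids <- unique(responses$descriptor_id)
  }
  n_i <- length(pids)
  n_d <- length(dids)
  shape <- function() {
    matrix(0, n_i, n_d, dimnames = list(pids, dids))
  }
  qd <- shape(); ol <- shape(); mask <- shape()
  i <- match(responses$participant_id, pids)
  j <- match(responses$descriptor_id, dids)
  idx <- cbind(i, j)
  resp <- responses$response
  mask[idx[resp != "unknown", , drop = FALSE]] <- 1
  qd[idx[resp == "qualitatively_different", , drop = FALSE]] <- 1
  ol[idx[resp == "odorless", , drop = FALSE]] <- 1
  structure(list(QD = qd, OL = ol, observed_mask = mask),
            class = "parosim_coded")
}

#' Degree of parosmia from its intensity, frequency, and consequences
#'
#' The degree is a weighted sum of parosmia intensity (0-10 VAS), parosmia
#' frequency (daily = 1, not daily = 0), and significant consequences
#' (present = 1). Weights default to (1, 1, 1). A missing component makes
#' the result missing so it can be handled by imputation.
#'
#' @param intensity numeric 0-10.
#' @param frequency `"daily"`/`"not_daily"` or 1/0.
#' @param consequences 0/1 indicator.
#' @param weights length-3 numeric weights.
#' @return numeric vector of degrees (NA where any component is missing).
#' @export
compute_parosmia_degree <- function(intensity, frequency, consequences,
                                    weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3, is.numeric(weights))
  if (is.character(frequency) || is.factor(frequency)) {
    frequency <- as.character(frequency)
    bad <- !is.na(frequency) & !(frequency %in% c("daily", "not_daily"))
    if (any(bad)) {
      abort_validation(sprintf("parosmia_frequency value '%s' unrecognized",
                               frequency[which(bad)[1L]]))
    }
    frequency <- ifelse(is.na(frequency), NA_real_,
                        as.numeric(frequency == "daily"))
  }
  intensity <- as.numeric(intensity)
  consequences <- as.numeric(consequences)
  if (any(!is.na(intensity) & (intensity < 0 | intensity > 10))) {
    abort_validation("parosmia intensity outside [0, 10]")
  }
  weights[1] * intensity + weights[2] * frequency + weights[3] * consequences
}

#' Standardize a predictor by twice its standard deviation
#'
#' Centers at the mean of the non-missing values and divides by two sample
#' standard deviations, so the scaled column has SD 0.5 and a coefficient on
#' it is comparable in size to one on a binary +/-1 predictor.
#'
#' @param x numeric vector with at least two non-missing, non-constant values.
#' @param name column name used in error messages.
#' @return the scaled vector, with attributes `center` and `scale`
#'   (`scale` = 2 * SD) recording the transform.
#' @export
standardize_2sd <- function(x, name = deparse(substitute(x))) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2) {
    stop(sprintf("column '%s': need at least 2 non-missing values", name),
         call. = FALSE)
  }
  s <- stats::sd(obs)
  if (s == 0) {
    stop(sprintf("column '%s' has zero standard deviation", name),
         call. = FALSE)
  }
  out <- (x - mean(obs)) / (2 * s)
  attr(out, "center") <- mean(obs)
  attr(out, "scale") <- 2 * s
  out
}

#' Invert a 2-SD standardization from its transform record
#'
#' @param z output of [standardize_2sd()] (or any numeric vector, if `center`
#'   and `scale` are supplied).
#' @param center,scale transform record; default taken from `z`'s attributes.
#' @return the original-scale vector.
#' @export
unstandardize_2sd <- function(z, center = attr(z, "center"),
                              scale = attr(z, "scale")) {
  if (is.null(center) || is.null(scale)) {
    stop("no transform record: supply center and scale", call. = FALSE)
  }
  as.numeric(z) * scale + center
}

#' Effect-code a two-level sex factor
#'
#' @param sex character/factor vector of `"F"`/`"M"`.
#' @param female_positive if `TRUE` (default) F is +1 and M is -1; flip with
#'   `FALSE`. Only the coefficient's sign depends on the direction.
#' @return numeric +/-1 vector; warns if only one level is present (the
#'   coefficient is then inestimable downstream).
#' @export
effect_code <- function(sex, female_positive = TRUE) {
  sex <- as.character(sex)
  bad <- !is.na(sex) & !(sex %in% c("F", "M"))
  if (any(bad)) {
    abort_validation(sprintf("sex value '%s' is not 'F' or 'M'",
                             sex[which(bad)[1L]]))
  }
  out <- ifelse(is.na(sex), NA_real_, ifelse(sex == "F", 1, -1))
  if (!female_positive) out <- -out
  if (length(unique(stats::na.omit(out))) < 2) {
    warning("sex has a single level; its coefficient is inestimable",
            call. = FALSE)
  }
  out
}

# Spline-expanded design matrix for one imputation model. Knots are fixed
# from the full data so every bootstrap fit and every prediction uses the
# same basis. With spline = FALSE every predictor enters linearly (used when
# the spline basis would have more columns than observed rows).
impute_basis <- function(predictors, spline = TRUE) {
  cols <- list(`(Intercept)` = rep(1, nrow(predictors)))
  for (nm in colnames(predictors)) {
    x <- predictors[, nm]
    ux <- unique(x)
    if (spline && length(ux) >= 6) {
      b <- splines::ns(x, df = 3)
      colnames(b) <- paste0(nm, "_ns", seq_len(ncol(b)))
      for (k in seq_len(ncol(b))) cols[[colnames(b)[k]]] <- b[, k]
    } else if (length(ux) >= 2) {
      cols[[nm]] <- x
    } # constant predictors contribute nothing
  }
  do.call(cbind, cols)
}

#' Bootstrap-regression multiple imputation of participant covariates
#'
#' For each incomplete numeric variable, an additive regression on the other
#' numeric covariates (natural cubic spline basis, 3 df, on continuous
#' predictors) is fitted on `n_boot` bootstrap resamples of the rows observed
#' for that variable; the missing entries are imputed with the mean of the
#' `n_boot` predictions. Observed cells are never modified. Predictor
#' missingness is mean-filled for the purpose of the imputation models only.
#'
#' @param participants participant data frame (as in a `parosim_cohort`).
#' @param n_boot number of bootstrap samples (default 10).
#' @param seed integer seed.
#' @return list with `data` (completed table; `parosmia_frequency` /
#'   `parosmia_consequences` are left as observed) and `report` (data frame
#'   `variable, participant_id, imputed_value, prediction_sd`).
#' @export
impute_missing <- function(participants, n_boot = 10L, seed = 1L) {
  participants <- validate_participants(participants)
  set.seed(seed)
  num_vars <- intersect(.participant_numeric, names(participants))
  x <- as.matrix(participants[num_vars])

  frac_obs <- colMeans(!is.na(x))
  if (any(frac_obs == 0)) {
    stop(sprintf("variable '%s' has no observed values; cannot impute",
                 num_vars[which(frac_obs == 0)[1L]]), call. = FALSE)
  }
  if (any(frac_obs < 0.6)) {
    warning(sprintf(
      "variable '%s' is only %.0f%% observed (below the 60%% the imputation model assumes); imputations may be unstable",
      num_vars[which(frac_obs < 0.6)[1L]],
      100 * min(frac_obs)), call. = FALSE)
  }

  completed <- participants
  report <- list()
  incomplete <- num_vars[colSums(is.na(x)) > 0]

  # mean-filled predictor pool shared by all models
  filled <- x
  for (j in seq_len(ncol(filled))) {
    filled[is.na(filled[, j]), j] <- mean(filled[, j], na.rm = TRUE)
  }

  for (v in incomplete) {
    y <- x[, v]
    miss <- which(is.na(y))
    obs <- which(!is.na(y))
    preds <- filled[, setdiff(num_vars, v), drop = FALSE]
    basis <- tryCatch(impute_basis(preds), error = function(e) NULL)
    if (!is.null(basis) && length(obs) < ncol(basis) + 2L) {
      # spline basis too rich for the observed rows: drop to linear terms
      basis <- tryCatch(impute_basis(preds, spline = FALSE),
                        error = function(e) NULL)
    }

    enough <- !is.null(basis) && length(obs) >= max(10L, ncol(basis) + 2L)
    if (!enough) {
      warning(sprintf(
        "variable '%s': degenerate design, falling back to mean imputation", v
      ), call. = FALSE)
      imput <- rep(mean(y[obs]), length(miss))
      pred_sd <- rep(0, length(miss))
    } else {
      pred_mat <- matrix(NA_real_, length(miss), n_boot)
      for (b in seq_len(n_boot)) {
        idx <- sample(obs, length(obs), replace = TRUE)
        fit <- stats::lm.fit(basis[idx, , drop = FALSE], y[idx])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        pred_mat[, b] <- basis[miss, , drop = FALSE] %*% beta
      }
      imput <- rowMeans(pred_mat)
      pred_sd <- apply(pred_mat, 1, stats::sd)
      # keep imputations inside the variable's declared range
      rng <- .participant_ranges[[v]]
      imput <- pmin(pmax(imput, rng[1]), rng[2])
    }
    completed[[v]][miss] <- imput
    report[[v]] <- data.frame(
      variable = v,
      participant_id = participants$participant_id[miss],
      imputed_value = imput,
      prediction_sd = pred_sd,
      stringsAsFactors = FALSE
    )
  }

  report <- if (length(report)) {
    do.call(rbind, c(report, list(make.row.names = FALSE)))
  } else {
    data.frame(variable = character(0), participant_id = character(0),
               imputed_value = numeric(0), prediction_sd = numeric(0))
  }
  list(data = completed, report = report)
}

#' Build the standardized participant design table
#'
#' Derives the parosmia degree, imputes incomplete numeric covariates
#' ([impute_missing()]), then 2-SD standardizes the continuous predictors
#' and effect-codes sex. The result carries the ten participant predictors
#' used by the response models.
#'
#' @param participants participant data frame.
#' @param n_boot bootstrap samples for imputation.
#' @param seed integer seed for imputation.
#' @param degree_weights weights passed to [compute_parosmia_degree()].
#' @return object of class `parosim_design`: list with `x` (participants x
#'   10 predictor matrix, rownames = participant ids), `transforms` (per
#'   column: center/scale or coding), and `imputation` (the report).
#' @export
build_design <- function(participants, n_boot = 10L, seed = 1L,
                         degree_weights = c(1, 1, 1)) {
  participants <- validate_participants(participants)
  imp <- impute_missing(participants, n_boot = n_boot, seed = seed)
  d <- imp$data
  degree <- compute_parosmia_degree(d$parosmia_intensity,
                                    d$parosmia_frequency,
                                    d$parosmia_consequences,
                                    weights = degree_weights)
  if (anyNA(degree)) {
    # frequency/consequences may still be missing; fill degree from its
    # observed mean (the numeric components were already imputed)
    degree[is.na(degree)] <- mean(degree, na.rm = TRUE)
  }
  cont <- list(
    age = d$age, bmi = d$bmi, tdi = d$tdi,
    duration_months = d$duration_months, parosmia_degree = degree,
    parosmia_intensity = d$parosmia_intensity,
    parosmia_valence = d$parosmia_valence,
    subjective_impairment = d$subjective_impairment,
    importance_olfaction = d$importance_olfaction
  )
  transforms <- list()
  for (nm in names(cont)) {
    z <- standardize_2sd(cont[[nm]], name = nm)
    transforms[[nm]] <- list(type = "standardize_2sd",
                             center = attr(z, "center"),
                             scale = attr(z, "scale"))
    cont[[nm]] <- as.numeric(z)
  }
  sex <- suppressWarnings(effect_code(d$sex))
  transforms$sex <- list(type = "effect_code", positive = "F")

  x <- cbind(
    age = cont$age, bmi = cont$bmi, sex = sex, tdi = cont$tdi,
    duration_months = cont$duration_months,
    parosmia_degree = cont$parosmia_degree,
    parosmia_intensity = cont$parosmia_intensity,
    parosmia_valence = cont$parosmia_valence,
    subjective_impairment = cont$subjective_impairment,
    importance_olfaction = cont$importance_olfaction
  )
  rownames(x) <- d$participant_id
  structure(list(x = x, transforms = transforms, imputation = imp$report),
            class = "parosim_design")
}
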