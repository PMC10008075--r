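# Descriptor-level affectedness statistics, semantic-variable correlations,
# and the random-intercept logistic model suite.

#' Per-descriptor affectedness percentages with normal-approximation CIs
#'
#' For each descriptor, the percentage of observed responses classified as
#' qualitatively different and as odorless, with Wald (normal-approximation)
#' binomial confidence intervals `pct +/- z * 100 * sqrt(p(1-p)/n)`, clipped
#' to `[0, 100]`.
#'
#' @param coded a [code_responses()] object.
#' @param ci_level confidence level (default 0.95).
#' @return data frame with one row per descriptor: `descriptor_id`,
#'   `n_observed`, `n_qd`, `n_ol`, `pct_qd`, `pct_ol`, and CI bounds
#'   `ci_qd_low`, `ci_qd_high`, `ci_ol_low`, `ci_ol_high`. Descriptors with
#'   no observed response get an all-NA row rather than an error.
#' @export
descriptor_percentages <- function(coded, ci_level = 0.95) {
  stopifnot(inherits(coded, "parosim_coded"), ci_level > 0, ci_level < 1)
  n <- colSums(coded$observed_mask)
  k_qd <- colSums(coded$QD)
  k_ol <- colSums(coded$OL)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)

  ci <- function(k, n) {
    p <- k / n
    half <- z * 100 * sqrt(p * (1 - p) / n)
    pct <- 100 * p
    cbind(pct = pct,
          low = pmax(pct - half, 0),
          high = pmin(pct + half, 100))
  }
  qd <- ci(k_qd, n)
  ol <- ci(k_ol, n)
  out <- data.frame(
    descriptor_id = colnames(coded$observed_mask),
    n_observed = as.integer(n),
    n_qd = as.integer(k_qd), n_ol = as.integer(k_ol),
    pct_qd = qd[, "pct"], pct_ol = ol[, "pct"],
    ci_qd_low = qd[, "low"], ci_qd_high = qd[, "high"],
    ci_ol_low = ol[, "low"], ci_ol_high = ol[, "high"],
    stringsAsFactors = FALSE
  )
  empty <- n == 0
  out[empty, c("pct_qd", "pct_ol", "ci_qd_low", "ci_qd_high",
               "ci_ol_low", "ci_ol_high")] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Two-sided p-value for a Pearson correlation
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param r Pearson correlation.
#' @param n number of (pairwise-complete) observations, at least 3.
#' @return two-sided p-value (1 for r = 0; 0 at |r| = 1).
#' @export
r_to_p <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Pearson correlation with pairwise-complete n and t-based p-value
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value in
#'   either are dropped.
#' @return list with `n` (complete pairs), `r`, and two-sided `p`. Zero
#'   variance in either vector (or `n < 3`) yields `r = NA` with a warning.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) {
    warning("fewer than 3 complete pairs; correlation undefined",
            call. = FALSE)
    return(list(n = n, r = NA_real_, p = NA_real_))
  }
  xs <- x[ok] - mean(x[ok])
  ys <- y[ok] - mean(y[ok])
  sx <- sqrt(sum(xs^2))
  sy <- sqrt(sum(ys^2))
  if (sx == 0 || sy == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(list(n = n, r = NA_real_, p = NA_real_))
  }
  r <- sum(xs * ys) / (sx * sy)
  r <- max(min(r, 1), -1)
  list(n = n, r = r, p = r_to_p(r, n))
}

#' Correlations between semantic variables and affectedness percentages
#'
#' One row per semantic variable x target percentage (`pct_qd`, `pct_ol`),
#' using pairwise-complete descriptors (descriptors lacking the semantic
#' rating are dropped for that row only). Significance is starred at
#' p < 0.05; no multiple-testing correction is applied unless requested.
#'
#' @param summary output of [descriptor_percentages()].
#' @param descriptors descriptor table sharing `descriptor_id`.
#' @param adjust optional p-adjustment method (e.g. `"BH"`) applied across
#'   the table; default `"none"`.
#' @return data frame `variable, target, n, r, p, significant`.
#' @export
semantic_correlation_table <- function(summary, descriptors,
                                       adjust = "none") {
  idx <- match(summary$descriptor_id, descriptors$descriptor_id)
  if (anyNA(idx)) {
    stop("summary contains descriptor_ids absent from the descriptor table",
         call. = FALSE)
  }
  desc <- descriptors[idx, , drop = FALSE]
  rows <- list()
  for (v in .semantic_vars) {
    for (target in c("pct_qd", "pct_ol")) {
      cc <- pearson_with_p(desc[[v]], summary[[target]])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, target = target, n = cc$n, r = cc$r, p = cc$p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  rownames(out) <- NULL
  out
}

#' Fit one random-intercept logistic model
#'
#' Flattens a binary indicator matrix over its observed cells into one row
#' per (participant, descriptor) and fits a logistic mixed-effects model with
#' the supplied participant predictors, at most one semantic descriptor
#' variable, and a random participant intercept (Laplace approximation via
#' \pkg{lme4}). Cells whose semantic value is missing are dropped for that
#' model only. Reported per-term statistics are Wald: `z = estimate / SE`,
#' `p` the two-sided normal tail.
#'
#' @param outcome participants x descriptors binary matrix (`QD` or `OL`
#'   from [code_responses()]).
#' @param mask same-shape observed mask.
#' @param design optional [build_design()] object or participant-level
#'   predictor matrix with rownames matching the outcome's.
#' @param semantic optional named numeric vector over descriptors (one
#'   semantic variable); standardized by 2 SDs before fitting.
#' @param semantic_name column label for the semantic term.
#' @return object of class `parosim_glmm`: list with `terms` (data frame
#'   `term, estimate, std_error, z, p`), `ranef_sd`, `converged`,
#'   `n_obs`, `n_participants`, `method`, and `fit` (the merMod).
#' @export
fit_glmm <- function(outcome, mask, design = NULL, semantic = NULL,
                     semantic_name = "semantic") {
  stopifnot(is.matrix(outcome), is.matrix(mask),
            all(dim(outcome) == dim(mask)))
  x <- if (inherits(design, "parosim_design")) design$x else design
  if (!is.null(x)) {
    stopifnot(is.matrix(x), nrow(x) == nrow(outcome))
  }

  keep <- mask == 1
  if (!is.null(semantic)) {
    sem <- semantic[match(colnames(outcome), names(semantic))]
    sem_obs <- !is.na(sem)
    keep <- keep & matrix(rep(sem_obs, each = nrow(outcome)),
                          nrow(outcome), ncol(outcome))
    sem_z <- rep(NA_real_, length(sem))
    sem_z[sem_obs] <- as.numeric(
      standardize_2sd(sem[sem_obs], name = semantic_name)
    )
  }

  idx <- which(keep, arr.ind = TRUE)
  dat <- data.frame(
    y = outcome[keep],
    participant = factor(rownames(outcome)[idx[, 1]],
                         levels = rownames(outcome)),
    stringsAsFactors = FALSE
  )
  fe_terms <- character(0)
  if (!is.null(x)) {
    xx <- x[idx[, 1], , drop = FALSE]
    for (nm in colnames(xx)) dat[[nm]] <- xx[, nm]
    fe_terms <- colnames(xx)
  }
  if (!is.null(semantic)) {
    dat[[semantic_name]] <- sem_z[idx[, 2]]
    fe_terms <- c(fe_terms, semantic_name)
  }
  rhs <- paste(c("1", fe_terms, "(1 | participant)"), collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))

  converged <- TRUE
  messages <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(form, data = dat, family = stats::binomial(),
                  control = lme4::glmerControl(optimizer = "bobyqa")),
      error = function(e) e
    ),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (inherits(fit, "error")) {
    return(structure(list(
      terms = data.frame(term = c("(Intercept)", fe_terms),
                         estimate = NA_real_, std_error = NA_real_,
                         z = NA_real_, p = NA_real_,
                         stringsAsFactors = FALSE),
      ranef_sd = NA_real_, converged = FALSE,
      diagnostics = conditionMessage(fit),
      n_obs = nrow(dat), n_participants = nlevels(droplevels(dat$participant)),
      method = "glmer Laplace", fit = NULL
    ), class = "parosim_glmm"))
  }
  if (length(fit@optinfo$conv$lme4) || length(messages)) converged <- FALSE

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  vc <- lme4::VarCorr(fit)
  structure(list(
    terms = data.frame(term = names(est), estimate = as.numeric(est),
                       std_error = as.numeric(se), z = as.numeric(z),
                       p = as.numeric(p), stringsAsFactors = FALSE),
    ranef_sd = as.numeric(attr(vc$participant, "stddev")),
    converged = converged,
    diagnostics = messages,
    n_obs = nrow(dat),
    n_participants = nlevels(droplevels(dat$participant)),
    method = "glmer Laplace", fit = fit
  ), class = "parosim_glmm")
}

#' @export
print.parosim_glmm <- function(x, ...) {
  cat(sprintf("logistic mixed model (%s), %d obs, %d participants%s\n",
              x$method, x$n_obs, x$n_participants,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("random intercept SD: %.3f\n", x$ranef_sd))
  print(x$terms, digits = 3)
  invisible(x)
}

#' Fit the full model suite for both outcomes
#'
#' Per outcome (qualitatively different, odorless): one baseline model with
#' the ten participant predictors only, plus one model per semantic variable
#' (participant predictors + that variable) — 14 fits for six semantic
#' variables. The assembled table reports participant terms from the
#' baseline model and each semantic term from its own model, mirroring the
#' conventional presentation.
#'
#' @param coded a [code_responses()] object.
#' @param design a [build_design()] object.
#' @param descriptors descriptor table supplying the semantic variables.
#' @return list with `fits` (nested list `[[outcome]][[model]]`) and `table`
#'   (data frame `outcome, group, term, estimate, std_error, z, p,
#'   significant, converged`).
#' @export
semantic_model_suite <- function(coded, design, descriptors) {
  stopifnot(inherits(coded, "parosim_coded"))
  outcomes <- list(qd = coded$QD, ol = coded$OL)
  fits <- list()
  rows <- list()
  for (oc in names(outcomes)) {
    fits[[oc]] <- list()
    base <- fit_glmm(outcomes[[oc]], coded$observed_mask, design)
    fits[[oc]][["baseline"]] <- base
    bt <- base$terms
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = oc, group = "participant", term = bt$term,
      estimate = bt$estimate, std_error = bt$std_error, z = bt$z, p = bt$p,
      converged = base$converged, stringsAsFactors = FALSE
    )
    for (v in .semantic_vars) {
      sem <- stats::setNames(descriptors[[v]], descriptors$descriptor_id)
      m <- fit_glmm(outcomes[[oc]], coded$observed_mask, design,
                    semantic = sem, semantic_name = v)
      fits[[oc]][[v]] <- m
      tr <- m$terms[m$terms$term == v, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, group = "semantic", term = v,
        estimate = tr$estimate, std_error = tr$std_error, z = tr$z, p = tr$p,
        converged = m$converged, stringsAsFactors = FALSE
      )
    }
  }
  table <- do.call(rbind, rows)
  table$significant <- !is.na(table$p) & table$p < 0.05
  rownames(table) <- NULL
  list(fits = fits, table = table)
}
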