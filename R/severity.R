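# The parosmia severity index.
#
# Rationale: odors that are rarely reported as affected should indicate
# severe parosmia when a patient does report them affected — they are the
# ones affected last. Descriptor weights therefore invert how strongly each
# descriptor loads on response-related principal components:
#
#   OLs[p,d] = s[p,d] * cor(s[p,], ol)          (QD analogous)
#   OLw[d]   = sum_p (1 - minmax_p(OLs[p,d])) * v[p]
#   ps[i]    = sum_{d in D_i} (OL[i,d] OLw[d] + QD[i,d] QDw[d])
#              / sum_{d in D_i} max(OLw[d], QDw[d])
#
# where s are PC scores over descriptors, v the variance fractions, ol/qd
# the by-descriptor percentages, and D_i the descriptors participant i
# classified (unknown responses excluded). ps is in [0, 1] by construction.

#' Assemble the descriptor matrix for the severity PCA
#'
#' Columns: the six semantic variables plus the by-descriptor percentages of
#' qualitatively-different and odorless responses.
#'
#' @param descriptors descriptor table.
#' @param summary output of [descriptor_percentages()] on the same cohort.
#' @return numeric matrix (descriptors x 8) with descriptor ids as rownames.
#' @export
descriptor_pca_input <- function(descriptors, summary) {
  idx <- match(descriptors$descriptor_id, summary$descriptor_id)
  if (anyNA(idx)) {
    stop("summary lacks rows for some descriptors", call. = FALSE)
  }
  x <- cbind(as.matrix(descriptors[.semantic_vars]),
             pct_qd = summary$pct_qd[idx],
             pct_ol = summary$pct_ol[idx])
  rownames(x) <- descriptors$descriptor_id
  x
}

#' Principal component analysis of the descriptor variables
#'
#' Columns are z-standardized (unit SD) and the correlation matrix is
#' decomposed; missing cells are mean-imputed for this step only (recorded
#' in the result). Scores are the projections of the standardized rows;
#' variance fractions are computed over ALL components, of which `n_pcs`
#' are retained for the severity weights.
#'
#' @param x descriptor x variable numeric matrix (see
#'   [descriptor_pca_input()]); at least 3 rows, no constant column.
#' @param n_pcs number of components to retain (default 3).
#' @return object of class `parosim_pca`: `loadings` (variable x PC),
#'   `scores` (descriptor x PC), `variance_fraction` (all PCs, sums to 1),
#'   `n_pcs`, `imputed_cells`.
#' @export
run_pca <- function(x, n_pcs = 3L) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 descriptors for PCA", call. = FALSE)
  imputed <- which(is.na(x), arr.ind = TRUE)
  for (j in seq_len(ncol(x))) {
    m <- mean(x[, j], na.rm = TRUE)
    if (!is.finite(m)) {
      stop(sprintf("column '%s' has no observed values", colnames(x)[j]),
           call. = FALSE)
    }
    x[is.na(x[, j]), j] <- m
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant column '%s' cannot be standardized for PCA",
                 colnames(x)[which(sds == 0)[1L]]), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 1 || n_pcs > ncol(pc$x)) {
    stop(sprintf("n_pcs must be in [1, %d]", ncol(pc$x)), call. = FALSE)
  }
  structure(list(
    loadings = pc$rotation,
    scores = pc$x,
    variance_fraction = vf,
    n_pcs = n_pcs,
    center = pc$center, scale = pc$scale,
    imputed_cells = imputed
  ), class = "parosim_pca")
}

#' Correlations of PC scores with the affectedness percentages
#'
#' For each retained component, the Pearson correlation of its descriptor
#' scores with the by-descriptor odorless and qualitatively-different
#' percentages.
#'
#' @param pca a [run_pca()] object.
#' @param summary output of [descriptor_percentages()] with a row for every
#'   scored descriptor.
#' @return object of class `parosim_pc_cor`: list with numeric vectors
#'   `rho_ol` and `rho_qd` of length `n_pcs`.
#' @export
pc_response_correlations <- function(pca, summary) {
  stopifnot(inherits(pca, "parosim_pca"))
  idx <- match(rownames(pca$scores), summary$descriptor_id)
  if (anyNA(idx)) {
    stop("summary lacks rows for some scored descriptors", call. = FALSE)
  }
  ol <- summary$pct_ol[idx]
  qd <- summary$pct_qd[idx]
  if (anyNA(ol) || anyNA(qd)) {
    stop("percentages missing for some descriptors", call. = FALSE)
  }
  if (stats::sd(ol) == 0 || stats::sd(qd) == 0) {
    stop("constant percentage vector: PC-response correlation undefined",
         call. = FALSE)
  }
  p <- seq_len(pca$n_pcs)
  rho_ol <- vapply(p, function(k) pearson_with_p(pca$scores[, k], ol)$r,
                   numeric(1))
  rho_qd <- vapply(p, function(k) pearson_with_p(pca$scores[, k], qd)$r,
                   numeric(1))
  structure(list(rho_ol = rho_ol, rho_qd = rho_qd),
            class = "parosim_pc_cor")
}

#' Descriptor weights from inverted, variance-weighted PC scores
#'
#' Weighted scores `OLs[p,d] = s[p,d] * rho_ol[p]` (`QDs` analogous) are
#' min-max normalized across descriptors within each retained PC, inverted
#' (`1 - normalized`), scaled by the PC's variance fraction, and summed over
#' PCs. A descriptor at the per-PC maximum on every retained PC gets weight
#' 0; one at the minimum gets `sum_p v_p`. A degenerate PC (max = min)
#' contributes `0.5 * v_p` to every descriptor.
#'
#' @param pca a [run_pca()] object.
#' @param rho a [pc_response_correlations()] object.
#' @param normalization `"per_pc"` (default) min-max normalizes each PC's
#'   weighted scores separately; `"global"` uses a single min/max over all
#'   retained PCs.
#' @return object of class `parosim_weights`: data frame `descriptor_id,
#'   olw, qdw` with attribute `intermediates` (the `OLs`/`QDs` matrices,
#'   per-PC min/max, variance fractions used).
#' @export
compute_weights <- function(pca, rho, normalization = c("per_pc", "global")) {
  stopifnot(inherits(pca, "parosim_pca"), inherits(rho, "parosim_pc_cor"))
  normalization <- match.arg(normalization)
  p <- seq_len(pca$n_pcs)
  s <- pca$scores[, p, drop = FALSE]
  v <- pca$variance_fraction[p]

  weight_for <- function(rho_vec) {
    ws <- sweep(s, 2, rho_vec, `*`)  # descriptor x PC weighted scores
    if (normalization == "global") {
      lo <- rep(min(ws), length(p))
      hi <- rep(max(ws), length(p))
    } else {
      lo <- apply(ws, 2, min)
      hi <- apply(ws, 2, max)
    }
    w <- numeric(nrow(ws))
    norm <- matrix(NA_real_, nrow(ws), ncol(ws))
    for (k in seq_along(p)) {
      if (hi[k] > lo[k]) {
        norm[, k] <- (ws[, k] - lo[k]) / (hi[k] - lo[k])
      } else {
        norm[, k] <- 0.5  # neutral contribution for a degenerate PC
        message(sprintf(
          "PC %d has constant weighted scores; contributing 0.5 * v_p", k
        ))
      }
      w <- w + (1 - norm[, k]) * v[k]
    }
    list(w = w, ws = ws, lo = lo, hi = hi, norm = norm)
  }

  ol <- weight_for(rho$rho_ol)
  qd <- weight_for(rho$rho_qd)
  out <- data.frame(
    descriptor_id = rownames(pca$scores),
    olw = ol$w, qdw = qd$w,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "intermediates") <- list(
    OLs = ol$ws, QDs = qd$ws,
    ol_min = ol$lo, ol_max = ol$hi, qd_min = qd$lo, qd_max = qd$hi,
    variance_fraction = v, normalization = normalization
  )
  class(out) <- c("parosim_weights", "data.frame")
  out
}

#' Per-participant parosmia severity scores
#'
#' `ps_i` sums, over the descriptors the participant classified, the weight
#' of each descriptor reported odorless or qualitatively different, and
#' normalizes by the maximum attainable sum `sum max(OLw, QDw)` over the
#' same descriptors, giving a score in `[0, 1]`. Unknown responses do not
#' count as classified.
#'
#' @param coded a [code_responses()] object.
#' @param weights a [compute_weights()] table covering every descriptor in
#'   `coded`.
#' @return data frame `participant_id, ps, n_classified, n_affected`; `ps`
#'   is NA (with a warning) for participants who classified nothing or whose
#'   classified descriptors all have zero weight.
#' @export
severity_scores <- function(coded, weights) {
  stopifnot(inherits(coded, "parosim_coded"))
  dids <- colnames(coded$observed_mask)
  idx <- match(dids, weights$descriptor_id)
  if (anyNA(idx)) {
    stop("weights table lacks descriptors present in the coded responses",
         call. = FALSE)
  }
  olw <- weights$olw[idx]
  qdw <- weights$qdw[idx]
  if (any(olw < 0 | qdw < 0)) stop("weights must be non-negative",
                                   call. = FALSE)
  mx <- pmax(olw, qdw)

  num <- as.numeric(coded$OL %*% olw + coded$QD %*% qdw)
  den <- as.numeric(coded$observed_mask %*% mx)
  n_classified <- as.integer(rowSums(coded$observed_mask))
  n_affected <- as.integer(rowSums(coded$OL + coded$QD))

  ps <- num / den
  none <- n_classified == 0
  zero_den <- !none & den == 0
  if (any(none)) {
    warning(sprintf("%d participant(s) classified no descriptor; ps is NA",
                    sum(none)), call. = FALSE)
  }
  if (any(zero_den)) {
    warning(sprintf(
      "%d participant(s) have all-zero weights over their descriptors; ps is NA",
      sum(zero_den)), call. = FALSE)
  }
  ps[none | zero_den] <- NA_real_
  data.frame(
    participant_id = rownames(coded$observed_mask),
    ps = ps, n_classified = n_classified, n_affected = n_affected,
    stringsAsFactors = FALSE
  )
}

#' Evaluate the severity index against participant variables
#'
#' Pearson correlations (pairwise complete) of `ps` with the percentage of
#' classified odors reported affected, subjective impairment severity,
#' depression score, olfactory-perceptual ability (TDI), detection
#' threshold, and importance of olfaction.
#'
#' @param scores a [severity_scores()] table.
#' @param participants participant table sharing `participant_id`.
#' @return data frame `variable, n, r, p`; rows whose correlation is
#'   undefined (constant vector) carry NA and `defined = FALSE`.
#' @export
evaluate_severity <- function(scores, participants) {
  idx <- match(scores$participant_id, participants$participant_id)
  if (anyNA(idx)) {
    stop("participant table lacks rows for some scored participants",
         call. = FALSE)
  }
  pt <- participants[idx, , drop = FALSE]
  pct_affected <- ifelse(scores$n_classified > 0,
                         100 * scores$n_affected / scores$n_classified,
                         NA_real_)
  vars <- list(
    pct_affected = pct_affected,
    subjective_impairment = pt$subjective_impairment,
    depression_adsl = pt$depression_adsl,
    tdi = pt$tdi,
    threshold = pt$threshold,
    importance_olfaction = pt$importance_olfaction
  )
  rows <- lapply(names(vars), function(nm) {
    cc <- suppressWarnings(pearson_with_p(scores$ps, vars[[nm]]))
    data.frame(variable = nm, n = cc$n, r = cc$r, p = cc$p,
               defined = !is.na(cc$r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' End-to-end parosmia severity pipeline
#'
#' Convenience wrapper: codes the responses, computes descriptor
#' percentages, runs the PCA on semantic variables + percentages, derives
#' the weights, and scores every participant.
#'
#' @param cohort a `parosim_cohort`.
#' @param n_pcs retained principal components (default 3).
#' @param ci_level confidence level for the descriptor percentage CIs.
#' @param normalization passed to [compute_weights()].
#' @return list with `coded`, `summary`, `pca`, `rho`, `weights`, `scores`,
#'   and `evaluation`.
#' @export
parosmia_severity <- function(cohort, n_pcs = 3L, ci_level = 0.95,
                              normalization = "per_pc") {
  stopifnot(inherits(cohort, "parosim_cohort"))
  coded <- code_responses(cohort)
  summary <- descriptor_percentages(coded, ci_level = ci_level)
  x <- descriptor_pca_input(cohort$descriptors, summary)
  pca <- run_pca(x, n_pcs = n_pcs)
  rho <- pc_response_correlations(pca, summary)
  weights <- compute_weights(pca, rho, normalization = normalization)
  scores <- severity_scores(coded, weights)
  evaluation <- evaluate_severity(scores, cohort$participants)
  list(coded = coded, summary = summary, pca = pca, rho = rho,
       weights = weights, scores = scores, evaluation = evaluation)
}
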