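# Shared fixture builders for the test suite.

# Hand-written minimal cohort: 2 participants x 3 descriptors.
small_tables <- function() {
  responses <- data.frame(
    participant_id = rep(c("p1", "p2"), each = 3),
    descriptor_id = rep(c("coffee", "fish", "rose"), times = 2),
    response = c("normal", "qualitatively_different", "odorless",
                 "unknown", "normal", "qualitatively_different"),
    stringsAsFactors = FALSE
  )
  descriptors <- data.frame(
    descriptor_id = c("coffee", "fish", "rose"),
    label = c("coffee", "fish", "rose"),
    oai = c(1.2, 0.8, NA), osi = c(0.5, NA, 0.1),
    valence = c(6.5, 3.2, 8.1), arousal = c(4.4, 3.9, 5.0),
    olfactory = c(4.2, 3.8, 4.5), gustatory = c(4.0, 3.5, 1.2),
    stringsAsFactors = FALSE
  )
  participants <- data.frame(
    participant_id = c("p1", "p2"),
    age = c(34, 58), sex = c("F", "M"), bmi = c(22.5, NA),
    tdi = c(18.25, 27.5), threshold = c(2.5, 6.75),
    duration_months = c(9, 14),
    parosmia_intensity = c(7, 4),
    parosmia_frequency = c("daily", "not_daily"),
    parosmia_consequences = c(1, 0),
    parosmia_valence = c(-3, -1),
    subjective_impairment = c(8, NA),
    importance_olfaction = c(21, 13),
    depression_adsl = c(12, 30),
    stringsAsFactors = FALSE
  )
  list(responses = responses, descriptors = descriptors,
       participants = participants)
}

small_cohort <- function() {
  t <- small_tables()
  new_cohort(t$responses, t$descriptors, t$participants)
}

write_small_cohort_csvs <- function(dir) {
  t <- small_tables()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    responses = file.path(dir, "responses.csv"),
    descriptors = file.path(dir, "descriptors.csv"),
    participants = file.path(dir, "participants.csv")
  )
  write.csv(t$responses, paths$responses, row.names = FALSE, na = "")
  write.csv(t$descriptors, paths$descriptors, row.names = FALSE, na = "")
  write.csv(t$participants, paths$participants, row.names = FALSE, na = "")
  paths
}

# Scale SDs small enough that the clip to the rating scales never triggers
# (> 5 sigma from every bound), for correlation-calibration checks.
narrow_semantic_sds <- function() {
  c(oai = 1, osi = 1, valence = 0.7, arousal = 0.6, olfactory = 0.45,
    gustatory = 0.35)
}

# Fast simulator configuration for property-style loops.
tiny_config <- function(n_participants = 6L, n_descriptors = 5L, ...) {
  sim_config(n_participants = n_participants, n_descriptors = n_descriptors,
             ...)
}

# Random coded-response + weight instance for severity property tests.
random_severity_instance <- function(n_i, n_d, seed) {
  set.seed(seed)
  pids <- sprintf("p%02d", seq_len(n_i))
  dids <- sprintf("d%02d", seq_len(n_d))
  mask <- matrix(rbinom(n_i * n_d, 1, 0.85), n_i, n_d,
                 dimnames = list(pids, dids))
  cat_draw <- matrix(sample(0:2, n_i * n_d, replace = TRUE), n_i, n_d)
  qd <- (cat_draw == 1) * mask
  ol <- (cat_draw == 2) * mask
  coded <- structure(list(QD = qd, OL = ol, observed_mask = mask),
                     class = "parosim_coded")
  weights <- data.frame(
    descriptor_id = dids,
    olw = runif(n_d), qdw = runif(n_d),
    stringsAsFactors = FALSE
  )
  list(coded = coded, weights = weights)
}

# Independent brute-force transcription of the weight and score equations,
# written as plain loops against which the vectorized implementation is
# checked. Inputs are raw scores, correlations, and variance fractions.
brute_weights <- function(scores, rho, v) {
  n_d <- nrow(scores); n_p <- ncol(scores)
  w <- numeric(n_d)
  ws <- matrix(NA_real_, n_d, n_p)
  for (p in seq_len(n_p)) {
    for (d in seq_len(n_d)) ws[d, p] <- scores[d, p] * rho[p]
  }
  for (d in seq_len(n_d)) {
    acc <- 0
    for (p in seq_len(n_p)) {
      lo <- min(ws[, p]); hi <- max(ws[, p])
      norm <- if (hi > lo) (ws[d, p] - lo) / (hi - lo) else 0.5
      acc <- acc + (1 - norm) * v[p]
    }
    w[d] <- acc
  }
  w
}

brute_ps <- function(ol, qd, mask, olw, qdw) {
  n_i <- nrow(ol)
  ps <- numeric(n_i)
  for (i in seq_len(n_i)) {
    num <- 0; den <- 0
    for (d in seq_len(ncol(ol))) {
      if (mask[i, d] == 1) {
        num <- num + ol[i, d] * olw[d] + qd[i, d] * qdw[d]
        den <- den + max(olw[d], qdw[d])
      }
    }
    ps[i] <- if (den > 0) num / den else NA_real_
  }
  ps
}

# Wrap raw score/rho/variance fixtures in the package's classes.
fixture_pca <- function(scores, v) {
  dids <- sprintf("d%02d", seq_len(nrow(scores)))
  rownames(scores) <- dids
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores, loadings = NULL,
                 variance_fraction = v, n_pcs = ncol(scores)),
            class = "parosim_pca")
}
fixture_rho <- function(rho_ol, rho_qd) {
  structure(list(rho_ol = rho_ol, rho_qd = rho_qd),
            class = "parosim_pc_cor")
}
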