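test_that("PCA of two perfectly correlated columns puts all variance on PC1", {
  x <- cbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4) + 1)
  pca <- run_pca(x, n_pcs = 1)
  expect_equal(pca$variance_fraction[1], 1)
})

test_that("the full PC basis reconstructs the input", {
  set.seed(5)
  x <- matrix(rnorm(38 * 8), 38, 8,
              dimnames = list(sprintf("d%02d", 1:38), letters[1:8]))
  pca <- run_pca(x, n_pcs = 8)
  recon <- pca$scores %*% t(pca$loadings)
  recon <- sweep(sweep(recon, 2, pca$scale, `*`), 2, pca$center, `+`)
  expect_equal(unname(recon), unname(x), tolerance = 1e-10)
  # score columns mutually orthogonal
  g <- crossprod(pca$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-12)
})

test_that("variance fractions match a brute-force eigen decomposition", {
  set.seed(9)
  x <- matrix(rnorm(10 * 4), 10, 4)
  pca <- run_pca(x, n_pcs = 2)
  z <- scale(x)  # unit-SD standardization, as the PCA uses
  ev <- eigen(cov(z), symmetric = TRUE)$values
  expect_equal(pca$variance_fraction, ev / sum(ev), tolerance = 1e-10)
})

test_that("PCA rejects degenerate inputs by name", {
  expect_error(run_pca(matrix(1:4, 2, 2)), "at least 3")
  x <- cbind(a = rnorm(5), flat = rep(2, 5))
  expect_error(run_pca(x), "flat")
})

test_that("PC-response correlations match pearson_with_p per column", {
  sim <- simulate_cohort(sim_config(), seed = 14)
  res <- parosmia_severity(sim$cohort)
  for (k in seq_len(res$pca$n_pcs)) {
    idx <- match(rownames(res$pca$scores), res$summary$descriptor_id)
    expect_equal(res$rho$rho_ol[k],
                 pearson_with_p(res$pca$scores[, k],
                                res$summary$pct_ol[idx])$r,
                 tolerance = 1e-12)
  }
  # constant percentage vector is an error
  summ <- res$summary
  summ$pct_ol[] <- 10
  expect_error(pc_response_correlations(res$pca, summ), "constant")
})

test_that("weights equal the brute-force transcription on random fixtures", {
  for (s in 1:10) {
    set.seed(400 + s)
    n_d <- sample(3:8, 1); n_p <- sample(1:4, 1)
    scores <- matrix(rnorm(n_d * n_p, sd = 2), n_d, n_p)
    v <- runif(n_p); v <- v / sum(v) * runif(1, 0.5, 1)
    rho_ol <- runif(n_p, -1, 1); rho_qd <- runif(n_p, -1, 1)
    w <- compute_weights(fixture_pca(scores, v), fixture_rho(rho_ol, rho_qd))
    expect_equal(w$olw, brute_weights(scores, rho_ol, v), tolerance = 1e-12)
    expect_equal(w$qdw, brute_weights(scores, rho_qd, v), tolerance = 1e-12)
  }
})

test_that("extreme-score descriptors get the boundary weights", {
  # descriptor 1 attains the per-PC max of weighted scores on every PC;
  # descriptor 3 the minimum
  scores <- rbind(c(3, 2), c(0, 0), c(-1, -2))
  v <- c(0.6, 0.3)
  w <- compute_weights(fixture_pca(scores, v), fixture_rho(c(1, 1), c(1, 1)))
  expect_equal(w$olw[1], 0)
  expect_equal(w$olw[3], sum(v))
  expect_true(all(w$olw >= 0 & w$olw <= sum(v)))
})

test_that("a degenerate PC contributes a neutral half-weight", {
  scores <- cbind(c(1, 2, 3), c(5, 5, 5))
  v <- c(0.5, 0.4)
  expect_message(
    w <- compute_weights(fixture_pca(scores, v), fixture_rho(c(1, 1), c(1, 1))),
    "constant weighted scores"
  )
  # PC2 contributes 0.5 * 0.4 to every descriptor
  expect_equal(w$olw, (1 - (scores[, 1] - 1) / 2) * 0.5 + 0.2,
               tolerance = 1e-12)
})

test_that("severity scores hit their trivial anchors", {
  w <- data.frame(descriptor_id = c("a", "b"), olw = c(0.4, 0.1),
                  qdw = c(0.2, 0.6), stringsAsFactors = FALSE)
  mk <- function(resp) {
    code_responses(data.frame(
      participant_id = "p1", descriptor_id = c("a", "b"),
      response = resp, stringsAsFactors = FALSE
    ))
  }
  # all normal -> 0
  s <- severity_scores(mk(c("normal", "normal")), w)
  expect_equal(s$ps, 0)
  # argmax-weight category everywhere -> 1 (a: olw wins; b: qdw wins)
  s <- severity_scores(mk(c("odorless", "qualitatively_different")), w)
  expect_equal(s$ps, 1)
  # nothing classified -> NA with warning
  expect_warning(
    s <- severity_scores(mk(c("unknown", "unknown")), w),
    "classified no descriptor"
  )
  expect_true(is.na(s$ps))
})

test_that("severity scores equal a brute-force participant loop", {
  for (s in 1:10) {
    inst <- random_severity_instance(n_i = 4, n_d = 8, seed = 500 + s)
    got <- suppressWarnings(severity_scores(inst$coded, inst$weights))
    want <- brute_ps(inst$coded$OL, inst$coded$QD, inst$coded$observed_mask,
                     inst$weights$olw, inst$weights$qdw)
    expect_equal(got$ps, want, tolerance = 1e-12)
  }
})

test_that("ps is invariant to PC sign flips and to weight rescaling", {
  for (s in 1:25) {
    set.seed(600 + s)
    n_d <- 8; n_p <- 3
    scores <- matrix(rnorm(n_d * n_p), n_d, n_p)
    v <- runif(n_p); v <- v / sum(v + 2)
    rho_ol <- runif(n_p, -1, 1); rho_qd <- runif(n_p, -1, 1)
    w1 <- compute_weights(fixture_pca(scores, v), fixture_rho(rho_ol, rho_qd))

    flip <- sample(n_p, 1)
    scores2 <- scores; scores2[, flip] <- -scores2[, flip]
    rho_ol2 <- rho_ol; rho_ol2[flip] <- -rho_ol2[flip]
    rho_qd2 <- rho_qd; rho_qd2[flip] <- -rho_qd2[flip]
    w2 <- compute_weights(fixture_pca(scores2, v),
                          fixture_rho(rho_ol2, rho_qd2))
    expect_equal(w1$olw, w2$olw, tolerance = 1e-12)
    expect_equal(w1$qdw, w2$qdw, tolerance = 1e-12)

    inst <- random_severity_instance(5, n_d, seed = 700 + s)
    wt <- inst$weights
    s1 <- suppressWarnings(severity_scores(inst$coded, wt))
    wt2 <- wt; c <- runif(1, 0.1, 10)
    wt2$olw <- wt2$olw * c; wt2$qdw <- wt2$qdw * c
    s2 <- suppressWarnings(severity_scores(inst$coded, wt2))
    expect_equal(s1$ps, s2$ps, tolerance = 1e-12)
  }
})

test_that("flipping one normal cell to an affected category never lowers ps", {
  for (s in 1:25) {
    inst <- random_severity_instance(4, 8, seed = 800 + s)
    coded <- inst$coded
    base <- suppressWarnings(severity_scores(coded, inst$weights))
    normal_cells <- which(coded$observed_mask == 1 & coded$QD == 0 &
                          coded$OL == 0, arr.ind = TRUE)
    if (nrow(normal_cells) == 0) next
    cell <- normal_cells[1, , drop = FALSE]
    to_qd <- coded; to_qd$QD[cell] <- 1
    after <- suppressWarnings(severity_scores(to_qd, inst$weights))
    i <- cell[1, 1]
    expect_gte(after$ps[i] - base$ps[i], -1e-12)
    if (inst$weights$qdw[cell[1, 2]] > 0) {
      expect_gt(after$ps[i], base$ps[i])
    }
  }
})

test_that("reordering descriptors or participants permutes outputs identically", {
  sim <- simulate_cohort(sim_config(), seed = 17)
  res <- parosmia_severity(sim$cohort)

  set.seed(99)
  perm_d <- sample(nrow(sim$cohort$descriptors))
  perm_p <- sample(nrow(sim$cohort$participants))
  cohort2 <- new_cohort(sim$cohort$responses,
                        sim$cohort$descriptors[perm_d, ],
                        sim$cohort$participants[perm_p, ])
  res2 <- parosmia_severity(cohort2)

  m1 <- setNames(res$scores$ps, res$scores$participant_id)
  m2 <- setNames(res2$scores$ps, res2$scores$participant_id)
  expect_equal(m2[names(m1)], m1, tolerance = 1e-9)
  w1 <- setNames(res$weights$olw, res$weights$descriptor_id)
  w2 <- setNames(res2$weights$olw, res2$weights$descriptor_id)
  expect_equal(w2[names(w1)], w1, tolerance = 1e-9)
})

test_that("the index tracks its unweighted analog and the severity latent", {
  r_aff <- r_imp <- numeric(20)
  for (s in 1:20) {
    sim <- simulate_cohort(sim_config(), seed = 900 + s)
    res <- suppressWarnings(parosmia_severity(sim$cohort))
    ev <- res$evaluation
    r_aff[s] <- ev$r[ev$variable == "pct_affected"]
    r_imp[s] <- ev$r[ev$variable == "subjective_impairment"]
  }
  expect_true(all(r_aff > 0))
  expect_gte(mean(r_imp > 0), 0.9)
})

test_that("a constant score vector is flagged undefined, not an error", {
  scores <- data.frame(participant_id = sprintf("p%03d", 1:3), ps = 0.5,
                       n_classified = 10L, n_affected = 5L,
                       stringsAsFactors = FALSE)
  pp <- simulate_participants(sim_config(n_participants = 3L), seed = 1)
  ev <- evaluate_severity(scores, pp$participants)
  expect_false(any(ev$defined[ev$variable == "subjective_impairment"]))
  expect_true(all(is.na(ev$r)))
})
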