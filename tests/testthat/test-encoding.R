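test_that("reliability floors reproduce the critical correlations", {
  expect_equal(round(reliability_floor(83), 3), 0.182)
  expect_equal(round(reliability_floor(82), 3), 0.183)
  # oracle: the one-tailed P < 0.05 point found by direct inversion of cor.test
  r_grid <- seq(0.15, 0.22, by = 1e-5)
  p_of_r <- function(r, n) {
    t <- r * sqrt((n - 2) / (1 - r^2))
    1 - pt(t, n - 2)
  }
  oracle83 <- r_grid[which.min(abs(vapply(r_grid, p_of_r, numeric(1),
                                          n = 83) - 0.05))]
  expect_equal(reliability_floor(83), oracle83, tolerance = 1e-4)
})

test_that("the ridge grid holds 81 log-spaced penalties", {
  g <- ridge_lambda_grid()
  expect_length(g, 81)
  expect_equal(g[1], 1e-40)
  expect_equal(g[81], 1e40)
  expect_equal(unique(round(diff(log10(g)), 10)), 1)
})

test_that("Spearman-Brown correction matches direct evaluation", {
  expect_equal(spearman_brown(1, 3), 1)
  expect_equal(spearman_brown(0, 3), 0)
  expect_equal(spearman_brown(0.5, 3), 0.75)
  expect_equal(spearman_brown(0.5, 2), 2 / 3)
  expect_error(spearman_brown(-1, 3), class = "metamerlab_validation_error")
})

test_that("closed-form LOO equals explicit leave-one-out refits", {
  set.seed(19)
  for (rep in 1:4) {
    n <- 8; p <- 3
    x <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    grid <- 10^seq(-4, 4, by = 2)
    fit <- ridge_loo_select(x, y, grid)
    xc <- sweep(x, 2, colMeans(x))
    yc <- y - mean(y)
    for (li in seq_along(grid)) {
      loo <- vapply(seq_len(n), function(i) {
        xi <- xc[-i, , drop = FALSE]; yi <- yc[-i]
        w <- solve(crossprod(xi) + grid[li] * diag(p), crossprod(xi, yi))
        (yc[i] - drop(xc[i, ] %*% w))^2
      }, numeric(1))
      expect_equal(fit$loo_mse[li, 1], mean(loo), tolerance = 1e-8)
    }
  }
})

test_that("lambda selection lands where the signal regime dictates", {
  set.seed(23)
  n <- 40; p <- 6
  x <- matrix(rnorm(n * p), n, p)
  w <- rnorm(p)
  fit_clean <- ridge_loo_select(x, drop(x %*% w))
  expect_lte(fit_clean$lambda, 1e-10)
  xt <- matrix(rnorm(200 * p), 200, p)
  pred <- sweep(xt, 2, fit_clean$x_center) %*% fit_clean$weights +
    fit_clean$intercepts
  expect_gt(cor(drop(pred), drop(xt %*% w))^2, 0.999)
  fit_noise <- ridge_loo_select(x, rnorm(n))
  expect_gte(fit_noise$lambda, 1e6)
  expect_error(ridge_loo_select(x, c(NA, rnorm(n - 1))),
               class = "metamerlab_validation_error")
})

test_that("noiseless voxels give perfect reliabilities and r2* = r2", {
  m <- random_image_model()
  stim <- generate_stimuli("image", 10, seed = 31)
  spec <- voxel_sim_spec("fc_relu", n_voxels = 6, noise_sd = 0,
                         sparsity = 0.3)
  vox <- simulate_voxel_responses(m, stim, spec, seed = 2)
  feats <- list(fc_relu = stage_feature_matrix(m, stim, "fc_relu"))
  res <- corrected_variance_pipeline(feats, vox$responses, n_splits = 3,
                                     seed = 4)
  # with zero scan noise the raw reliabilities are exactly 1 (before floors),
  # so the corrected variance equals the raw r2
  expect_equal(res$detail$r2_star, res$detail$r2 / (res$detail$r_v *
                                                      res$detail$r_vhat))
  expect_equal(res$detail$r_v, rep(1, nrow(res$detail)))
  expect_gt(median(res$summary$median_r2_star), 0.95)
})

test_that("weak reliabilities are floored before the noise-ceiling division", {
  m <- random_image_model()
  stim <- generate_stimuli("image", 10, seed = 32)
  spec <- voxel_sim_spec("fc_relu", n_voxels = 8, noise_sd = 8,
                         sparsity = 0.3)
  vox <- simulate_voxel_responses(m, stim, spec, seed = 3)
  feats <- list(fc_relu = stage_feature_matrix(m, stim, "fc_relu"))
  res <- corrected_variance_pipeline(feats, vox$responses, n_splits = 2,
                                     seed = 5)
  n_tr <- round(40 * 83 / 165)
  expect_true(all(res$detail$r_v >= reliability_floor(n_tr) - 1e-12))
  expect_true(all(res$detail$r_vhat >=
                    reliability_floor(40 - n_tr) - 1e-12))
})

test_that("best-stage selection is cross-validated and masked", {
  scores <- expand.grid(participant = paste0("p", 1:4),
                        stage = c("early", "mid", "late"),
                        stringsAsFactors = FALSE)
  scores$value <- ifelse(scores$stage == "mid", 0.8, 0.3)
  # give p1 a private preference for "late"; it must not affect p1's choice
  scores$value[scores$participant == "p1" & scores$stage == "late"] <- 2
  res <- best_stage_cross_validated(scores)
  expect_equal(res$per_participant$chosen_stage[
    res$per_participant$participant == "p1"], "mid")
  # p1's inflated value drags the others toward "late"
  expect_true(all(res$per_participant$chosen_stage[
    res$per_participant$participant != "p1"] == "late"))
  expect_error(best_stage_cross_validated(scores[scores$participant == "p1", ]),
               class = "metamerlab_validation_error")
})

test_that("RDMs are symmetric, zero-diagonal, and hit the analytic endpoints", {
  set.seed(41)
  x <- matrix(rnorm(50), 10, 5)
  x[2, ] <- x[1, ] * 2          # perfectly correlated patterns
  rdm <- compute_rdm(x, zscore = "none")
  expect_equal(rdm, t(rdm))
  expect_equal(diag(rdm), rep(0, 10))
  expect_equal(rdm[1, 2], 0)
  x[3, ] <- -x[1, ]
  rdm2 <- compute_rdm(x, zscore = "none")
  expect_equal(rdm2[1, 3], 2)
  expect_true(all(rdm2 >= 0 & rdm2 <= 2 + 1e-12))
  xz <- cbind(x, 0)
  expect_warning(compute_rdm(xz), "zero-variance")
})

test_that("RDM similarity recovers the generating stage and a unit ceiling", {
  m <- random_image_model()
  stim <- generate_stimuli("image", 12, seed = 33)
  feats <- list(
    conv1_relu = stage_feature_matrix(m, stim, "conv1_relu"),
    pool2 = stage_feature_matrix(m, stim, "pool2"),
    fc_relu = stage_feature_matrix(m, stim, "fc_relu"))
  # participants whose responses ARE the fc_relu geometry
  parts <- lapply(1:3, function(p) feats$fc_relu)
  res <- suppressWarnings(rdm_similarity_cv(feats, parts, n_splits = 4,
                                            seed = 7))
  expect_true(all(res$per_participant$modal_stage == "fc_relu"))
  expect_gt(res$mean_rho, 0.99)
  expect_gt(res$ceiling, 0.99)
})
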