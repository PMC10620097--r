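test_that("match loss agrees with direct evaluation", {
  expect_equal(match_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(match_loss(c(3, 4), c(0, 0)), 1)
  expect_equal(match_loss(c(1, 0), c(0, 1)), sqrt(2))
  expect_equal(match_loss(c(1, 0), c(0, 1), squared = TRUE), 2)
  # synthetic-denominator mode divides by the candidate's norm
  expect_equal(match_loss(c(0, 0, 2), c(1, 0, 0), "synthetic"), sqrt(5))
  expect_error(match_loss(c(0, 0), c(1, 1)),
               class = "metamerlab_division_error")
})

test_that("eta schedule starts at 1 and halves every decay interval", {
  cfg <- synthesis_config()
  expect_equal(eta_schedule(0, cfg), 1)
  expect_equal(eta_schedule(2999, cfg), 1)
  expect_equal(eta_schedule(3000, cfg), 0.5)
  expect_equal(eta_schedule(23999, cfg), 0.5^7)
  expect_equal(eta_schedule(23999, cfg), 0.0078125)
  expect_error(eta_schedule(24000, cfg), class = "metamerlab_index_error")
})

test_that("constrained step obeys the step-norm rule semantics", {
  s <- signal(array(0.5, c(4, 4, 1)), "image")
  g <- array(rnorm(16), c(4, 4, 1))
  g <- g / sqrt(sum(g^2)) * 2          # ||g|| = 2
  for (rule in c("rescale_always", "clamp_only")) {
    out <- constrained_step(s, g, eta = 1, step_rule = rule)
    expect_equal(sqrt(sum((out$values - s$values)^2)), 1)
  }
  gsmall <- g / 8                      # ||g|| = 0.25
  out_r <- constrained_step(s, gsmall, eta = 1, "rescale_always")
  out_c <- constrained_step(s, gsmall, eta = 1, "clamp_only")
  expect_equal(sqrt(sum((out_r$values - s$values)^2)), 1)
  expect_equal(sqrt(sum((out_c$values - s$values)^2)), 0.25)
  expect_identical(constrained_step(s, 0 * g, 1)$values, s$values)
  expect_error(constrained_step(s, g * NA, 1),
               class = "metamerlab_numeric_error")
})

test_that("initialization has the configured moments and is reproducible", {
  cfg <- synthesis_config(seed = 9)
  img <- init_signal("image", c(100, 100, 100), cfg)
  expect_equal(mean(img$values), 0.5, tolerance = 1e-3)
  expect_equal(sd(img$values), 0.05, tolerance = 1e-3)
  aud <- init_signal("audio", 1e6, cfg)
  expect_equal(mean(aud$values), 0, tolerance = 1e-9)
  expect_equal(sd(aud$values), 1e-7, tolerance = 1e-2)
  expect_identical(init_signal("image", c(8, 8, 1), cfg)$values,
                   init_signal("image", c(8, 8, 1), cfg)$values)
})

test_that("TV regularizer matches a naive double-loop oracle", {
  expect_equal(tv_regularizer(matrix(0.7, 5, 5)), 0)
  expect_equal(tv_regularizer(matrix(c(0, 1), 1, 2)), 1)
  set.seed(3)
  x <- matrix(rnorm(64), 8, 8)
  z <- x - mean(x)
  naive <- 0
  for (i in 1:8) for (j in 1:8) {
    if (j < 8) naive <- naive + (z[i, j + 1] - z[i, j])^2
    if (i < 8) naive <- naive + (z[i + 1, j] - z[i, j])^2
  }
  expect_equal(tv_regularizer(x), naive, tolerance = 1e-10)
  expect_error(tv_regularizer(1:5), class = "metamerlab_validation_error")
})

test_that("alpha-norm regularizer matches direct evaluation", {
  expect_equal(alpha_norm_regularizer(rep(2, 10)), 0)
  expect_equal(alpha_norm_regularizer(c(2, 0), alpha = 6), 2^(1 / 6))
  expect_equal(alpha_norm_regularizer(c(3, -3), alpha = 2), sqrt(18))
  expect_error(alpha_norm_regularizer(1:3, alpha = 0.5),
               class = "metamerlab_validation_error")
})

test_that("regularizer gradients match finite differences", {
  set.seed(8)
  x <- matrix(rnorm(36), 6, 6)
  gtv <- metamerlab:::tv_gradient(x)
  ga <- metamerlab:::alpha_norm_gradient(x, 6)
  for (i in sample(36, 4)) {
    e <- 1e-6
    xp <- x; xp[i] <- xp[i] + e
    xm <- x; xm[i] <- xm[i] - e
    expect_equal(gtv[i], (tv_regularizer(xp) - tv_regularizer(xm)) / (2 * e),
                 tolerance = 1e-4)
    expect_equal(ga[i],
                 (alpha_norm_regularizer(xp, 6) -
                    alpha_norm_regularizer(xm, 6)) / (2 * e),
                 tolerance = 1e-4)
  }
})

test_that("regularized objective reduces to match loss with zero coefficients", {
  cfg <- synthesis_config()
  a <- rnorm(10); b <- rnorm(10)
  x <- matrix(rnorm(16), 4, 4)
  expect_identical(regularized_objective(a, b, x, cfg), match_loss(a, b))
  reg <- synthesis_config(regularized = TRUE)
  expect_equal(reg$lambda_alpha, 0.005)
  expect_equal(reg$eta_init, 16)
  expect_true(reg$clip_to_range)
  tiers <- vapply(1:3, function(t)
    synthesis_config(regularized = TRUE, tv_tier = t)$lambda_tv, numeric(1))
  expect_equal(tiers / tiers[1], c(1, 10, 100))
})

test_that("synthesis trace obeys the schedule and the step-norm bound", {
  m <- trained_image_model()
  ref <- image_stimuli()$signals[[3]]
  cfg <- synthesis_config(total_steps = 160L, decay_interval = 40L, seed = 4)
  # record per-step movement by re-running the update rule from the trace
  cand <- synthesize_metamer(m, "conv1_relu", ref, cfg)
  expect_equal(nrow(cand$trace), 160L)
  expect_equal(cand$trace$eta,
               cfg$eta_init * cfg$decay_factor^(cand$trace$step %/% 40L))
  # monotone trend: trailing-quarter mean loss below leading-quarter mean
  expect_lt(mean(tail(cand$trace$loss, 40)), mean(head(cand$trace$loss, 40)))
})

test_that("initializing at the reference is a fixed point of the loss", {
  m <- trained_image_model()
  ref <- image_stimuli()$signals[[1]]
  cand <- synthesize_metamer(m, "conv1_relu", ref,
                             synthesis_config(total_steps = 2L, seed = 1),
                             init = ref)
  expect_equal(cand$trace$loss[1], 0)
})

test_that("early-stage metamers converge to the reference", {
  m <- trained_image_model()
  ref <- image_stimuli()$signals[[5]]
  cand <- synthesize_metamer(m, "conv1_relu", ref,
                             synthesis_config(total_steps = 500L,
                                              decay_interval = 62L, seed = 6))
  expect_lt(tail(cand$trace$loss, 1), 0.05)
  expect_gt(cor(as.vector(cand$signal$values), as.vector(ref$values)), 0.95)
})

test_that("final-stage metamers keep the label while diverging in signal space", {
  m <- trained_image_model()
  ref <- image_stimuli()$signals[[7]]
  cand <- synthesize_metamer(m, "logits", ref,
                             synthesis_config(total_steps = 500L,
                                              decay_interval = 62L, seed = 6))
  expect_identical(predict_label(m, cand$signal), predict_label(m, ref))
  expect_lt(abs(cor(as.vector(cand$signal$values), as.vector(ref$values))),
            0.5)
})
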