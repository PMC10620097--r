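test_that("forward activations are deterministic and stage-validated", {
  m <- random_image_model()
  s <- image_stimuli()$signals[[1]]
  a1 <- forward_activations(m, s, "conv2_relu")
  a2 <- forward_activations(m, s, "conv2_relu")
  expect_identical(a1, a2)
  expect_error(forward_activations(m, s, "nope"),
               class = "metamerlab_stage_error")
  bad <- s
  bad$values[1] <- NA
  expect_error(forward_activations(m, bad, "conv1_relu"),
               class = "metamerlab_validation_error")
})

test_that("a linear staged model reproduces the hand-multiplied matrices", {
  m <- linear_toy_model()
  x <- c(0.3, -1, 2)
  a1 <- forward_activations(m, signal(array(x, c(3, 1, 1)), "image"), "lin1")
  w1 <- matrix(c(1, 2, -1, 0.5, 0, 1), 3, 2)
  expect_equal(as.vector(a1), drop(x %*% w1) + c(0.1, -0.2))
  a2 <- forward_activations(m, signal(array(x, c(3, 1, 1)), "image"), "lin2")
  w2 <- matrix(c(1, -1, 2, 0.5), 2, 2)
  expect_equal(as.vector(a2), drop((drop(x %*% w1) + c(0.1, -0.2)) %*% w2))
})

test_that("toy models are reproducible from the seed", {
  m1 <- make_toy_model("image", 4, "random_weights", seed = 42)
  m2 <- make_toy_model("image", 4, "random_weights", seed = 42)
  expect_identical(m1, m2)
  expect_error(make_toy_model("image", 1), class = "metamerlab_validation_error")
})

test_that("briefly trained models beat 80% held-out accuracy; random weights sit near chance", {
  test_set <- generate_stimuli("image", 20, seed = 999)
  expect_gt(model_accuracy(trained_image_model(), test_set), 0.8)
  acc_rand <- model_accuracy(random_image_model(), test_set)
  expect_lt(abs(acc_rand - 0.25), 0.2)
  audio_test <- generate_stimuli("audio", 10, seed = 998)
  expect_gt(model_accuracy(trained_audio_model(), audio_test), 0.8)
})

test_that("stimulus sets are class-balanced, in range, and seed-reproducible", {
  s1 <- generate_stimuli("image", 5, seed = 3)
  s2 <- generate_stimuli("image", 5, seed = 3)
  expect_identical(s1, s2)
  expect_equal(unname(table(s1$labels)), rep(5L, 4), ignore_attr = TRUE)
  rng <- range(vapply(s1$signals, function(x) range(x$values), numeric(2)))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
  expect_error(generate_stimuli("image", 2, classes = character(0)),
               class = "metamerlab_validation_error")
})

test_that("filterbank: silence maps to zeros and tones peak at their channel", {
  n <- 4000
  silence <- signal(numeric(n), "audio")
  out <- filterbank_frontend(silence)
  expect_true(all(out == 0))
  cfs <- attr(out, "center_frequencies")
  for (ch in c(8, 16, 24)) {
    tone <- signal(0.1 * sin(2 * pi * cfs[ch] * seq_len(n) / 20000), "audio")
    energy <- colSums(filterbank_frontend(tone)^2)
    expect_equal(which.max(energy), ch)
  }
  expect_error(filterbank_frontend(signal(rnorm(100), "audio",
                                          sample_rate = 44100)),
               class = "metamerlab_validation_error")
})

test_that("filterbank output equals a naive per-channel filtering oracle", {
  set.seed(41)
  n <- 600
  x <- rnorm(n, sd = 0.1)
  out <- filterbank_frontend(signal(x, "audio"), n_channels = 4)
  fb <- metamerlab:::design_filterbank(4, 20000)
  naive_conv <- function(x, h) {
    l <- length(h); half <- (l - 1) %/% 2
    xp <- c(numeric(half), x, numeric(half))
    vapply(seq_along(x), function(i) sum(xp[i:(i + l - 1)] * rev(h)),
           numeric(1))
  }
  for (ch in 1:4) {
    band <- naive_conv(x, fb$filters[, ch])
    env <- naive_conv(abs(band), rep(1 / 51, 51))
    nd <- n %/% 50
    envd <- vapply(seq_len(nd), function(b)
      mean(env[((b - 1) * 50 + 1):(b * 50)]), numeric(1))
    expect_equal(out[, ch], ifelse(envd > 0, envd^0.3, 0), tolerance = 1e-6)
  }
})

test_that("input gradients match central finite differences (property)", {
  m <- random_image_model()
  x <- image_stimuli()$signals[[2]]$values
  for (stage in c("conv1_relu", "pool2", "logits")) {
    fw <- metamerlab:::model_forward(m, signal(x, "image"), stage = stage,
                                     keep_cache = TRUE)
    d <- dim(fw$act)
    w <- array(rnorm(length(fw$act)), if (is.null(d)) length(fw$act) else d)
    g <- metamerlab:::model_backward_input(m, fw$stage_index, w, fw$caches)
    set.seed(7)
    for (i in sample(length(x), 4)) {
      e <- 1e-5
      vp <- x; vp[i] <- vp[i] + e
      vm <- x; vm[i] <- vm[i] - e
      f <- function(v) sum(metamerlab:::model_forward(
        m, signal(v, "image"), stage = stage)$act * w)
      expect_equal(as.vector(g)[i], (f(vp) - f(vm)) / (2 * e),
                   tolerance = 1e-5)
    }
  }
})

test_that("matching stage activations pins down all downstream computation", {
  # cut-point property: two inputs with equal stage-s activations yield equal
  # later-stage activations and classifier decisions
  m <- trained_image_model()
  ref <- image_stimuli()$signals[[1]]
  cand <- synthesize_metamer(m, "pool1", ref,
                             synthesis_config(total_steps = 400L,
                                              decay_interval = 50L, seed = 2))
  a_ref <- forward_activations(m, ref, "pool1")
  a_cand <- forward_activations(m, cand$signal, "pool1")
  rel <- sqrt(sum((a_ref - a_cand)^2)) / sqrt(sum(a_ref^2))
  down_ref <- forward_activations(m, ref, "logits")
  down_cand <- forward_activations(m, cand$signal, "logits")
  rel_down <- sqrt(sum((down_ref - down_cand)^2)) / sqrt(sum(down_ref^2))
  expect_lt(rel_down, 100 * rel + 1e-8)
  expect_identical(predict_label(m, cand$signal), predict_label(m, ref))
})
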