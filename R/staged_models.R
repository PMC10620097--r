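# Staged differentiable models: the contract every downstream operation
# (synthesis, criteria, transfer, encoding) builds on, plus a toy-model zoo
# and parametric stimulus sets so the full pipeline is testable end to end.

#' Construct a signal
#'
#' Wraps a numeric array as an input signal. Images are height x width x
#' channel arrays with values in \[0, 1\] before model preprocessing; audio is
#' a mono waveform vector with unitless amplitude.
#'
#' @param values Numeric array (image) or numeric vector (audio).
#' @param modality `"image"` or `"audio"`.
#' @param sample_rate Sampling rate in Hz (audio only). Default 20000.
#' @return An object of class `metamer_signal`.
#' @export
signal <- function(values, modality = c("image", "audio"), sample_rate = 20000) {
  modality <- match.arg(modality)
  if (modality == "image") {
    if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
    if (length(dim(values)) != 3L)
      stopf("image signal must be an H x W x C array",
            class = "metamerlab_validation_error")
    check_finite(values, "image signal")
  } else {
    values <- as.numeric(values)
    if (length(values) == 0L)
      stopf("audio signal must have positive length",
            class = "metamerlab_validation_error")
    check_finite(values, "audio signal")
  }
  structure(list(values = values, modality = modality,
                 sample_rate = if (modality == "audio") sample_rate else NULL),
            class = "metamer_signal")
}

as_signal <- function(x, modality, sample_rate = 20000) {
  if (inherits(x, "metamer_signal")) x else signal(x, modality, sample_rate)
}

#' @export
print.metamer_signal <- function(x, ...) {
  if (x$modality == "image") {
    cat(sprintf("<image signal %s>\n", paste(dim(x$values), collapse = "x")))
  } else {
    cat(sprintf("<audio signal %d samples @ %g Hz>\n",
                length(x$values), x$sample_rate))
  }
  invisible(x)
}

#' Stage names of a staged model
#'
#' @param model A `staged_model`.
#' @return Character vector of stage names, in computation order. Every name is
#'   a cut point: the model output depends on the input only through that
#'   stage's activations.
#' @export
stage_names <- function(model) {
  vapply(model$stages, `[[`, character(1), "name")
}

model_check_signal <- function(model, sig) {
  sig <- as_signal(sig, model$modality, model$sample_rate %||% 20000)
  if (sig$modality != model$modality)
    stopf("signal modality '%s' does not match model modality '%s'",
          sig$modality, model$modality, class = "metamerlab_validation_error")
  if (model$modality == "audio" && !is.null(model$sample_rate) &&
      !is.null(sig$sample_rate) && sig$sample_rate != model$sample_rate)
    stopf("signal sample rate %g does not match model rate %g",
          sig$sample_rate, model$sample_rate,
          class = "metamerlab_validation_error")
  check_finite(sig$values, "signal")
  sig
}

# Forward pass. Returns activations at `stage` (or all stages), with per-layer
# caches when keep_cache = TRUE so gradients can be propagated back to the input.
model_forward <- function(model, sig, stage = NULL, keep_cache = FALSE,
                          all_stages = is.null(stage)) {
  sig <- model_check_signal(model, sig)
  names <- stage_names(model)
  if (!is.null(stage) && !stage %in% names)
    stopf("unknown stage '%s' (stages: %s)", stage,
          paste(names, collapse = ", "), class = "metamerlab_stage_error")
  x <- sig$values
  caches <- list()
  acts <- list()
  for (si in seq_along(model$stages)) {
    st <- model$stages[[si]]
    stage_cache <- list()
    for (li in seq_along(st$layers)) {
      fw <- layer_forward(st$layers[[li]], x)
      x <- fw$out
      if (keep_cache) stage_cache[[li]] <- fw$cache
    }
    if (keep_cache) caches[[si]] <- stage_cache
    if (all_stages) acts[[st$name]] <- x
    if (!is.null(stage) && st$name == stage) {
      return(list(act = x, stage_index = si, caches = caches, acts = acts))
    }
  }
  list(act = x, stage_index = length(model$stages), caches = caches, acts = acts)
}

#' Activations of a model stage
#'
#' Runs the model forward and returns the activations at the named stage, with
#' all model preprocessing (e.g. channel normalization) applied inside the
#' differentiable graph. Deterministic: the same input always yields identical
#' activations.
#'
#' @param model A `staged_model`.
#' @param sig Input [signal()] (or a bare array/vector coerced to one).
#' @param stage Stage name; must be one of [stage_names()].
#' @return Numeric array of activations with attribute `stage_name`.
#' @export
forward_activations <- function(model, sig, stage) {
  out <- model_forward(model, sig, stage = stage)$act
  attr(out, "stage_name") <- stage
  out
}

# Backpropagate a gradient at `stage` activations to the input signal.
# relu_override: treat the final rectifier of the matched stage as identity
# (used during metamer synthesis only; all other rectifiers keep their usual
# zero gradient for negative inputs).
model_backward_input <- function(model, stage_index, dact, caches,
                                 relu_override = FALSE) {
  g <- dact
  for (si in seq(stage_index, 1L)) {
    layers <- model$stages[[si]]$layers
    for (li in seq(length(layers), 1L)) {
      last_of_matched <- (si == stage_index && li == length(layers))
      g <- layer_backward(layers[[li]], g, caches[[si]][[li]],
                          identity_relu = relu_override && last_of_matched &&
                            layers[[li]]$type == "relu")
    }
  }
  g
}

# Classifier decision: argmax over the final-stage activations.
#' Predict the class label of a signal
#'
#' @param model A `staged_model` with a classifier head (`classifier_labels`).
#' @param sig Input signal.
#' @return The predicted label (character scalar).
#' @export
predict_label <- function(model, sig) {
  if (is.null(model$classifier_labels))
    stopf("model has no classifier head", class = "metamerlab_config_error")
  logits <- model_forward(model, sig)$act
  model$classifier_labels[which.max(logits)]
}

# ---- toy model zoo ----------------------------------------------------------

toy_image_classes <- c("disk", "square", "cross", "stripes",
                       "rings", "checker", "hbars", "diag")
toy_audio_classes <- c("tone", "chirp", "am_noise", "click_train",
                       "noise_burst", "fm_tone")

rand_weights <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Build a toy staged model
#'
#' Constructs a small convolutional staged model for images (16 x 16 inputs)
#' or audio (4000-sample waveforms at 20 kHz passed through a fixed filterbank
#' front end). Stages are post-nonlinearity cut points; the final stage is a
#' linear classifier. The `briefly_trained` variant is trained by SGD on a
#' matching synthetic stimulus set until it reaches high held-out accuracy;
#' `random_weights` leaves the weights at their random initialization.
#'
#' @param modality `"image"` or `"audio"`.
#' @param n_classes Number of classes (>= 2; at most 8 for images, 6 for audio).
#' @param variant `"random_weights"` or `"briefly_trained"`.
#' @param seed Integer seed; the model is reproducible from it.
#' @param n_train Training examples per class for the briefly_trained variant.
#' @return A `staged_model`.
#' @export
make_toy_model <- function(modality = c("image", "audio"), n_classes = 4,
                           variant = c("random_weights", "briefly_trained"),
                           seed = 1, n_train = 40) {
  modality <- match.arg(modality)
  variant <- match.arg(variant)
  if (n_classes < 2) stopf("n_classes must be >= 2",
                           class = "metamerlab_validation_error")
  vocab <- if (modality == "image") toy_image_classes else toy_audio_classes
  if (n_classes > length(vocab))
    stopf("at most %d %s classes are available", length(vocab), modality,
          class = "metamerlab_validation_error")
  labels <- vocab[seq_len(n_classes)]

  model <- with_seed(seed, {
    if (modality == "image") toy_image_arch(labels) else toy_audio_arch(labels)
  })
  model$seed <- as.integer(seed)
  model$variant <- variant
  if (variant == "briefly_trained") {
    train <- generate_stimuli(modality, n_per_class = n_train, classes = labels,
                              seed = child_seed(seed, 101))
    model <- train_toy_model(model, train, seed = child_seed(seed, 202))
  }
  model
}

toy_image_arch <- function(labels) {
  n_classes <- length(labels)
  st <- list(
    list(name = "norm", layers = list(
      list(type = "normalize", mean = 0.5, sd = 0.25))),
    list(name = "conv1_relu", layers = list(
      list(type = "conv2d", kh = 3L, kw = 3L, cin = 1L, cout = 8L,
           w = rand_weights(c(3, 3, 1, 8), 9), b = numeric(8)),
      list(type = "relu"))),
    list(name = "pool1", layers = list(list(type = "avgpool2"))),
    list(name = "conv2_relu", layers = list(
      list(type = "conv2d", kh = 3L, kw = 3L, cin = 8L, cout = 16L,
           w = rand_weights(c(3, 3, 8, 16), 72), b = numeric(16)),
      list(type = "relu"))),
    list(name = "pool2", layers = list(list(type = "avgpool2"),
                                       list(type = "flatten"))),
    list(name = "fc_relu", layers = list(
      list(type = "dense", w = matrix(stats::rnorm(256 * 32, sd = sqrt(2 / 256)),
                                      256, 32), b = numeric(32)),
      list(type = "relu"))),
    list(name = "logits", layers = list(
      list(type = "dense", w = matrix(stats::rnorm(32 * n_classes,
                                                   sd = sqrt(1 / 32)),
                                      32, n_classes), b = numeric(n_classes))))
  )
  structure(list(stages = st, modality = "image", input_shape = c(16L, 16L, 1L),
                 preprocessing = "grayscale (x - 0.5) / 0.25 inside the graph",
                 classifier_labels = labels),
            class = "staged_model")
}

toy_audio_arch <- function(labels, sample_rate = 20000, n_samples = 4000L,
                           n_channels = 32L) {
  n_classes <- length(labels)
  fb <- design_filterbank(n_channels, sample_rate)
  dec <- 50L
  nd <- n_samples %/% dec          # 80 time frames
  flat_dim <- (nd %/% 4L) * (n_channels %/% 4L) * 16L
  st <- list(
    list(name = "cochleagram", layers = list(
      list(type = "fir_bank", filters = fb$filters, centers = fb$centers,
           env_width = 51L, decimation = dec, compression = 0.3, eps = 1e-8))),
    list(name = "conv1_relu", layers = list(
      list(type = "as_image"),
      list(type = "conv2d", kh = 3L, kw = 3L, cin = 1L, cout = 8L,
           w = rand_weights(c(3, 3, 1, 8), 9), b = numeric(8)),
      list(type = "relu"))),
    list(name = "pool1", layers = list(list(type = "avgpool2"))),
    list(name = "conv2_relu", layers = list(
      list(type = "conv2d", kh = 3L, kw = 3L, cin = 8L, cout = 16L,
           w = rand_weights(c(3, 3, 8, 16), 72), b = numeric(16)),
      list(type = "relu"))),
    list(name = "pool2", layers = list(list(type = "avgpool2"),
                                       list(type = "flatten"))),
    list(name = "fc_relu", layers = list(
      list(type = "dense",
           w = matrix(stats::rnorm(flat_dim * 32, sd = sqrt(2 / flat_dim)),
                      flat_dim, 32), b = numeric(32)),
      list(type = "relu"))),
    list(name = "logits", layers = list(
      list(type = "dense", w = matrix(stats::rnorm(32 * n_classes,
                                                   sd = sqrt(1 / 32)),
                                      32, n_classes), b = numeric(n_classes))))
  )
  structure(list(stages = st, modality = "audio",
                 input_shape = n_samples, sample_rate = sample_rate,
                 preprocessing = "fixed filterbank cochleagram front end",
                 classifier_labels = labels),
            class = "staged_model")
}

#' @export
print.staged_model <- function(x, ...) {
  cat(sprintf("<staged_model: %s, %d stages (%s), %s>\n", x$modality,
              length(x$stages), paste(stage_names(x), collapse = " -> "),
              x$variant %||% "untrained"))
  invisible(x)
}

# ---- training ---------------------------------------------------------------

# Plain SGD with momentum on softmax cross-entropy. For audio models the fixed
# cochleagram front end is precomputed once per stimulus and only the stages
# after `from_stage` are trained.
train_toy_model <- function(model, stimuli, seed = 1, epochs = 30, lr = 0.05,
                            momentum = 0.9, batch = 8L, target_acc = 0.9) {
  labels <- model$classifier_labels
  from_stage <- if (model$modality == "audio") 2L else 1L
  inputs <- lapply(stimuli$signals, function(s) {
    if (from_stage == 1L) s$values
    else model_forward(model, s, stage = "cochleagram")$act
  })
  y <- match(stimuli$labels, labels)
  n <- length(inputs)
  vel <- list()
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = batch)) {
        idx <- ord[b0:min(b0 + batch - 1L, n)]
        grads <- NULL
        for (i in idx) {
          fb <- forward_from(model, inputs[[i]], from_stage)
          p <- softmax(fb$act)
          dlogits <- p
          dlogits[y[i]] <- dlogits[y[i]] - 1
          g <- backward_params(model, from_stage, dlogits, fb$caches)
          grads <- if (is.null(grads)) g else add_grads(grads, g)
        }
        model <- sgd_update(model, grads, lr / length(idx), momentum)
      }
      acc <- mean(vapply(seq_len(n), function(i) {
        which.max(forward_from(model, inputs[[i]], from_stage)$act) == y[i]
      }, logical(1)))
      if (acc >= target_acc) break
    }
  })
  attr(model, "sgd_velocity") <- NULL
  model
}

forward_from <- function(model, x, from_stage) {
  caches <- vector("list", length(model$stages))
  for (si in seq(from_stage, length(model$stages))) {
    st <- model$stages[[si]]
    stage_cache <- list()
    for (li in seq_along(st$layers)) {
      fw <- layer_forward(st$layers[[li]], x)
      x <- fw$out
      stage_cache[[li]] <- fw$cache
    }
    caches[[si]] <- stage_cache
  }
  list(act = x, caches = caches)
}

backward_params <- function(model, from_stage, dout, caches) {
  grads <- list()
  g <- dout
  for (si in seq(length(model$stages), from_stage)) {
    layers <- model$stages[[si]]$layers
    for (li in seq(length(layers), 1L)) {
      ly <- layers[[li]]
      if (has_params(ly)) {
        grads[[paste(si, li, sep = ".")]] <-
          layer_grad_params(ly, g, caches[[si]][[li]])
      }
      if (!(si == from_stage && li == 1L)) {
        g <- layer_backward(ly, g, caches[[si]][[li]])
      }
    }
  }
  grads
}

add_grads <- function(a, b) {
  for (k in names(b)) {
    a[[k]]$w <- a[[k]]$w + b[[k]]$w
    a[[k]]$b <- a[[k]]$b + b[[k]]$b
  }
  a
}

sgd_update <- function(model, grads, lr, momentum) {
  vel <- attr(model, "sgd_velocity") %||% list()
  for (k in names(grads)) {
    ij <- as.integer(strsplit(k, ".", fixed = TRUE)[[1]])
    ly <- model$stages[[ij[1]]]$layers[[ij[2]]]
    v <- vel[[k]] %||% list(w = 0 * ly$w, b = 0 * ly$b)
    v$w <- momentum * v$w - lr * grads[[k]]$w
    v$b <- momentum * v$b - lr * grads[[k]]$b
    ly$w <- ly$w + v$w
    ly$b <- ly$b + v$b
    model$stages[[ij[1]]]$layers[[ij[2]]] <- ly
    vel[[k]] <- v
  }
  attr(model, "sgd_velocity") <- vel
  model
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# ---- synthetic stimulus sets ------------------------------------------------

#' Generate a parametric stimulus set
#'
#' Images are 16 x 16 grayscale parametric shapes (disk, square, cross,
#' stripes, ...) with positional jitter and additive noise, clipped to
#' \[0, 1\]. Audio stimuli are 0.2-s tokens at 20 kHz (pure tones, chirps,
#' AM noise, click trains, ...) with parameter jitter and a low noise floor.
#' Class-balanced and exactly reproducible from the seed.
#'
#' @param modality `"image"` or `"audio"`.
#' @param n_per_class Stimuli per class (>= 1).
#' @param classes Class names; defaults to the toy vocabulary for the modality.
#' @param seed Integer seed.
#' @return A `stimulus_set`: list with `signals`, `labels`, `seed`.
#' @export
generate_stimuli <- function(modality = c("image", "audio"), n_per_class = 10,
                             classes = NULL, seed = 1) {
  modality <- match.arg(modality)
  if (is.null(classes))
    classes <- if (modality == "image") toy_image_classes[1:4] else
      toy_audio_classes[1:3]
  if (length(classes) == 0L)
    stopf("class list must be non-empty", class = "metamerlab_validation_error")
  if (n_per_class < 1) stopf("n_per_class must be >= 1",
                             class = "metamerlab_validation_error")
  signals <- list()
  labels <- character(0)
  with_seed(seed, {
    for (cl in classes) {
      for (i in seq_len(n_per_class)) {
        s <- if (modality == "image") draw_image_token(cl) else
          draw_audio_token(cl)
        signals[[length(signals) + 1L]] <- s
        labels <- c(labels, cl)
      }
    }
  })
  structure(list(signals = signals, labels = labels, seed = as.integer(seed),
                 modality = modality),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set: %d %s stimuli, %d classes>\n",
              length(x$signals), x$modality, length(unique(x$labels))))
  invisible(x)
}

draw_image_token <- function(class, size = 16L) {
  bg <- 0.15; fg <- 0.85
  img <- matrix(bg, size, size)
  cx <- size / 2 + stats::runif(1, -2, 2)
  cy <- size / 2 + stats::runif(1, -2, 2)
  xs <- matrix(seq_len(size), size, size)
  ys <- matrix(seq_len(size), size, size, byrow = TRUE)
  r <- sqrt((xs - cx)^2 + (ys - cy)^2)
  mask <- switch(class,
    disk = r <= 4.5,
    square = abs(xs - cx) <= 3.5 & abs(ys - cy) <= 3.5,
    cross = (abs(xs - cx) <= 1.5 & abs(ys - cy) <= 5) |
            (abs(ys - cy) <= 1.5 & abs(xs - cx) <= 5),
    stripes = ((ys + round(stats::runif(1, 0, 3))) %% 4) < 2,
    rings = r <= 6 & r >= 3.5,
    checker = ((xs %/% 2 + ys %/% 2) %% 2) == 0,
    hbars = ((xs + round(stats::runif(1, 0, 3))) %% 4) < 2,
    diag = (((xs + ys) + round(stats::runif(1, 0, 3))) %% 6) < 3,
    stopf("unknown image class '%s'", class,
          class = "metamerlab_validation_error")
  )
  img[mask] <- fg
  img <- img + matrix(stats::rnorm(size^2, sd = 0.08), size, size)
  img <- pmin(pmax(img, 0), 1)
  signal(array(img, c(size, size, 1L)), "image")
}

draw_audio_token <- function(class, n = 4000L, sr = 20000) {
  t <- seq_len(n) / sr
  amp <- 0.1
  x <- switch(class,
    tone = amp * sin(2 * pi * stats::runif(1, 400, 700) * t),
    chirp = {
      f0 <- stats::runif(1, 250, 350); f1 <- stats::runif(1, 2500, 3500)
      amp * sin(2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * max(t))))
    },
    am_noise = amp * stats::rnorm(n) *
      (1 + sin(2 * pi * stats::runif(1, 30, 50) * t)) / 2,
    click_train = {
      period <- round(stats::runif(1, 400, 600))
      x0 <- numeric(n)
      x0[seq(round(stats::runif(1, 1, period)), n, by = period)] <- 1
      3 * amp * x0
    },
    noise_burst = {
      env <- exp(-((t - stats::runif(1, 0.05, 0.15)) / 0.02)^2)
      amp * stats::rnorm(n) * env
    },
    fm_tone = amp * sin(2 * pi * 800 * t +
                          4 * sin(2 * pi * stats::runif(1, 8, 15) * t)),
    stopf("unknown audio class '%s'", class,
          class = "metamerlab_validation_error")
  )
  x <- x + stats::rnorm(n, sd = 0.002)
  signal(x, "audio", sample_rate = sr)
}

#' Simplified auditory filterbank front end
#'
#' Maps a mono waveform to a time x frequency "cochleagram": a fixed bank of
#' windowed-sinc bandpass filters, envelope extraction (rectification and
#' smoothing), temporal downsampling, and a compressive power nonlinearity
#' (exponent 0.3). The operation is differentiable and deterministic; it is
#' also the first stage of the toy audio models.
#'
#' @param sig Audio [signal()].
#' @param n_channels Number of filterbank channels (default 32).
#' @param sample_rate Expected sample rate (default 20000 Hz).
#' @return Time x frequency matrix of compressed envelopes, with attribute
#'   `center_frequencies`.
#' @export
filterbank_frontend <- function(sig, n_channels = 32L, sample_rate = 20000) {
  sig <- as_signal(sig, "audio", sample_rate)
  if (sig$modality != "audio")
    stopf("filterbank front end requires audio input",
          class = "metamerlab_validation_error")
  if (!is.null(sig$sample_rate) && sig$sample_rate != sample_rate)
    stopf("sample rate %g does not match configured rate %g",
          sig$sample_rate, sample_rate, class = "metamerlab_validation_error")
  fb <- design_filterbank(n_channels, sample_rate)
  layer <- list(type = "fir_bank", filters = fb$filters, centers = fb$centers,
                env_width = 51L, decimation = 50L, compression = 0.3,
                eps = 1e-8)
  out <- layer_forward(layer, sig$values)$out
  attr(out, "center_frequencies") <- fb$centers
  out
}

#' Held-out accuracy of a model on a stimulus set
#'
#' @param model A `staged_model` with a classifier head.
#' @param stimuli A `stimulus_set`.
#' @return Proportion of stimuli whose predicted label matches the true label.
#' @export
model_accuracy <- function(model, stimuli) {
  pred <- vapply(stimuli$signals, function(s) predict_label(model, s),
                 character(1))
  mean(pred == stimuli$labels)
}
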