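# Metamer synthesis: constrained gradient descent on the input signal to match
# the activations of a chosen model stage.

#' Synthesis configuration
#'
#' Collects the knobs of the metamer optimization. The defaults implement the
#' standard recipe: 24,000 steps, step-norm bound eta initialized at 1 and
#' halved every 3,000 steps, image initialization N(0.5, 0.05), audio
#' initialization N(0, 1e-7), identity gradient through the matched stage's
#' rectifier, and no regularization. `regularized = TRUE` switches to the
#' regularized preset: alpha-norm (alpha = 6, lambda 0.005) and total-variation
#' regularizers on the model-normalized signal, 16x initial step size, and
#' clipping of images to \[0, 1\] after each step.
#'
#' @param total_steps Number of gradient steps (default 24000).
#' @param eta_init Initial step-norm bound eta (default 1).
#' @param decay_factor Multiplier applied to eta every `decay_interval` steps
#'   (default 0.5).
#' @param decay_interval Steps between eta drops (default 3000).
#' @param init_mean,init_std Initialization moments; per-modality defaults
#'   (image 0.5 / 0.05, audio 0 / 1e-7) are used when `NULL`.
#' @param step_rule `"rescale_always"` (every step has L2 norm exactly eta) or
#'   `"clamp_only"` (the raw gradient step is only shrunk when it exceeds eta).
#' @param relu_override Propagate gradients through the matched stage's final
#'   rectifier as identity during synthesis (default TRUE).
#' @param clip_to_range Clip image values to \[0, 1\] after each step.
#' @param lambda_tv Total-variation coefficient (default 0; regularized preset
#'   uses 5e-6 scaled by `tv_tier` in 1x/10x/100x steps).
#' @param tv_tier TV coefficient tier (1, 2 or 3 meaning 1x/10x/100x).
#' @param lambda_alpha Alpha-norm coefficient (default 0; 0.005 when enabled).
#' @param alpha Norm order for the alpha-norm regularizer (default 6).
#' @param denominator_mode `"reference"` (loss denominator is the reference
#'   activations) or `"synthetic"` (the candidate's activations, as in the
#'   regularized objective).
#' @param squared_loss Use the squared norm ratio instead of the un-squared one.
#' @param regularized Convenience switch for the regularized preset.
#' @param seed Integer seed for the initialization.
#' @return A `synthesis_config` list.
#' @export
synthesis_config <- function(total_steps = 24000L, eta_init = 1,
                             decay_factor = 0.5, decay_interval = 3000L,
                             init_mean = NULL, init_std = NULL,
                             step_rule = c("rescale_always", "clamp_only"),
                             relu_override = TRUE, clip_to_range = FALSE,
                             lambda_tv = 0, tv_tier = 1L, lambda_alpha = 0,
                             alpha = 6, denominator_mode = c("reference",
                                                             "synthetic"),
                             squared_loss = FALSE, regularized = FALSE,
                             seed = 1L) {
  step_rule <- match.arg(step_rule)
  denominator_mode <- match.arg(denominator_mode)
  if (total_steps <= 0) stopf("total_steps must be > 0",
                              class = "metamerlab_validation_error")
  if (decay_interval <= 0) stopf("decay_interval must be > 0",
                                 class = "metamerlab_validation_error")
  if (decay_factor <= 0 || decay_factor > 1)
    stopf("decay_factor must be in (0, 1]",
          class = "metamerlab_validation_error")
  if (alpha < 1) stopf("alpha must be >= 1",
                       class = "metamerlab_validation_error")
  cfg <- list(total_steps = as.integer(total_steps), eta_init = eta_init,
              decay_factor = decay_factor,
              decay_interval = as.integer(decay_interval),
              init_mean = init_mean, init_std = init_std,
              step_rule = step_rule, relu_override = relu_override,
              clip_to_range = clip_to_range, lambda_tv = lambda_tv,
              tv_tier = as.integer(tv_tier), lambda_alpha = lambda_alpha,
              alpha = alpha, denominator_mode = denominator_mode,
              squared_loss = squared_loss, seed = as.integer(seed))
  if (regularized) {
    cfg$lambda_alpha <- 0.005
    cfg$lambda_tv <- 5e-6 * 10^(cfg$tv_tier - 1L)
    cfg$eta_init <- 16 * eta_init
    cfg$clip_to_range <- TRUE
    cfg$denominator_mode <- "synthetic"
  }
  structure(cfg, class = "synthesis_config")
}

#' Normalized activation-match loss
#'
#' The Euclidean norm of the difference between reference and synthetic
#' activations divided by the Euclidean norm of the denominator array
#' (the reference activations by default, the synthetic ones in
#' `"synthetic"` mode).
#'
#' @param reference_acts,synth_acts Activation arrays of identical shape.
#' @param denominator_mode `"reference"` or `"synthetic"`.
#' @param squared Square the ratio (the un-squared ratio is the default).
#' @return Scalar loss.
#' @export
match_loss <- function(reference_acts, synth_acts,
                       denominator_mode = c("reference", "synthetic"),
                       squared = FALSE) {
  denominator_mode <- match.arg(denominator_mode)
  if (length(reference_acts) != length(synth_acts))
    stopf("activation arrays must have the same shape",
          class = "metamerlab_validation_error")
  den_arr <- if (denominator_mode == "reference") reference_acts else synth_acts
  den <- sqrt(sum(den_arr^2))
  if (den == 0) stopf("denominator activations have zero norm",
                      class = "metamerlab_division_error")
  r <- sqrt(sum((reference_acts - synth_acts)^2)) / den
  if (squared) r^2 else r
}

#' Step-size schedule
#'
#' eta(step) = eta_init * decay_factor^floor(step / decay_interval).
#' With the defaults, eta starts at 1 and is halved after every 3,000 steps.
#'
#' @param step Zero-based step index (0 <= step < total_steps).
#' @param config A [synthesis_config()].
#' @return The step-norm bound at `step`.
#' @export
eta_schedule <- function(step, config) {
  if (any(step < 0 | step >= config$total_steps))
    stopf("step out of range [0, %d)", config$total_steps,
          class = "metamerlab_index_error")
  config$eta_init * config$decay_factor^(step %/% config$decay_interval)
}

#' Norm-constrained descent step
#'
#' Applies the update Delta = -g scaled so its L2 norm is exactly `eta`
#' (`rescale_always`) or at most `eta` (`clamp_only`, which leaves gradients
#' whose norm is already below the bound untouched). A zero gradient leaves the
#' signal unchanged.
#'
#' @param sig Input [signal()].
#' @param gradient Gradient array of the same shape as the signal values.
#' @param eta Step-norm bound.
#' @param step_rule `"rescale_always"` or `"clamp_only"`.
#' @param clip_to_range Clip to \[0, 1\] after the step (images).
#' @return The updated signal.
#' @export
constrained_step <- function(sig, gradient, eta,
                             step_rule = c("rescale_always", "clamp_only"),
                             clip_to_range = FALSE) {
  step_rule <- match.arg(step_rule)
  if (!all(is.finite(gradient)))
    stopf("non-finite gradient", class = "metamerlab_numeric_error")
  if (length(gradient) != length(sig$values))
    stopf("gradient shape must equal signal shape",
          class = "metamerlab_validation_error")
  gnorm <- sqrt(sum(gradient^2))
  scale <- if (gnorm == 0) 0
           else if (step_rule == "rescale_always") eta / gnorm
           else min(1, eta / gnorm)
  v <- sig$values - scale * gradient
  if (clip_to_range) v <- pmin(pmax(v, 0), 1)
  sig$values <- v
  sig
}

#' Initialize the synthesis signal
#'
#' I.i.d. normal draws with the configured moments: mean 0.5, sd 0.05 for
#' images; mean 0, sd 1e-7 for audio (overridable through the config).
#'
#' @param modality `"image"` or `"audio"`.
#' @param shape Image dimensions (H, W, C) or audio length.
#' @param config A [synthesis_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return A [signal()].
#' @export
init_signal <- function(modality = c("image", "audio"), shape, config,
                        seed = config$seed) {
  modality <- match.arg(modality)
  mu <- config$init_mean %||% if (modality == "image") 0.5 else 0
  sdv <- config$init_std %||% if (modality == "image") 0.05 else 1e-7
  vals <- with_seed(seed, stats::rnorm(prod(shape), mean = mu, sd = sdv))
  if (modality == "image") signal(array(vals, shape), "image")
  else signal(vals, "audio")
}

#' Total-variation regularizer
#'
#' Sum over in-bounds neighbor pairs of squared horizontal and vertical
#' differences of the mean-subtracted image, summed over channels. Boundary
#' terms whose neighbor falls outside the image are omitted.
#'
#' @param signal_normalized 2-D matrix or H x W x C array (the model-normalized
#'   signal).
#' @return Scalar regularizer value.
#' @export
tv_regularizer <- function(signal_normalized) {
  x <- signal_normalized
  if (is.null(dim(x)))
    stopf("TV regularizer requires a 2-D (or per-channel 2-D) input",
          class = "metamerlab_validation_error")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  z <- x - mean(x)
  total <- 0
  for (c in seq_len(dim(z)[3])) {
    zc <- array(z[, , c], dim(z)[1:2])
    total <- total + sum((zc[, -1, drop = FALSE] -
                          zc[, -ncol(zc), drop = FALSE])^2) +
                     sum((zc[-1, , drop = FALSE] -
                          zc[-nrow(zc), , drop = FALSE])^2)
  }
  total
}

tv_gradient <- function(signal_normalized) {
  x <- signal_normalized
  had2d <- length(dim(x)) == 2L
  if (had2d) dim(x) <- c(dim(x), 1L)
  z <- x - mean(x)
  g <- array(0, dim(z))
  for (c in seq_len(dim(z)[3])) {
    zc <- array(z[, , c], dim(z)[1:2])
    dh <- zc[, -1, drop = FALSE] - zc[, -ncol(zc), drop = FALSE]
    dv <- zc[-1, , drop = FALSE] - zc[-nrow(zc), , drop = FALSE]
    gc <- matrix(0, nrow(zc), ncol(zc))
    gc[, -1] <- gc[, -1] + 2 * dh
    gc[, -ncol(zc)] <- gc[, -ncol(zc)] - 2 * dh
    gc[-1, ] <- gc[-1, ] + 2 * dv
    gc[-nrow(zc), ] <- gc[-nrow(zc), ] - 2 * dv
    g[, , c] <- gc
  }
  # TV depends only on differences, so the mean-subtraction Jacobian term
  # vanishes (the gradient already sums to zero)
  if (had2d) dim(g) <- dim(g)[1:2]
  g
}

#' Alpha-norm regularizer
#'
#' The alpha-norm (default alpha = 6) of the mean-subtracted, flattened signal.
#'
#' @param signal_normalized Numeric array (the model-normalized signal).
#' @param alpha Norm order, >= 1 (default 6).
#' @return Scalar regularizer value.
#' @export
alpha_norm_regularizer <- function(signal_normalized, alpha = 6) {
  if (alpha < 1) stopf("alpha must be >= 1",
                       class = "metamerlab_validation_error")
  z <- as.vector(signal_normalized) - mean(signal_normalized)
  sum(abs(z)^alpha)^(1 / alpha)
}

alpha_norm_gradient <- function(signal_normalized, alpha = 6) {
  z <- as.vector(signal_normalized) - mean(signal_normalized)
  r <- sum(abs(z)^alpha)^(1 / alpha)
  if (r == 0) return(array(0, dim(signal_normalized) %||%
                               length(signal_normalized)))
  gz <- sign(z) * abs(z)^(alpha - 1) * r^(1 - alpha)
  gz <- gz - mean(gz)      # chain rule through the mean subtraction
  array(gz, dim(signal_normalized) %||% length(signal_normalized))
}

#' Regularized synthesis objective
#'
#' match_loss plus `lambda_alpha` times the alpha-norm regularizer and
#' `lambda_tv` times the TV regularizer, both evaluated on the
#' model-normalized signal. With both coefficients zero this equals
#' [match_loss()] exactly.
#'
#' @param reference_acts,synth_acts Activation arrays of identical shape.
#' @param signal_normalized The model-normalized input signal.
#' @param config A [synthesis_config()].
#' @return Scalar objective value.
#' @export
regularized_objective <- function(reference_acts, synth_acts,
                                  signal_normalized, config) {
  if (config$lambda_tv < 0 || config$lambda_alpha < 0)
    stopf("regularizer coefficients must be >= 0",
          class = "metamerlab_validation_error")
  obj <- match_loss(reference_acts, synth_acts, config$denominator_mode,
                    squared = config$squared_loss)
  if (config$lambda_alpha > 0)
    obj <- obj + config$lambda_alpha *
      alpha_norm_regularizer(signal_normalized, config$alpha)
  if (config$lambda_tv > 0)
    obj <- obj + config$lambda_tv * tv_regularizer(signal_normalized)
  obj
}

# Gradient of the (possibly squared) norm-ratio loss with respect to the
# synthetic activations.
match_loss_gradient <- function(reference_acts, synth_acts, denominator_mode,
                                squared = FALSE) {
  diff <- synth_acts - reference_acts
  nd <- sqrt(sum(diff^2))
  if (denominator_mode == "reference") {
    den <- sqrt(sum(reference_acts^2))
    if (squared) return(2 * diff / den^2)
    if (nd == 0) return(array(0, dim(diff) %||% length(diff)))
    diff / (nd * den)
  } else {
    den <- sqrt(sum(synth_acts^2))
    if (squared) {
      return(2 * diff / den^2 - 2 * nd^2 * synth_acts / den^4)
    }
    if (nd == 0) return(array(0, dim(diff) %||% length(diff)))
    diff / (nd * den) - nd * synth_acts / den^3
  }
}

#' Synthesize a model metamer
#'
#' Runs `total_steps` norm-constrained gradient-descent updates on the input
#' signal, starting from the configured random initialization, to minimize the
#' normalized activation difference to the reference at `stage` (plus optional
#' regularizers). Model weights stay fixed. When `relu_override` is set and the
#' matched stage ends in a rectifier, that rectifier propagates gradients as
#' identity during the synthesis (all other rectifiers are unchanged).
#'
#' @param model A `staged_model`.
#' @param stage Stage name to match.
#' @param reference Reference [signal()].
#' @param config A [synthesis_config()].
#' @param init Optional starting signal (overrides the random initialization,
#'   e.g. to start at the reference itself).
#' @return A `metamer_candidate`: list with `signal`, `reference`, `stage`,
#'   and `trace` (data frame of per-step loss and eta).
#' @export
synthesize_metamer <- function(model, stage, reference, config =
                                 synthesis_config(), init = NULL) {
  reference <- model_check_signal(model, reference)
  ref_fw <- model_forward(model, reference, stage = stage)
  ref_act <- ref_fw$act
  x <- init %||% init_signal(model$modality,
                             if (model$modality == "image")
                               dim(reference$values)
                             else length(reference$values),
                             config)
  x <- model_check_signal(model, x)
  norm_layer <- find_normalize_layer(model)
  losses <- numeric(config$total_steps)
  etas <- numeric(config$total_steps)
  use_reg <- config$lambda_tv > 0 || config$lambda_alpha > 0
  for (t in seq_len(config$total_steps) - 1L) {
    fw <- model_forward(model, x, stage = stage, keep_cache = TRUE)
    xn <- if (use_reg) normalized_signal(x, norm_layer) else NULL
    loss <- if (use_reg)
      regularized_objective(ref_act, fw$act, xn, config)
    else match_loss(ref_act, fw$act, config$denominator_mode,
                    squared = config$squared_loss)
    if (!is.finite(loss)) {
      stop(structure(class = c("metamerlab_synthesis_failure", "error",
                               "condition"),
                     list(message = sprintf(
                       "synthesis diverged at step %d", t),
                       call = sys.call(-1),
                       trace = data.frame(step = seq_len(t) - 1L,
                                          loss = losses[seq_len(t)],
                                          eta = etas[seq_len(t)]))))
    }
    dact <- match_loss_gradient(ref_act, fw$act, config$denominator_mode,
                                squared = config$squared_loss)
    g <- model_backward_input(model, fw$stage_index, dact, fw$caches,
                              relu_override = config$relu_override)
    if (use_reg) {
      gn <- 0
      if (config$lambda_alpha > 0)
        gn <- gn + config$lambda_alpha *
          alpha_norm_gradient(xn, config$alpha)
      if (config$lambda_tv > 0)
        gn <- gn + config$lambda_tv * tv_gradient(xn)
      # regularizers act on the normalized signal; chain through the affine map
      g <- g + gn / (norm_layer$sd %||% 1)
    }
    eta <- eta_schedule(t, config)
    losses[t + 1L] <- loss
    etas[t + 1L] <- eta
    x <- constrained_step(x, g, eta, config$step_rule,
                          clip_to_range = config$clip_to_range &&
                            model$modality == "image")
  }
  structure(list(signal = x, reference = reference, stage = stage,
                 trace = data.frame(step = seq_len(config$total_steps) - 1L,
                                    loss = losses, eta = etas),
                 config = config),
            class = "metamer_candidate")
}

#' @export
print.metamer_candidate <- function(x, ...) {
  cat(sprintf("<metamer_candidate: stage %s, %d steps, final loss %.4g>\n",
              x$stage, nrow(x$trace), x$trace$loss[nrow(x$trace)]))
  invisible(x)
}

find_normalize_layer <- function(model) {
  for (st in model$stages) for (ly in st$layers)
    if (ly$type == "normalize") return(ly)
  NULL
}

normalized_signal <- function(sig, norm_layer) {
  if (is.null(norm_layer)) return(sig$values)
  layer_forward(norm_layer, sig$values)$out
}
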