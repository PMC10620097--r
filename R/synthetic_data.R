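# Ground-truth generators for behavioral and neural fixtures: simulated
# observers with controllable accuracy/confusion structure, and voxel
# responses built as a noisy linear readout of a known model stage.

#' Observer specification
#'
#' @param p_by_condition Named vector of per-condition probabilities correct.
#' @param classes Class vocabulary.
#' @param kernel Optional row-stochastic confusion kernel over wrong classes
#'   (class x class, zero diagonal, rows summing to 1). Default: uniform over
#'   wrong classes.
#' @param n_participants Number of simulated participants.
#' @param sigma_item Item-difficulty spread on the logit scale (>= 0).
#' @param observer_type `"human"` or `"model"`.
#' @return An `observer_spec` list.
#' @export
observer_spec <- function(p_by_condition, classes, kernel = NULL,
                          n_participants = 10, sigma_item = 0,
                          observer_type = "human") {
  k <- length(classes)
  if (is.null(kernel)) {
    kernel <- matrix(1 / (k - 1), k, k,
                     dimnames = list(classes, classes))
    diag(kernel) <- 0
  }
  if (!all(dim(kernel) == k) || any(diag(kernel) != 0) ||
      any(abs(rowSums(kernel) - 1) > 1e-8) || any(kernel < 0))
    stopf("kernel must be row-stochastic over wrong classes with zero diagonal",
          class = "metamerlab_validation_error")
  if (any(p_by_condition < 0 | p_by_condition > 1))
    stopf("accuracies must lie in [0, 1]",
          class = "metamerlab_validation_error")
  if (sigma_item < 0) stopf("sigma_item must be >= 0",
                            class = "metamerlab_validation_error")
  structure(list(p_by_condition = p_by_condition, classes = classes,
                 kernel = kernel, n_participants = as.integer(n_participants),
                 sigma_item = sigma_item, observer_type = observer_type),
            class = "observer_spec")
}

#' Simulate observer response tables
#'
#' Every participant responds once to every stimulus in every condition. A
#' trial is correct with probability `plogis(qlogis(p_c) + item_effect)`,
#' where item effects are Gaussian on the logit scale with sd `sigma_item`
#' (shared across participants and conditions, giving stimuli stable
#' difficulties); errors are drawn from the confusion kernel row of the true
#' class. Exactly reproducible from the seed.
#'
#' @param spec An [observer_spec()].
#' @param stimuli Either a `stimulus_set` or a data frame with `stimulus_id`
#'   and `true_class`.
#' @param conditions Conditions to simulate (default: names of
#'   `spec$p_by_condition`).
#' @param seed Integer seed.
#' @return A response table data frame (see [as_response_table()]).
#' @export
simulate_observers <- function(spec, stimuli,
                               conditions = names(spec$p_by_condition),
                               seed = 1) {
  if (inherits(stimuli, "stimulus_set")) {
    stim <- data.frame(stimulus_id = sprintf("stim%03d",
                                             seq_along(stimuli$labels)),
                       true_class = stimuli$labels, stringsAsFactors = FALSE)
  } else stim <- stimuli
  if (!all(stim$true_class %in% spec$classes))
    stopf("stimulus classes not in the observer vocabulary",
          class = "metamerlab_validation_error")
  with_seed(seed, {
    item_eff <- stats::rnorm(nrow(stim), sd = spec$sigma_item)
    rows <- list()
    for (pid in seq_len(spec$n_participants)) {
      for (cond in conditions) {
        p_c <- spec$p_by_condition[[cond]]
        p_trial <- stats::plogis(stats::qlogis(
          pmin(pmax(p_c, 1e-9), 1 - 1e-9)) + item_eff)
        correct <- stats::runif(nrow(stim)) < p_trial
        resp <- stim$true_class
        for (i in which(!correct)) {
          resp[i] <- sample(spec$classes, 1,
                            prob = spec$kernel[stim$true_class[i], ])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = sprintf("%s%02d", substr(spec$observer_type, 1, 1),
                                   pid),
          observer_type = spec$observer_type, condition = cond,
          stimulus_id = stim$stimulus_id, true_class = stim$true_class,
          response_class = resp, stringsAsFactors = FALSE)
      }
    }
    as_response_table(do.call(rbind, rows))
  })
}

#' Voxel simulation specification
#'
#' @param stage Generating model stage.
#' @param n_voxels Number of voxels.
#' @param sparsity Fraction of features with nonzero weight per voxel.
#' @param noise_sd Per-scan noise standard deviation (signals are scaled to
#'   unit variance across stimuli, so the expected inter-scan correlation is
#'   `1 / (1 + noise_sd^2)`).
#' @param n_scans Number of scans (default 3).
#' @return A `voxel_sim_spec` list.
#' @export
voxel_sim_spec <- function(stage, n_voxels = 30, sparsity = 0.1,
                           noise_sd = 0.5, n_scans = 3) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0",
                          class = "metamerlab_validation_error")
  if (sparsity <= 0 || sparsity > 1)
    stopf("sparsity must be in (0, 1]", class = "metamerlab_validation_error")
  structure(list(stage = stage, n_voxels = as.integer(n_voxels),
                 sparsity = sparsity, noise_sd = noise_sd,
                 n_scans = as.integer(n_scans)),
            class = "voxel_sim_spec")
}

#' Time-averaged stage features for a stimulus set
#'
#' Activations at `stage` for every stimulus, averaged over the time axis when
#' one exists (audio stages), then flattened to a stimulus x feature matrix.
#'
#' @param model A `staged_model`.
#' @param stimuli A `stimulus_set`.
#' @param stage Stage name.
#' @return stimulus x feature matrix.
#' @export
stage_feature_matrix <- function(model, stimuli, stage) {
  rows <- lapply(stimuli$signals, function(s) {
    a <- model_forward(model, s, stage = stage)$act
    if (model$modality == "audio" && length(dim(a)) >= 2L) {
      # first axis of audio activations is time
      a <- apply(a, seq_along(dim(a))[-1], mean)
    }
    as.vector(a)
  })
  do.call(rbind, rows)
}

#' Simulate voxel responses as a noisy readout of a model stage
#'
#' Each voxel is a sparse nonnegative linear combination of the generating
#' stage's time-averaged features, scaled to unit variance across stimuli,
#' plus i.i.d. Gaussian noise drawn independently per scan. The generating
#' weights are retained for parameter-recovery tests.
#'
#' @param model A `staged_model`.
#' @param stimuli A `stimulus_set`.
#' @param spec A [voxel_sim_spec()].
#' @param seed Integer seed.
#' @return List with `responses` (stimulus x voxel x scan array), `weights`,
#'   `stage`, `signal` (the noiseless component).
#' @export
simulate_voxel_responses <- function(model, stimuli, spec, seed = 1) {
  if (!spec$stage %in% stage_names(model))
    stopf("stage '%s' not in model", spec$stage,
          class = "metamerlab_validation_error")
  x <- stage_feature_matrix(model, stimuli, spec$stage)
  n_stim <- nrow(x); p <- ncol(x)
  with_seed(seed, {
    w <- matrix(stats::runif(p * spec$n_voxels) *
                  (stats::runif(p * spec$n_voxels) < spec$sparsity),
                p, spec$n_voxels)
    # ensure no voxel has an empty readout
    empty <- colSums(w) == 0
    if (any(empty)) {
      for (j in which(empty)) w[sample.int(p, 1L), j] <- stats::runif(1)
    }
    sig <- x %*% w
    sds <- apply(sig, 2L, stats::sd)
    sds[sds == 0] <- 1
    sig <- sweep(sig, 2L, sds, "/")
    responses <- array(0, c(n_stim, spec$n_voxels, spec$n_scans))
    for (s in seq_len(spec$n_scans)) {
      responses[, , s] <- sig +
        matrix(stats::rnorm(n_stim * spec$n_voxels, sd = spec$noise_sd),
               n_stim, spec$n_voxels)
    }
    list(responses = responses, weights = w, stage = spec$stage, signal = sig)
  })
}
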