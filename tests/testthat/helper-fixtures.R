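# Shared fixtures, memoized so expensive model training runs once per session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

trained_image_model <- function() {
  fixture("trained_image_model", function()
    make_toy_model("image", 4, "briefly_trained", seed = 11))
}

random_image_model <- function() {
  fixture("random_image_model", function()
    make_toy_model("image", 4, "random_weights", seed = 11))
}

trained_audio_model <- function() {
  fixture("trained_audio_model", function()
    make_toy_model("audio", 3, "briefly_trained", seed = 11, n_train = 30))
}

image_stimuli <- function() {
  fixture("image_stimuli", function() generate_stimuli("image", 10, seed = 5))
}

# A tiny fully linear staged model with known weights, for exact
# matrix-product oracles (no nonlinearity, no conv).
linear_toy_model <- function() {
  w1 <- matrix(c(1, 2, -1, 0.5, 0, 1), 3, 2)   # 3 -> 2
  w2 <- matrix(c(1, -1, 2, 0.5), 2, 2)         # 2 -> 2
  structure(list(
    stages = list(
      list(name = "lin1", layers = list(
        list(type = "dense", w = w1, b = c(0.1, -0.2)))),
      list(name = "lin2", layers = list(
        list(type = "dense", w = w2, b = c(0, 0))))),
    modality = "image", input_shape = c(3L, 1L, 1L),
    preprocessing = "none", classifier_labels = c("a", "b")),
    class = "staged_model")
}

# Response table with a known group x condition accuracy structure.
simulated_mixed_table <- function(p_human, p_model, n_per_group = 6,
                                  n_stimuli = 40, sigma_item = 0, seed = 1) {
  classes <- letters[1:6]
  stim <- data.frame(stimulus_id = sprintf("s%02d", seq_len(n_stimuli)),
                     true_class = rep(classes,
                                      length.out = n_stimuli),
                     stringsAsFactors = FALSE)
  conds <- names(p_human)
  h <- simulate_observers(
    observer_spec(p_human, classes, n_participants = n_per_group,
                  sigma_item = sigma_item, observer_type = "human"),
    stim, conds, seed = seed)
  m <- simulate_observers(
    observer_spec(p_model, classes, n_participants = n_per_group,
                  sigma_item = sigma_item, observer_type = "model"),
    stim, conds, seed = seed + 1000)
  m$participant_id <- paste0("m_", m$participant_id)
  rbind(h, m)
}
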