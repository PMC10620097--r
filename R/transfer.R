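# Cross-model transfer: present metamers generated from one model to other
# recognition models and test group differences by permutation.

#' Recognition of metamers by another model
#'
#' Classifies each metamer with a recognition model and reports, per generation
#' stage, the fraction whose predicted label equals the reference class.
#'
#' @param metamers List of `metamer_candidate` objects (each carries its
#'   reference signal and matched stage).
#' @param recognition_model A `staged_model` with a classifier head.
#' @param reference_labels Optional character vector of true classes (defaults
#'   to the recognition model's own labels for the references).
#' @return Data frame with `stage`, `n_trials`, `n_correct`, `accuracy`.
#' @export
cross_model_recognition <- function(metamers, recognition_model,
                                    reference_labels = NULL) {
  if (is.null(recognition_model$classifier_labels))
    stopf("recognition model has no classifier head",
          class = "metamerlab_config_error")
  truth <- reference_labels %||% vapply(metamers, function(mm)
    predict_label(recognition_model, mm$reference), character(1))
  if (!all(truth %in% recognition_model$classifier_labels))
    stopf("class vocabularies cannot be reconciled",
          class = "metamerlab_config_error")
  pred <- vapply(metamers, function(mm)
    predict_label(recognition_model, mm$signal), character(1))
  stage <- vapply(metamers, `[[`, character(1), "stage")
  agg <- stats::aggregate(correct ~ stage,
                          data.frame(stage = stage, correct = pred == truth),
                          FUN = function(v) c(n = length(v), k = sum(v)))
  data.frame(stage = agg$stage,
             n_trials = agg$correct[, "n"],
             n_correct = agg$correct[, "k"],
             accuracy = agg$correct[, "k"] / agg$correct[, "n"],
             stringsAsFactors = FALSE)
}

#' Assemble a transfer matrix
#'
#' Combines per-(generation model, recognition model) recognition results into
#' the tidy transfer format. Self cells (recognition model == generation
#' model) are marked missing, never zero.
#'
#' @param results Data frame with columns `generation_model`, `stage`,
#'   `recognition_model`, `n_trials`, `n_correct` (accuracy recomputed).
#' @return A `transfer_matrix` data frame (adds `accuracy`, NA for self cells).
#' @export
transfer_matrix <- function(results) {
  needed <- c("generation_model", "stage", "recognition_model",
              "n_trials", "n_correct")
  if (!all(needed %in% names(results)))
    stopf("results must have columns %s", paste(needed, collapse = ", "),
          class = "metamerlab_validation_error")
  results$accuracy <- ifelse(
    results$generation_model == results$recognition_model |
      results$n_trials == 0,
    NA_real_, results$n_correct / results$n_trials)
  class(results) <- c("transfer_matrix", "data.frame")
  results
}

#' Average transfer curve for a group of generation models
#'
#' For each recognition model, averages accuracy over the group's generation
#' models per stage (missing self cells are skipped), then averages the
#' resulting curves across recognition models. The spread is the s.e.m. across
#' recognition models.
#'
#' @param matrix A `transfer_matrix` (or tidy data frame of the same shape).
#' @param generation_group Character vector of generation model names.
#' @return Data frame with `stage`, `mean_accuracy`, `sem`, `n_models`.
#' @export
aggregate_transfer <- function(matrix, generation_group) {
  if (length(generation_group) == 0L)
    stopf("generation group must be non-empty",
          class = "metamerlab_validation_error")
  m <- matrix[matrix$generation_model %in% generation_group, , drop = FALSE]
  stages <- unique(m$stage)
  recs <- unique(m$recognition_model)
  out <- lapply(stages, function(st) {
    per_rec <- vapply(recs, function(r) {
      v <- m$accuracy[m$stage == st & m$recognition_model == r]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    per_rec <- per_rec[!is.na(per_rec)]
    if (length(per_rec) == 0L) return(NULL)  # absent, not zero
    data.frame(stage = st, mean_accuracy = mean(per_rec),
               sem = if (length(per_rec) > 1) sem(per_rec) else 0,
               n_models = length(per_rec), stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# Group mean used by the permutation test: for one recognition model, average
# the group's cells per stage (NA-skipping), average over stages, then average
# across recognition models that contribute at least one value.
transfer_group_stat <- function(acc, group_idx) {
  # acc: gen x stage x rec array with NA for missing cells
  per_rec <- apply(acc[group_idx, , , drop = FALSE], 3L, function(sl) {
    stage_means <- colMeans(sl, na.rm = TRUE)     # sl: gen x stage
    stage_means <- stage_means[is.finite(stage_means)]
    if (length(stage_means) == 0L) NA_real_ else mean(stage_means)
  })
  mean(per_rec, na.rm = TRUE)
}

#' Permutation test for a difference between generation-model groups
#'
#' The statistic is the difference of group means of metamer recognizability
#' (accuracy averaged across model stages and recognition models, with missing
#' self cells skipped). The null distribution is obtained by permuting the
#' generation-model labels independently for each recognition model (whole
#' accuracy curves move together; missing cells are permuted as placeholders
#' and stay missing in the averages).
#'
#' @param matrix A `transfer_matrix`.
#' @param groupA,groupB Disjoint character vectors of generation model names.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param alternative `"greater"` (A > B, the default), `"less"`, or
#'   `"two.sided"`.
#' @param p_convention `"add_one"`: p = (1 + #\{null >= obs\}) / (1 + n_perm)
#'   (never below 1/(n_perm+1)); or `"rank"`: p = 1 - rank(obs)/n_perm,
#'   clamped below at 1/n_perm.
#' @return List with `statistic`, `p_value`, `null` (permuted statistics),
#'   `n_perm`.
#' @export
transfer_permutation_test <- function(matrix, groupA, groupB, n_perm = 10000,
                                      seed = 1,
                                      alternative = c("greater", "less",
                                                      "two.sided"),
                                      p_convention = c("add_one", "rank")) {
  alternative <- match.arg(alternative)
  p_convention <- match.arg(p_convention)
  if (n_perm < 1) stopf("n_perm must be >= 1",
                        class = "metamerlab_validation_error")
  if (length(intersect(groupA, groupB)) > 0L)
    stopf("groups must be disjoint", class = "metamerlab_validation_error")
  gens <- sort(unique(matrix$generation_model))
  stages <- sort(unique(matrix$stage))
  recs <- sort(unique(matrix$recognition_model))
  acc <- array(NA_real_, c(length(gens), length(stages), length(recs)),
               dimnames = list(gens, stages, recs))
  acc[cbind(match(matrix$generation_model, gens),
            match(matrix$stage, stages),
            match(matrix$recognition_model, recs))] <- matrix$accuracy
  ia <- match(groupA, gens); ib <- match(groupB, gens)
  if (anyNA(ia) || anyNA(ib))
    stopf("unknown generation model in group",
          class = "metamerlab_validation_error")
  obs <- transfer_group_stat(acc, ia) - transfer_group_stat(acc, ib)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    perm <- acc
    for (r in seq_along(recs)) {
      perm[, , r] <- acc[sample.int(length(gens)), , r]
    }
    transfer_group_stat(perm, ia) - transfer_group_stat(perm, ib)
  }, numeric(1)))
  side <- switch(alternative,
    greater = function(v, o) v >= o,
    less = function(v, o) v <= o,
    two.sided = function(v, o) abs(v) >= abs(o))
  p <- permutation_p(sum(side(null, obs)), n_perm, p_convention)
  list(statistic = obs, p_value = p, null = null, n_perm = as.integer(n_perm),
       alternative = alternative)
}

# Shared p-value conventions for all permutation tests.
permutation_p <- function(n_at_least, n_perm, convention = c("add_one",
                                                             "rank")) {
  convention <- match.arg(convention)
  if (convention == "add_one") (1 + n_at_least) / (1 + n_perm)
  else max(n_at_least / n_perm, 1 / n_perm)
}
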