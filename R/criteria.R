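# Metamer success criteria: activation-match metrics, null distributions from
# random natural stimulus pairs, and the pass/fail verdict.

#' Signal-to-noise ratio between two activation arrays (dB)
#'
#' `10 * log10(sum(x^2) / sum((x - y)^2))`, where `x` is the reference
#' activations and `y` the comparison activations. An exact match has zero
#' error energy and returns `Inf`, which is treated as a pass by the criteria.
#'
#' @param x,y Numeric arrays of identical shape.
#' @return SNR in decibels (possibly `Inf`).
#' @export
snr_db <- function(x, y) {
  if (length(x) != length(y))
    stopf("arrays must have the same shape",
          class = "metamerlab_validation_error")
  sx <- sum(x^2)
  if (sx == 0) stopf("SNR undefined for all-zero reference",
                     class = "metamerlab_validation_error")
  se <- sum((x - y)^2)
  if (se == 0) return(Inf)
  10 * log10(sx / se)
}

#' Activation-match metrics
#'
#' Computes the three match-fidelity metrics between flattened activation
#' arrays: Spearman rank correlation (average ranks for ties), squared Pearson
#' correlation, and SNR in dB.
#'
#' @param reference_acts,synth_acts Activation arrays of identical shape with
#'   at least 3 elements.
#' @return List with `spearman_rho`, `pearson_r2`, `snr_db`. Metrics that are
#'   undefined (zero-variance input) are `NA` and flagged in `undefined`.
#' @export
match_metrics <- function(reference_acts, synth_acts) {
  x <- as.vector(reference_acts); y <- as.vector(synth_acts)
  if (length(x) != length(y))
    stopf("arrays must have the same shape",
          class = "metamerlab_validation_error")
  if (length(x) < 3L)
    stopf("need at least 3 elements", class = "metamerlab_validation_error")
  undefined <- character(0)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rho <- NA_real_; r2 <- NA_real_
    undefined <- c("spearman_rho", "pearson_r2")
  } else {
    rho <- stats::cor(x, y, method = "spearman")
    r2 <- stats::cor(x, y)^2
  }
  snr <- if (sum(x^2) == 0) { undefined <- c(undefined, "snr_db"); NA_real_ }
         else snr_db(x, y)
  list(spearman_rho = rho, pearson_r2 = r2, snr_db = snr,
       undefined = undefined)
}

#' Null distribution of match metrics from random stimulus pairs
#'
#' Samples `n_pairs` pairs of distinct stimuli (uniformly, with replacement
#' across pairs, never pairing a stimulus with itself), computes the three
#' match metrics between their activations at `stage`, and derives a pass
#' threshold per metric. A metamer qualifies only if it beats every required
#' threshold.
#'
#' @param model A `staged_model`.
#' @param stage Stage name.
#' @param training_set A `stimulus_set` with at least 2 stimuli (stands in for
#'   the model's training distribution).
#' @param n_pairs Number of pairs (default 1e6; use ~1e3-1e4 for tests).
#' @param seed Integer seed.
#' @param threshold_rule `"max"` (strictly above the largest null sample, the
#'   conservative default) or `"quantile"`.
#' @param quantile Quantile used when `threshold_rule = "quantile"` (default
#'   0.999).
#' @return A `null_distribution`: per-metric samples and thresholds.
#' @export
build_null_distribution <- function(model, stage, training_set,
                                    n_pairs = 1e6, seed = 1,
                                    threshold_rule = c("max", "quantile"),
                                    quantile = 0.999) {
  threshold_rule <- match.arg(threshold_rule)
  n <- length(training_set$signals)
  if (n < 2) stopf("training set must contain at least 2 stimuli",
                   class = "metamerlab_validation_error")
  acts <- lapply(training_set$signals, function(s)
    as.vector(model_forward(model, s, stage = stage)$act))
  rho <- numeric(n_pairs); r2 <- numeric(n_pairs); snr <- numeric(n_pairs)
  n_degenerate <- 0L
  with_seed(seed, {
    k <- 0L
    while (k < n_pairs) {
      i <- sample.int(n, 1L)
      j <- sample.int(n - 1L, 1L)
      if (j >= i) j <- j + 1L          # uniform over j != i
      m <- match_metrics(acts[[i]], acts[[j]])
      if (length(m$undefined) > 0L) {  # degenerate pair: resample, log it
        n_degenerate <- n_degenerate + 1L
        next
      }
      k <- k + 1L
      rho[k] <- m$spearman_rho; r2[k] <- m$pearson_r2; snr[k] <- m$snr_db
    }
  })
  thr <- function(v) if (threshold_rule == "max") max(v)
                     else stats::quantile(v, quantile, names = FALSE)
  structure(list(stage = stage, n_pairs = as.integer(n_pairs),
                 samples = list(spearman_rho = rho, pearson_r2 = r2,
                                snr_db = snr),
                 thresholds = list(spearman_rho = thr(rho),
                                   pearson_r2 = thr(r2), snr_db = thr(snr)),
                 threshold_rule = threshold_rule, quantile = quantile,
                 n_degenerate = n_degenerate, seed = as.integer(seed)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution: stage %s, %d pairs, thresholds rho %.3f r2 %.3f snr %.2f dB>\n",
    x$stage, x$n_pairs, x$thresholds$spearman_rho, x$thresholds$pearson_r2,
    x$thresholds$snr_db))
  invisible(x)
}

#' Evaluate a metamer candidate against the success criteria
#'
#' A candidate passes if (1) every required match metric at the matched stage
#' strictly exceeds its null-distribution threshold and (2) the model assigns
#' the candidate the same classification label as its reference. Candidates
#' that fail are flagged for exclusion.
#'
#' @param model The generating `staged_model`.
#' @param candidate A `metamer_candidate` from [synthesize_metamer()].
#' @param null A `null_distribution` built for the candidate's stage.
#' @param metric_subset Metrics to require (default all three). Use e.g.
#'   `"snr_db"` alone for stages whose activations are too low-dimensional for
#'   rank-based metrics to discriminate.
#' @param require_label Apply the classifier-decision criterion (default TRUE).
#' @return A `criterion_verdict`: metrics, per-metric passes, `label_match`,
#'   and the `overall` conjunction.
#' @export
evaluate_metamer <- function(model, candidate, null,
                             metric_subset = c("spearman_rho", "pearson_r2",
                                               "snr_db"),
                             require_label = TRUE) {
  metric_subset <- match.arg(metric_subset, several.ok = TRUE)
  if (!identical(null$stage, candidate$stage))
    stopf("null distribution was built for stage '%s', candidate is '%s'",
          null$stage, candidate$stage, class = "metamerlab_config_error")
  ref_act <- model_forward(model, candidate$reference,
                           stage = candidate$stage)$act
  syn_act <- model_forward(model, candidate$signal,
                           stage = candidate$stage)$act
  metrics <- match_metrics(ref_act, syn_act)
  passes <- lapply(metric_subset, function(mt) {
    v <- metrics[[mt]]
    if (is.na(v)) FALSE
    else if (is.infinite(v)) TRUE      # exact match always passes
    else v > null$thresholds[[mt]]
  })
  names(passes) <- metric_subset
  label_match <- if (require_label) {
    if (is.null(model$classifier_labels))
      stopf("label criterion requires a classifier head",
            class = "metamerlab_config_error")
    predict_label(model, candidate$signal) ==
      predict_label(model, candidate$reference)
  } else TRUE
  structure(list(stage = candidate$stage, metrics = metrics,
                 thresholds = null$thresholds[metric_subset],
                 passes = passes, label_match = label_match,
                 overall = all(unlist(passes)) && label_match),
            class = "criterion_verdict")
}

#' @export
print.criterion_verdict <- function(x, ...) {
  cat(sprintf("<criterion_verdict: stage %s, %s (label_match %s; %s)>\n",
              x$stage, if (x$overall) "PASS" else "FAIL", x$label_match,
              paste(sprintf("%s %s", names(x$passes),
                            unlist(x$passes)), collapse = ", ")))
  invisible(x)
}
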