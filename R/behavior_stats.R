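# Behavioral statistics: permutation-based mixed ANOVA, split-half
# confusion-matrix reliability, per-stimulus reliability, and consistency of
# the most/least recognizable items.

#' Validate a response table
#'
#' A response table holds trial-level classification responses with columns
#' `participant_id`, `observer_type` ("human"/"model"), `condition` (a model
#' stage or "natural"), `stimulus_id`, `true_class`, `response_class`,
#' `correct`.
#'
#' @param table Data frame of trials.
#' @return The table, with `correct` recomputed from the class columns.
#' @export
as_response_table <- function(table) {
  needed <- c("participant_id", "observer_type", "condition", "stimulus_id",
              "true_class", "response_class")
  if (!all(needed %in% names(table)))
    stopf("response table must have columns %s",
          paste(needed, collapse = ", "),
          class = "metamerlab_validation_error")
  table$correct <- table$response_class == table$true_class
  table
}

# participant x condition matrix of proportion correct
accuracy_matrix <- function(table, participants = NULL, conditions = NULL) {
  participants <- participants %||% unique(table$participant_id)
  conditions <- conditions %||% unique(table$condition)
  y <- matrix(NA_real_, length(participants), length(conditions),
              dimnames = list(participants, conditions))
  agg <- stats::aggregate(correct ~ participant_id + condition, table, mean)
  y[cbind(match(agg$participant_id, participants),
          match(agg$condition, conditions))] <- agg$correct
  if (anyNA(y)) {
    bad <- which(is.na(y), arr.ind = TRUE)[1, ]
    stopf("empty cell: participant %s, condition %s",
          participants[bad[1]], conditions[bad[2]],
          class = "metamerlab_validation_error")
  }
  y
}

# F statistics from the sums-of-squares decomposition of a balanced
# split-plot design: Y is participants x conditions, g the between-participant
# grouping factor. Returns F and partial eta^2 for the requested effect.
split_plot_f <- function(y, g, effect) {
  k <- ncol(y)
  grand <- mean(y)
  subj_means <- rowMeans(y)
  if (effect == "main_stage" && is.null(g)) {      # one-way repeated measures
    n <- nrow(y)
    cond_means <- colMeans(y)
    ss_stage <- n * sum((cond_means - grand)^2)
    resid <- y - outer(subj_means, rep(1, k)) -
      outer(rep(1, n), cond_means) + grand
    ss_err <- sum(resid^2)
    df1 <- k - 1; df2 <- (n - 1) * (k - 1)
    f <- (ss_stage / df1) / (ss_err / df2)
    return(list(f = f, eta_p2 = ss_stage / (ss_stage + ss_err),
                df1 = df1, df2 = df2))
  }
  g <- factor(g)
  a <- nlevels(g)
  gi <- as.integer(g)
  n_g <- tabulate(g)
  group_means <- as.numeric(tapply(subj_means, g, mean))
  cond_means <- colMeans(y)
  cell_means <- apply(y, 2L, function(col)
    as.numeric(tapply(col, g, mean)))            # a x k
  if (a == 1L) cell_means <- matrix(cell_means, 1L)
  ss_obs <- k * sum(n_g * (group_means - grand)^2)
  ss_subj <- k * sum((subj_means - group_means[gi])^2)
  ss_stage <- nrow(y) * sum((cond_means - grand)^2)
  ss_int <- sum(n_g * (cell_means - outer(group_means, rep(1, k)) -
                         outer(rep(1, a), cond_means) + grand)^2)
  resid <- y - cell_means[gi, , drop = FALSE] - subj_means +
    group_means[gi]
  ss_err <- sum(resid^2)
  df_obs <- a - 1; df_subj <- nrow(y) - a
  df_int <- (a - 1) * (k - 1); df_err <- (nrow(y) - a) * (k - 1)
  switch(effect,
    main_observer = list(f = (ss_obs / df_obs) / (ss_subj / df_subj),
                         eta_p2 = ss_obs / (ss_obs + ss_subj),
                         df1 = df_obs, df2 = df_subj),
    interaction = list(f = (ss_int / df_int) / (ss_err / df_err),
                       eta_p2 = ss_int / (ss_int + ss_err),
                       df1 = df_int, df2 = df_err),
    main_stage = list(f = (ss_stage / (k - 1)) / (ss_err / df_err),
                      eta_p2 = ss_stage / (ss_stage + ss_err),
                      df1 = k - 1, df2 = df_err),
    stopf("unknown effect '%s'", effect,
          class = "metamerlab_validation_error"))
}

#' Permutation-based mixed-design ANOVA on recognition accuracy
#'
#' Aggregates the response table to proportion correct per participant x
#' condition and computes the F statistic of the requested effect from the
#' standard split-plot (or one-way repeated-measures) sums-of-squares
#' decomposition. Significance is assessed non-parametrically: for a main
#' effect of observer, observer labels are permuted across participants; for
#' the observer x stage interaction (and for `main_stage`), observer labels
#' and condition labels are permuted independently for each participant.
#'
#' @param table A response table (see [as_response_table()]).
#' @param design `"mixed"` (between factor = observer_type, within factor =
#'   condition) or `"single_factor"` (one-way repeated measures over
#'   conditions).
#' @param effect `"main_observer"`, `"interaction"`, or `"main_stage"`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param p_convention See [transfer_permutation_test()].
#' @return List with `f`, `eta_p2`, `df`, `p_value`, `null` F samples.
#' @export
mixed_anova_permutation <- function(table, design = c("mixed",
                                                      "single_factor"),
                                    effect = c("interaction", "main_observer",
                                               "main_stage"),
                                    n_perm = 10000, seed = 1,
                                    p_convention = c("add_one", "rank")) {
  design <- match.arg(design)
  effect <- match.arg(effect)
  p_convention <- match.arg(p_convention)
  table <- as_response_table(table)
  participants <- unique(table$participant_id)
  conditions <- sort(unique(table$condition))
  y <- accuracy_matrix(table, participants, conditions)
  if (design == "mixed") {
    g <- table$observer_type[match(participants, table$participant_id)]
    if (min(table(g)) < 2)
      stopf("need >= 2 participants per observer group",
            class = "metamerlab_validation_error")
  } else {
    g <- NULL
    if (effect != "main_stage")
      stopf("single_factor design only tests main_stage",
            class = "metamerlab_validation_error")
  }
  obs <- split_plot_f(y, g, effect)
  permute_once <- function() {
    yp <- y
    gp <- g
    if (effect %in% c("interaction", "main_stage")) {
      for (i in seq_len(nrow(yp))) yp[i, ] <- yp[i, sample.int(ncol(yp))]
    }
    if (!is.null(g) && effect %in% c("main_observer", "interaction")) {
      gp <- g[sample.int(length(g))]
    }
    split_plot_f(yp, gp, effect)$f
  }
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) permute_once(),
                                 numeric(1)))
  p <- permutation_p(sum(null >= obs$f), n_perm, p_convention)
  list(f = obs$f, eta_p2 = obs$eta_p2, df = c(obs$df1, obs$df2),
       p_value = p, null = null, n_perm = as.integer(n_perm),
       effect = effect, design = design)
}

#' Row-normalized confusion matrix
#'
#' @param table A response table (already filtered to one condition if
#'   desired).
#' @param classes Class vocabulary (default: union of true and response
#'   classes).
#' @param normalize Divide each row by its trial count (rows without trials
#'   stay zero counts / NA proportions).
#' @return class x class matrix.
#' @export
confusion_matrix <- function(table, classes = NULL, normalize = TRUE) {
  classes <- classes %||% sort(unique(c(table$true_class,
                                        table$response_class)))
  k <- length(classes)
  idx <- (match(table$true_class, classes) - 1L) * k +
    match(table$response_class, classes)
  cm <- matrix(tabulate(idx, nbins = k * k), k, k, byrow = TRUE,
               dimnames = list(true = classes, response = classes))
  if (normalize) {
    n <- rowSums(cm)
    cm <- cm / ifelse(n > 0, n, NA_real_)
  }
  cm
}

split_participants <- function(participants, rng_balanced = TRUE) {
  n <- length(participants)
  perm <- sample(participants)
  h <- n %/% 2L
  # with odd counts the extra participant goes to a random half
  if (n %% 2L == 1L && stats::runif(1) < 0.5) h <- h + 1L
  list(a = perm[seq_len(h)], b = perm[(h + 1L):n])
}

#' Split-half reliability of a confusion matrix
#'
#' For each of `n_splits` random halvings of the participants in `condition`,
#' builds the row-normalized confusion matrix for each half and computes the
#' Spearman correlation over matrix cells; a comparison correlation is
#' computed from the same split after globally shuffling the responses within
#' the condition. The p value is `(1 + n_overlap) / n_splits`, where
#' `n_overlap` counts splits in which true minus shuffled correlation is <= 0.
#'
#' @param table A response table.
#' @param condition Condition to analyze.
#' @param n_splits Number of random splits (default 1000).
#' @param seed Integer seed.
#' @param cells `"all"` (diagonal included, default) or `"offdiag"`.
#' @return List with `mean_rho`, `n_overlap`, `p_value`, `n_splits`.
#' @export
confusion_split_half <- function(table, condition, n_splits = 1000, seed = 1,
                                 cells = c("all", "offdiag")) {
  cells <- match.arg(cells)
  table <- as_response_table(table)
  tc <- table[table$condition == condition, , drop = FALSE]
  if (nrow(tc) == 0L) stopf("condition '%s' not present", condition,
                            class = "metamerlab_validation_error")
  participants <- unique(tc$participant_id)
  if (length(participants) < 4L)
    stopf("need >= 4 participants", class = "metamerlab_validation_error")
  classes <- sort(unique(c(tc$true_class, tc$response_class)))
  k <- length(classes)
  cell_mask <- if (cells == "offdiag") !diag(k) > 0 else
    matrix(TRUE, k, k)
  # vectorized internals: trials indexed by participant / class integers
  pid <- match(tc$participant_id, participants)
  ti <- match(tc$true_class, classes)
  norm_confusion <- function(keep, ri) {
    cm <- matrix(tabulate((ti[keep] - 1L) * k + ri[keep], nbins = k * k),
                 k, k, byrow = TRUE)
    n <- rowSums(cm)
    cm / ifelse(n > 0, n, NA_real_)
  }
  corr_cells <- function(in_a, ri) {
    ca <- norm_confusion(in_a, ri)
    cb <- norm_confusion(!in_a, ri)
    ok <- cell_mask & !is.na(ca) & !is.na(cb)
    if (sum(ok) < 3L) return(NA_real_)
    stats::cor(ca[ok], cb[ok], method = "spearman")
  }
  ri0 <- match(tc$response_class, classes)
  res <- with_seed(seed, {
    vapply(seq_len(n_splits), function(s) {
      halves <- split_participants(participants)
      in_a <- participants[pid] %in% halves$a
      c(corr_cells(in_a, ri0), corr_cells(in_a, sample(ri0)))
    }, numeric(2))
  })
  d <- res[1, ] - res[2, ]
  n_overlap <- sum(d <= 0, na.rm = TRUE) + sum(is.na(d))
  list(mean_rho = mean(res[1, ], na.rm = TRUE),
       mean_rho_shuffled = mean(res[2, ], na.rm = TRUE),
       n_overlap = as.integer(n_overlap),
       p_value = (1 + n_overlap) / n_splits,
       n_splits = as.integer(n_splits))
}

#' Split-half reliability of per-stimulus recognizability
#'
#' For each split, the proportion correct of every stimulus is computed in
#' each half from exactly `min_trials` randomly subsampled trials (stimuli
#' with fewer than `min_trials` trials in either half are excluded from that
#' split), and the Spearman correlation between halves is recorded; the mean
#' over splits is the reliability. The p value compares the true correlations
#' with ones computed after shuffling responses within the condition.
#'
#' @param table A response table.
#' @param condition Condition to analyze.
#' @param n_splits Number of splits (default 1000).
#' @param min_trials Trials required (and used) per stimulus per half
#'   (default 4).
#' @param seed Integer seed.
#' @return List with `mean_rho`, `p_value`, `n_splits`, `mean_n_stimuli`.
#' @export
per_stimulus_reliability <- function(table, condition, n_splits = 1000,
                                     min_trials = 4, seed = 1) {
  table <- as_response_table(table)
  tc <- table[table$condition == condition, , drop = FALSE]
  if (nrow(tc) == 0L) stopf("condition '%s' not present", condition,
                            class = "metamerlab_validation_error")
  participants <- unique(tc$participant_id)
  half_scores <- function(sub) {
    # proportion correct per stimulus from exactly min_trials sampled trials
    split(sub$correct, sub$stimulus_id)
  }
  res <- with_seed(seed, {
    out <- matrix(NA_real_, 3, n_splits)
    for (s in seq_len(n_splits)) {
      halves <- split_participants(participants)
      score_half <- function(dat, ids) {
        trials <- split(dat$correct[dat$participant_id %in% ids],
                        dat$stimulus_id[dat$participant_id %in% ids])
        vapply(trials, function(v) {
          if (length(v) < min_trials) return(NA_real_)
          mean(v[sample.int(length(v), min_trials)])
        }, numeric(1))
      }
      pair_rho <- function(dat) {
        sa <- score_half(dat, halves$a)
        sb <- score_half(dat, halves$b)
        common <- intersect(names(sa)[!is.na(sa)], names(sb)[!is.na(sb)])
        if (length(common) < 3L) return(c(NA_real_, 0))
        c(stats::cor(sa[common], sb[common], method = "spearman"),
          length(common))
      }
      rt <- pair_rho(tc)
      shuf <- tc
      shuf$correct <- sample(shuf$correct)
      rs <- pair_rho(shuf)
      out[, s] <- c(rt[1], rs[1], rt[2])
    }
    out
  })
  valid <- !is.na(res[1, ]) & !is.na(res[2, ])
  if (!any(valid))
    stopf("no stimuli meet the %d-trials-per-half inclusion rule", min_trials,
          class = "metamerlab_validation_error")
  d <- res[1, valid] - res[2, valid]
  n_overlap <- sum(d <= 0)
  list(mean_rho = mean(res[1, valid]),
       mean_rho_shuffled = mean(res[2, valid]),
       p_value = (1 + n_overlap) / sum(valid),
       n_splits = as.integer(n_splits),
       mean_n_stimuli = mean(res[3, valid]))
}

#' Consistency of the most and least recognizable stimuli
#'
#' Per split, one half of the participants selects the `k` stimuli with the
#' highest and the `k` with the lowest recognition scores; the difference of
#' the two groups' scores is then evaluated in the held-out half. Reports the
#' proportion of splits in which the held-out difference is greater than 0 and
#' the complementary p value (proportion of splits with difference <= 0).
#'
#' @param table A response table.
#' @param condition Condition to analyze.
#' @param k Number of extreme stimuli per end (default 50).
#' @param n_splits Number of splits (default 1000).
#' @param seed Integer seed.
#' @return List with `p_value`, `proportion_greater`, `mean_difference`.
#' @export
extreme_item_consistency <- function(table, condition, k = 50,
                                     n_splits = 1000, seed = 1) {
  table <- as_response_table(table)
  tc <- table[table$condition == condition, , drop = FALSE]
  if (nrow(tc) == 0L) stopf("condition '%s' not present", condition,
                            class = "metamerlab_validation_error")
  stimuli <- unique(tc$stimulus_id)
  if (length(stimuli) < 2 * k)
    stopf("need at least 2k = %d stimuli (have %d)", 2 * k, length(stimuli),
          class = "metamerlab_validation_error")
  participants <- unique(tc$participant_id)
  diffs <- with_seed(seed, vapply(seq_len(n_splits), function(s) {
    halves <- split_participants(participants)
    score <- function(ids) {
      sub <- tc[tc$participant_id %in% ids, ]
      vapply(split(sub$correct, factor(sub$stimulus_id, levels = stimuli)),
             function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
    }
    s1 <- score(halves$a); s2 <- score(halves$b)
    ok <- !is.na(s1) & !is.na(s2)
    if (sum(ok) < 2 * k) return(NA_real_)
    s1 <- s1[ok]; s2 <- s2[ok]
    ord <- order(s1, stats::runif(length(s1)))  # random tie-break
    least <- ord[seq_len(k)]
    most <- ord[(length(ord) - k + 1L):length(ord)]
    mean(s2[most]) - mean(s2[least])
  }, numeric(1)))
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) == 0L)
    stopf("no split had %d scorable stimuli in both halves", 2 * k,
          class = "metamerlab_validation_error")
  list(p_value = max(mean(diffs <= 0), 1 / length(diffs)),
       proportion_greater = mean(diffs > 0),
       mean_difference = mean(diffs),
       n_splits_used = length(diffs))
}
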