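# Voxel-wise encoding with noise-ceiling correction, cross-validated
# best-stage selection, and representational similarity analysis.

#' Ridge regularization grid
#'
#' Each power of 10 between 1e-40 and 1e40 (81 values).
#'
#' @return Numeric vector of length 81.
#' @export
ridge_lambda_grid <- function() 10^seq(-40, 40, by = 1)

#' Critical Pearson correlation (reliability floor)
#'
#' The one-tailed P < 0.05 critical value of the Pearson correlation for `n`
#' observations (df = n - 2): the floor applied to voxel and prediction
#' reliabilities before the noise-ceiling division. At the canonical split
#' sizes of 83 training and 82 test sounds the floors are 0.182 and 0.183.
#'
#' @param n Number of observations.
#' @param alpha One-tailed significance level (default 0.05).
#' @return The critical correlation.
#' @export
reliability_floor <- function(n, alpha = 0.05) {
  tcrit <- stats::qt(1 - alpha, df = n - 2)
  tcrit / sqrt(n - 2 + tcrit^2)
}

#' Spearman-Brown prophecy correction
#'
#' `n * r / (1 + (n - 1) * r)`: the predicted reliability after an n-fold
#' increase in data (n = 3 when single-scan correlations stand in for
#' three-scan averages; n = 2 for participant split halves).
#'
#' @param r Correlation in (-1, 1].
#' @param n_factor Fold increase in data.
#' @return Corrected correlation.
#' @export
spearman_brown <- function(r, n_factor) {
  if (any(r <= -1, na.rm = TRUE))
    stopf("r must be > -1", class = "metamerlab_validation_error")
  n_factor * r / (1 + (n_factor - 1) * r)
}

# Closed-form leave-one-out ridge errors for all lambdas and response columns
# at once, via the SVD of the (centered) design. Equals explicit refitting on
# the centered data (verified in tests).
ridge_loo_core <- function(xc, yc, lambda_grid) {
  sv <- svd(xc)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)                 # r x V
  n <- nrow(xc)
  mse <- matrix(NA_real_, length(lambda_grid), ncol(yc))
  for (li in seq_along(lambda_grid)) {
    s <- d2 / (d2 + lambda_grid[li])
    fitted <- sv$u %*% (s * uty)
    h <- rowSums(sweep(sv$u^2, 2L, s, "*"))
    e <- (yc - fitted) / (1 - h)
    mse[li, ] <- colMeans(e^2)
  }
  list(svd = sv, mse = mse)
}

ridge_weights_for_lambda <- function(sv, yc, lambda) {
  d <- sv$d
  shrink <- d / (d^2 + lambda)
  sv$v %*% (shrink * crossprod(sv$u, yc))
}

#' Ridge regression with leave-one-out lambda selection
#'
#' Centers the features (and the response) on the training set, selects the
#' regularization parameter that minimizes the mean leave-one-out squared
#' error over [ridge_lambda_grid()], and refits the weights on all training
#' rows with that parameter. The closed-form LOO errors equal explicit
#' leave-one-out refits on the centered data.
#'
#' @param x_train n x p feature matrix.
#' @param y_train Response vector (or n x V matrix; selection is per column).
#' @param lambda_grid Candidate penalties (default [ridge_lambda_grid()]).
#' @return List with `weights` (p x V), `intercepts`, `lambda` (per column),
#'   `x_center`, `loo_mse` (grid x V), and a `predict(newx)` closure.
#' @export
ridge_loo_select <- function(x_train, y_train,
                             lambda_grid = ridge_lambda_grid()) {
  x_train <- as.matrix(x_train)
  y_train <- as.matrix(y_train)
  if (nrow(x_train) < 3) stopf("need at least 3 training rows",
                               class = "metamerlab_validation_error")
  if (anyNA(x_train) || anyNA(y_train))
    stopf("NA values in training data", class = "metamerlab_validation_error")
  x_center <- colMeans(x_train)
  y_center <- colMeans(y_train)
  xc <- sweep(x_train, 2L, x_center)
  yc <- sweep(y_train, 2L, y_center)
  core <- ridge_loo_core(xc, yc, lambda_grid)
  best <- apply(core$mse, 2L, which.min)
  w <- matrix(0, ncol(x_train), ncol(y_train))
  for (li in unique(best)) {
    cols <- which(best == li)
    w[, cols] <- ridge_weights_for_lambda(core$svd, yc[, cols, drop = FALSE],
                                          lambda_grid[li])
  }
  res <- list(weights = w, intercepts = y_center,
              lambda = lambda_grid[best], x_center = x_center,
              loo_mse = core$mse, lambda_grid = lambda_grid)
  res$predict <- function(newx) {
    sweep(sweep(as.matrix(newx), 2L, x_center) %*% w, 2L, y_center, "+")
  }
  res
}

#' Noise-ceiling-corrected encoding pipeline
#'
#' For each of `n_splits` random train/test splits of the stimuli (83/82
#' proportions by default), fits a per-voxel ridge encoding model from each
#' stage's features to the scan-averaged responses, scores the prediction with
#' the squared Pearson correlation on the held-out stimuli, and corrects it by
#' the product of the voxel reliability (median Spearman-Brown-corrected
#' correlation between scan pairs on the training stimuli) and the prediction
#' reliability (median Spearman-Brown-corrected correlation between the
#' per-scan-fit test predictions), both floored at the one-tailed P < 0.05
#' critical correlation for their sample sizes. Reports the per-voxel median
#' over splits.
#'
#' @param features Named list of stimulus x feature matrices, one per stage.
#' @param voxels stimulus x voxel x scan array (>= 2 scans).
#' @param n_splits Number of random splits (default 10).
#' @param train_frac Training fraction (default 83/165).
#' @param seed Integer seed.
#' @param lambda_grid Ridge grid (default [ridge_lambda_grid()]).
#' @return List with `summary` (data frame: stage, voxel, median r2_star) and
#'   `detail` (per split scores and reliabilities).
#' @export
corrected_variance_pipeline <- function(features, voxels, n_splits = 10,
                                        train_frac = 83 / 165, seed = 1,
                                        lambda_grid = ridge_lambda_grid()) {
  if (length(dim(voxels)) != 3L || dim(voxels)[3] < 2L)
    stopf("voxels must be a stimulus x voxel x scan array with >= 2 scans",
          class = "metamerlab_validation_error")
  n_stim <- dim(voxels)[1]
  n_vox <- dim(voxels)[2]
  n_scan <- dim(voxels)[3]
  stopifnot(all(vapply(features, nrow, integer(1)) == n_stim))
  y_avg <- apply(voxels, c(1, 2), mean)
  scan_pairs <- utils::combn(n_scan, 2)
  detail <- list()
  with_seed(seed, {
    for (split in seq_len(n_splits)) {
      tr <- sort(sample.int(n_stim, round(n_stim * train_frac)))
      te <- setdiff(seq_len(n_stim), tr)
      floor_v <- reliability_floor(length(tr))
      floor_vhat <- reliability_floor(length(te))
      # voxel reliability from inter-scan correlations on the training sounds
      r_v <- apply(vapply(seq_len(ncol(scan_pairs)), function(pi) {
        a <- voxels[tr, , scan_pairs[1, pi]]
        b <- voxels[tr, , scan_pairs[2, pi]]
        sb_safe(colwise_cor(a, b), n_scan)
      }, numeric(n_vox)), 1L, stats::median, na.rm = TRUE)
      r_v_floored <- floor_reliability(r_v, floor_v)
      for (stage in names(features)) {
        x <- features[[stage]]
        fit <- ridge_loo_select(x[tr, , drop = FALSE],
                                y_avg[tr, , drop = FALSE], lambda_grid)
        pred <- fit$predict(x[te, , drop = FALSE])
        r <- colwise_cor(pred, y_avg[te, , drop = FALSE])
        r2 <- r^2
        # prediction reliability: each scan's training data predicts that
        # scan's test data; correlate the per-scan predictions
        xc_tr <- sweep(x[tr, , drop = FALSE], 2L, fit$x_center)
        xc_te <- sweep(x[te, , drop = FALSE], 2L, fit$x_center)
        sv <- svd(xc_tr)
        scan_pred <- lapply(seq_len(n_scan), function(s) {
          ys <- voxels[tr, , s, drop = TRUE]
          ysc <- sweep(ys, 2L, colMeans(ys))
          p <- matrix(0, length(te), n_vox)
          for (lam in unique(fit$lambda)) {
            cols <- which(fit$lambda == lam)
            w <- ridge_weights_for_lambda(sv, ysc[, cols, drop = FALSE], lam)
            p[, cols] <- xc_te %*% w
          }
          p
        })
        r_vhat <- apply(vapply(seq_len(ncol(scan_pairs)), function(pi) {
          sb_safe(colwise_cor(scan_pred[[scan_pairs[1, pi]]],
                              scan_pred[[scan_pairs[2, pi]]]), n_scan)
        }, numeric(n_vox)), 1L, stats::median, na.rm = TRUE)
        r_vhat_floored <- floor_reliability(r_vhat, floor_vhat)
        detail[[length(detail) + 1L]] <- data.frame(
          stage = stage, split = split, voxel = seq_len(n_vox),
          r2 = r2, r_v = r_v_floored, r_vhat = r_vhat_floored,
          r2_star = r2 / (r_v_floored * r_vhat_floored),
          lambda = fit$lambda, stringsAsFactors = FALSE)
      }
    }
  })
  detail <- do.call(rbind, detail)
  summary <- stats::aggregate(r2_star ~ stage + voxel, detail, stats::median)
  names(summary)[names(summary) == "r2_star"] <- "median_r2_star"
  list(summary = summary, detail = detail)
}

# Spearman-Brown over correlations that may be NA or degenerate (-1): those
# carry no usable reliability and fall through to the floor.
sb_safe <- function(r, n_factor) {
  out <- rep(NA_real_, length(r))
  ok <- !is.na(r) & r > -1
  out[ok] <- spearman_brown(r[ok], n_factor)
  out
}

floor_reliability <- function(r, floor) {
  ifelse(is.na(r), floor, pmax(r, floor))
}

colwise_cor <- function(a, b) {
  vapply(seq_len(ncol(a)), function(j) {
    sa <- stats::sd(a[, j]); sb <- stats::sd(b[, j])
    if (sa == 0 || sb == 0) return(NA_real_)
    stats::cor(a[, j], b[, j])
  }, numeric(1))
}

#' Cross-validated best-stage selection
#'
#' For each held-out participant, the best stage is chosen by averaging the
#' remaining participants' per-stage summaries and taking the maximum; the
#' held-out participant is then scored at that stage. The participant's own
#' data never enter their stage selection.
#'
#' @param scores Data frame with columns `participant`, `stage`, `value`
#'   (e.g. the ROI median of corrected variance explained).
#' @return List with `per_participant` (data frame: participant, chosen_stage,
#'   value), `mean_value`, and `modal_stage` (the stage most frequently
#'   chosen, used to pick the comparison stage for metamer recognizability).
#' @export
best_stage_cross_validated <- function(scores) {
  stopifnot(all(c("participant", "stage", "value") %in% names(scores)))
  participants <- unique(scores$participant)
  if (length(participants) < 2)
    stopf("cannot cross-validate with a single participant",
          class = "metamerlab_validation_error")
  rows <- lapply(participants, function(p) {
    others <- scores[scores$participant != p, ]
    avg <- tapply(others$value, others$stage, mean)
    chosen <- names(avg)[which.max(avg)]
    own <- scores$value[scores$participant == p & scores$stage == chosen]
    data.frame(participant = p, chosen_stage = chosen, value = own,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  tab <- table(per$chosen_stage)
  list(per_participant = per, mean_value = mean(per$value),
       modal_stage = names(tab)[which.max(tab)])
}

#' Representational dissimilarity matrix
#'
#' Z-scores each unit across stimuli (dropping zero-variance units with a
#' warning), then computes pairwise `1 - Pearson r` between stimulus response
#' patterns.
#'
#' @param responses stimulus x unit matrix.
#' @param zscore `"unit"` (each unit across stimuli, the default),
#'   `"stimulus"`, or `"none"`.
#' @return Symmetric stimulus x stimulus dissimilarity matrix with zero
#'   diagonal; entries lie in \[0, 2\].
#' @export
compute_rdm <- function(responses, zscore = c("unit", "stimulus", "none")) {
  zscore <- match.arg(zscore)
  x <- as.matrix(responses)
  if (nrow(x) < 2 || ncol(x) < 2)
    stopf("need >= 2 stimuli and >= 2 units",
          class = "metamerlab_validation_error")
  if (zscore == "unit") {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping %d zero-variance unit(s)", sum(sds == 0)))
      x <- x[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    x <- scale(x)
  } else if (zscore == "stimulus") {
    x <- t(scale(t(x)))
  }
  rdm <- 1 - stats::cor(t(x))
  diag(rdm) <- 0
  rdm
}

upper_tri <- function(m) m[upper.tri(m)]

#' Cross-validated RDM similarity and its noise ceiling
#'
#' Per participant and per train/test split of the stimuli, the model stage
#' whose train-sound RDM correlates best (Spearman, upper triangle) with the
#' participant's train-sound RDM is selected; the reported value is the median
#' over splits of the test-sound Spearman correlation at the selected stage.
#' The ceiling is, for each held-out participant, the median over splits of
#' the correlation between their test-sound RDM and the average of the other
#' participants' test-sound RDMs, averaged over participants.
#'
#' @param stage_features Named list of stimulus x feature matrices per stage.
#' @param participant_responses List (one per participant) of stimulus x unit
#'   (voxel) response matrices.
#' @param n_splits Number of splits (default 10).
#' @param train_frac Training fraction (default 83/165).
#' @param seed Integer seed.
#' @return List with `per_participant` (data frame: participant, median test
#'   rho, modal chosen stage), `mean_rho`, and `ceiling`.
#' @export
rdm_similarity_cv <- function(stage_features, participant_responses,
                              n_splits = 10, train_frac = 83 / 165, seed = 1) {
  n_stim <- nrow(participant_responses[[1]])
  if (n_stim < 6) stopf("too few stimuli to split",
                        class = "metamerlab_validation_error")
  n_part <- length(participant_responses)
  with_seed(seed, {
    splits <- lapply(seq_len(n_splits), function(s) {
      tr <- sort(sample.int(n_stim, round(n_stim * train_frac)))
      list(tr = tr, te = setdiff(seq_len(n_stim), tr))
    })
    per <- lapply(seq_len(n_part), function(p) {
      rhos <- numeric(n_splits)
      chosen <- character(n_splits)
      for (s in seq_len(n_splits)) {
        tr <- splits[[s]]$tr; te <- splits[[s]]$te
        prdm_tr <- compute_rdm(participant_responses[[p]][tr, , drop = FALSE])
        train_rho <- vapply(stage_features, function(fx)
          stats::cor(upper_tri(compute_rdm(fx[tr, , drop = FALSE])),
                     upper_tri(prdm_tr), method = "spearman"), numeric(1))
        st <- names(stage_features)[which.max(train_rho)]
        chosen[s] <- st
        prdm_te <- compute_rdm(participant_responses[[p]][te, , drop = FALSE])
        rhos[s] <- stats::cor(
          upper_tri(compute_rdm(stage_features[[st]][te, , drop = FALSE])),
          upper_tri(prdm_te), method = "spearman")
      }
      tab <- table(chosen)
      data.frame(participant = p, median_rho = stats::median(rhos),
                 modal_stage = names(tab)[which.max(tab)],
                 stringsAsFactors = FALSE)
    })
    ceiling_vals <- if (n_part >= 2) vapply(seq_len(n_part), function(p) {
      stats::median(vapply(seq_len(n_splits), function(s) {
        te <- splits[[s]]$te
        own <- compute_rdm(participant_responses[[p]][te, , drop = FALSE])
        others <- Reduce(`+`, lapply(setdiff(seq_len(n_part), p), function(q)
          compute_rdm(participant_responses[[q]][te, , drop = FALSE]))) /
          (n_part - 1)
        stats::cor(upper_tri(own), upper_tri(others), method = "spearman")
      }, numeric(1)))
    }, numeric(1)) else NA_real_
    per <- do.call(rbind, per)
    list(per_participant = per, mean_rho = mean(per$median_rho),
         ceiling = mean(ceiling_vals))
  })
}
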