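test_that("split-plot F statistics equal the aov() decomposition", {
  set.seed(14)
  for (rep in 1:5) {
    n_per <- sample(3:5, 1)
    k <- sample(3:5, 1)
    y <- matrix(runif(2 * n_per * k), 2 * n_per, k)
    g <- rep(c("human", "model"), each = n_per)
    long <- data.frame(
      y = as.vector(y),
      subj = factor(rep(seq_len(2 * n_per), k)),
      cond = factor(rep(seq_len(k), each = 2 * n_per)),
      grp = factor(rep(g, k)))
    fit <- summary(aov(y ~ grp * cond + Error(subj / cond), data = long))
    frow <- function(tab, term) unname(tab[trimws(rownames(tab)) == term,
                                           "F value"])
    tab_between <- fit[["Error: subj"]][[1]]
    tab_within <- fit[["Error: subj:cond"]][[1]]
    f_obs <- metamerlab:::split_plot_f(y, g, "main_observer")$f
    f_int <- metamerlab:::split_plot_f(y, g, "interaction")$f
    expect_equal(f_obs, frow(tab_between, "grp"), tolerance = 1e-8)
    expect_equal(f_int, frow(tab_within, "grp:cond"), tolerance = 1e-8)
    # one-way repeated measures against aov as well
    y1 <- y[seq_len(n_per), ]
    long1 <- droplevels(long[long$grp == "human", ])
    fit1 <- summary(aov(y ~ cond + Error(subj / cond), data = long1))
    f_stage <- metamerlab:::split_plot_f(y1, NULL, "main_stage")$f
    expect_equal(f_stage, frow(fit1[["Error: subj:cond"]][[1]], "cond"),
                 tolerance = 1e-8)
  }
})

test_that("a textbook 4-participant x 3-condition table is reproduced by hand", {
  y <- matrix(c(0.9, 0.8, 0.7,
                0.85, 0.75, 0.6,
                0.5, 0.45, 0.3,
                0.55, 0.4, 0.35), 4, 3, byrow = TRUE)
  g <- c("human", "human", "model", "model")
  grand <- mean(y)
  subj <- rowMeans(y); cond <- colMeans(y)
  grp <- tapply(subj, g, mean)[c("human", "model")]
  ss_obs <- 3 * 2 * sum((grp - grand)^2)
  ss_subj <- 3 * sum((subj - rep(grp, each = 2))^2)
  f_hand <- (ss_obs / 1) / (ss_subj / 2)
  res <- metamerlab:::split_plot_f(y, g, "main_observer")
  expect_equal(res$f, f_hand, tolerance = 1e-10)
  expect_equal(res$eta_p2, ss_obs / (ss_obs + ss_subj), tolerance = 1e-10)
})

test_that("identical observer groups give F near 0 and p near 1", {
  conds <- c(natural = 0.9, stage1 = 0.7, stage2 = 0.5)
  tab <- simulated_mixed_table(conds, conds, n_per_group = 6, seed = 3)
  res <- mixed_anova_permutation(tab, "mixed", "main_observer",
                                 n_perm = 300, seed = 1)
  expect_lt(res$f, 3)
  expect_gt(res$p_value, 0.1)
})

test_that("a human decline against model ceiling yields a significant interaction", {
  human <- c(natural = 0.92, early = 0.85, mid = 0.55, late = 0.15)
  model <- c(natural = 0.95, early = 0.95, mid = 0.94, late = 0.95)
  hits <- vapply(1:6, function(r) {
    tab <- simulated_mixed_table(human, model, n_per_group = 6, seed = 100 + r)
    mixed_anova_permutation(tab, "mixed", "interaction", n_perm = 300,
                            seed = r)$p_value <= 0.01
  }, logical(1))
  expect_gte(mean(hits), 5 / 6)
})

test_that("empty participant-condition cells are refused by name", {
  tab <- simulated_mixed_table(c(a = 0.8, b = 0.6), c(a = 0.9, b = 0.9),
                               n_per_group = 3, seed = 2)
  tab <- tab[!(tab$participant_id == "h01" & tab$condition == "b"), ]
  expect_error(mixed_anova_permutation(tab, "mixed", "interaction",
                                       n_perm = 10),
               "h01", class = "metamerlab_validation_error")
})

test_that("confusion matrices are row-normalized over observed rows", {
  tab <- data.frame(participant_id = "p1", observer_type = "human",
                    condition = "c", stimulus_id = sprintf("s%d", 1:6),
                    true_class = c("a", "a", "b", "b", "b", "c"),
                    response_class = c("a", "b", "b", "b", "a", "c"))
  cm <- confusion_matrix(as_response_table(tab))
  expect_equal(rowSums(cm), c(a = 1, b = 1, c = 1))
  expect_equal(cm["b", "b"], 2 / 3)
  cm0 <- confusion_matrix(as_response_table(tab), classes = c("a", "b", "c",
                                                              "d"))
  expect_true(all(is.na(cm0["d", ])))
})

test_that("consistent confusions give the minimum split-half p", {
  # a strong, shared confusion structure: class a drawn to b, c drawn to a
  classes <- c("a", "b", "c", "d")
  kern <- matrix(0, 4, 4, dimnames = list(classes, classes))
  kern["a", "b"] <- 1
  kern["b", "a"] <- 1
  kern["c", "a"] <- 1
  kern["d", "b"] <- 1
  spec <- observer_spec(c(cond = 0.2), classes, kernel = kern,
                        n_participants = 14)
  stim <- data.frame(stimulus_id = sprintf("s%02d", 1:60),
                     true_class = rep(classes, 15))
  tab <- simulate_observers(spec, stim, "cond", seed = 4)
  res <- confusion_split_half(tab, "cond", n_splits = 100, seed = 1)
  expect_equal(res$n_overlap, 0L)
  expect_equal(res$p_value, 1 / 100)
  expect_gt(res$mean_rho, res$mean_rho_shuffled)
})

test_that("uniformly random responses give a non-significant split-half p", {
  classes <- letters[1:4]
  ps <- vapply(1:5, function(r) {
    spec <- observer_spec(c(cond = 0.25), classes, n_participants = 8)
    stim <- data.frame(stimulus_id = sprintf("s%02d", 1:30),
                       true_class = rep(classes, length.out = 30))
    tab <- simulate_observers(spec, stim, "cond", seed = 40 + r)
    confusion_split_half(tab, "cond", n_splits = 60, seed = r)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.05)
})

test_that("per-stimulus reliability tracks true item-difficulty spread", {
  classes <- letters[1:4]
  stim <- data.frame(stimulus_id = sprintf("s%02d", 1:36),
                     true_class = rep(classes, length.out = 36))
  spec_hard <- observer_spec(c(cond = 0.6), classes, n_participants = 12,
                             sigma_item = 3)
  tab_hard <- simulate_observers(spec_hard, stim, "cond", seed = 7)
  res_hard <- per_stimulus_reliability(tab_hard, "cond", n_splits = 80,
                                       seed = 2)
  expect_gt(res_hard$mean_rho, 0.5)
  expect_lte(res_hard$p_value, 2 / 80)
  spec_flat <- observer_spec(c(cond = 0.6), classes, n_participants = 12,
                             sigma_item = 0)
  tab_flat <- simulate_observers(spec_flat, stim, "cond", seed = 8)
  res_flat <- per_stimulus_reliability(tab_flat, "cond", n_splits = 80,
                                       seed = 2)
  expect_lt(abs(res_flat$mean_rho), 0.25)
})

test_that("stimuli lacking the per-half trial minimum are excluded", {
  classes <- c("a", "b")
  # 3 participants per half at most: no stimulus can reach 4 trials per half
  spec <- observer_spec(c(cond = 0.7), classes, n_participants = 6)
  stim <- data.frame(stimulus_id = sprintf("s%02d", 1:10),
                     true_class = rep(classes, 5))
  tab <- simulate_observers(spec, stim, "cond", seed = 3)
  expect_error(per_stimulus_reliability(tab, "cond", n_splits = 20,
                                        min_trials = 4, seed = 1),
               class = "metamerlab_validation_error")
})

test_that("extreme-item consistency detects genuine difficulty spread", {
  classes <- letters[1:4]
  stim <- data.frame(stimulus_id = sprintf("s%03d", 1:60),
                     true_class = rep(classes, 15))
  spec <- observer_spec(c(cond = 0.5), classes, n_participants = 14,
                        sigma_item = 3)
  tab <- simulate_observers(spec, stim, "cond", seed = 11)
  res <- extreme_item_consistency(tab, "cond", k = 10, n_splits = 100,
                                  seed = 1)
  expect_gte(res$proportion_greater, 0.95)
  expect_error(extreme_item_consistency(tab, "cond", k = 40, n_splits = 10),
               class = "metamerlab_validation_error")
})
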