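test_that("training feature counters match a hand trace", {
  # stimulus A (id 0) correct at block trials 1 and 4, shown again at trial 7
  tr <- block_table(stimulus = c(0, 1, 2, 0, 1, 2, 0, 1, 2),
                    action = rep(0L, 9),
                    correct = c(1, 0, 1, 1, 1, 0, 0, 1, 1))
  ft <- derive_training_features(tr)
  a7 <- ft[ft$stimulus_id == 0 & ft$trial_index == 7, ]
  expect_equal(a7$previous_correct, 2L)
  expect_equal(a7$delay, 3L)          # trials since the correct at trial 4
  expect_equal(a7$previous_iterations, 2L)
  # first presentations have zero counters and undefined delay
  firsts <- ft[ft$previous_iterations == 0, ]
  expect_true(all(firsts$previous_correct == 0))
  expect_true(all(is.na(firsts$delay)))
  # delay is >= 1 wherever defined
  expect_true(all(ft$delay >= 1, na.rm = TRUE))
  expect_true(all(ft$previous_correct <= ft$previous_iterations))
})

test_that("features are a pure per-session function and prefix-computable", {
  set.seed(61)
  sim1 <- sim_one(default_params(), mini_config())$training
  sim2 <- sim_one(default_params(), mini_config())$training
  sim2$subject_id <- 2L
  ft_alone <- derive_training_features(sim1)
  ft_joint <- derive_training_features(rbind(sim1, sim2))
  joint1 <- ft_joint[ft_joint$subject_id == 1L, ]
  rownames(joint1) <- rownames(ft_alone) <- NULL
  expect_equal(joint1, ft_alone)
  # truncating a session leaves the counters of the retained prefix
  # unchanged (the iteration-based late flag references the block's total
  # iteration count, so only the counters are prefix-computable)
  k <- 20
  counters <- c("previous_iterations", "previous_correct", "delay")
  pre <- derive_training_features(sim1[1:k, ])[counters]
  full <- derive_training_features(sim1)[1:k, counters]
  rownames(pre) <- rownames(full) <- NULL
  expect_equal(pre, full)
})

test_that("both early/late definitions are available", {
  tr <- block_table(stimulus = rep(c(0, 1), 9)[1:18],
                    action = rep(0L, 18), correct = rep(1L, 18))
  ft_it <- derive_training_features(tr, early_late = "iteration")
  expect_true(all(ft_it$early_flag == (ft_it$previous_iterations < 2)))
  expect_true(all(ft_it$late_flag == (ft_it$previous_iterations >= 7)))
  ft_pc <- derive_training_features(tr, early_late = "pcor")
  expect_true(all(ft_pc$early_flag == (ft_pc$previous_correct < 3)))
  expect_true(all(ft_pc$late_flag == !ft_pc$early_flag))
})

make_session <- function(subject, session, late_acc, n = 40) {
  n_late <- 10
  correct <- c(rep(1L, n - n_late), rbinom(n_late, 1, 1))
  tr <- block_table(stimulus = rep(0:1, n / 2), action = rep(0L, n),
                    correct = rep(1L, n))
  tr$subject_id <- subject; tr$session_label <- session
  ft <- derive_training_features(tr)
  # overwrite late-trial outcomes to hit the target accuracy exactly
  late_idx <- which(ft$late_flag)
  ft$correct[late_idx] <- 0L
  ft$correct[late_idx[seq_len(round(late_acc * length(late_idx)))]] <- 1L
  ft
}

test_that("the 53% rule drops subjects only when below in every session", {
  set.seed(62)
  bad <- do.call(rbind, Map(make_session, 1, c("PBO", "MPH", "SUL"),
                            c(0.40, 0.45, 0.50)))
  good <- do.call(rbind, Map(make_session, 2, c("PBO", "MPH", "SUL"),
                             c(0.40, 0.80, 0.40)))
  out <- apply_training_exclusions(rbind(bad, good))
  expect_equal(out$excluded_subjects, 1L)
  expect_true(all(out$data$subject_id == 2L))
  # pre-first-correct trials are marked, not deleted
  expect_true("analysis_include" %in% names(out$data))
  expect_true(all(out$data$analysis_include ==
                    (out$data$previous_correct >= 1)))
  expect_true(any(!out$data$analysis_include))
})

test_that("test-phase filters drop fast trials and pathological sessions", {
  mk <- function(subject, session, choices, rts) {
    data.frame(subject_id = subject, session_label = session,
               trial_index = seq_along(choices), left_stimulus = 1L,
               right_stimulus = 2L, choice = choices, rt = rts)
  }
  ok <- mk(1, "PBO", rep(c("left", "left", "right", "right"), 5),
           rep(1, 20))
  fast <- ok; fast$rt[3] <- 0.2
  # 16 alternations over 20 recorded responses = 0.842 > 0.75
  altern <- mk(2, "PBO", rep(c("left", "right"), 10), rep(1, 20))
  altern$choice[c(2, 11)] <- c("left", "right")
  capture <- mk(3, "PBO", c(rep("left", 15), rep(NA, 5)), rep(1, 20))
  out <- apply_test_exclusions(rbind(fast, altern, capture))
  rep <- out$report
  expect_false(rep$session_excluded[rep$subject_id == 1])
  expect_true(rep$session_excluded[rep$subject_id == 2])
  expect_true(rep$session_excluded[rep$subject_id == 3])
  expect_equal(rep$capture_rate[rep$subject_id == 3], 0.75)
  kept <- out$data
  expect_true(all(kept$subject_id == 1))
  expect_equal(nrow(kept), 19)            # the 0.2 s trial is gone
  # boundary: alternation exactly 0.75 is retained ("more than 75%" is strict)
  seq75 <- c("left", rep(c("right", "left"), length.out = 12),
             rep("left", 4))
  s75 <- mk(4, "PBO", seq75[1:17], rep(1, 17))
  r75 <- apply_test_exclusions(s75)$report
  expect_lte(r75$alternation_rate, 0.75)
  expect_false(r75$session_excluded)
})

test_that("test-pair features follow the earning arithmetic", {
  # H earns 1.6 points/trial in a set-size-5 block, L earns 1.0 in size 2
  tr <- rbind(
    block_table(stimulus = rep(100:104, 5), action = rep(0L, 25),
                correct = rep(1L, 25), block_id = 1, set_size = 5),
    block_table(stimulus = rep(200:201, 5), action = rep(0L, 10),
                correct = rep(1L, 10), block_id = 2, set_size = 2))
  tr$points[tr$stimulus_id == 100] <- rep(c(2L, 2L, 2L, 1L, 1L), 1)
  tr$points[tr$stimulus_id == 200] <- 1L
  te <- data.frame(subject_id = 1L, session_label = "PBO", trial_index = 1L,
                   left_stimulus = 100L, right_stimulus = 200L,
                   choice = "left", rt = 1)
  ft <- derive_test_features(te, tr)
  expect_equal(ft$delta_v, 0.6)
  expect_equal(ft$delta_ns, 3)
  expect_equal(ft$mean_set_size, 3.5)
  expect_equal(ft$mean_value, 1.3)
  expect_equal(ft$accuracy, 1L)
  expect_false(ft$tie)
  # equal earnings: flagged tie, excluded from accuracy
  te2 <- te; te2$right_stimulus <- 101L
  tr$points[tr$stimulus_id == 101] <- rep(c(2L, 2L, 2L, 1L, 1L), 1)
  ft2 <- derive_test_features(te2, tr)
  expect_true(ft2$tie)
  expect_true(is.na(ft2$accuracy))
  expect_equal(ft2$delta_ns, 0)           # same-block pair
  expect_error(derive_test_features(transform(te, right_stimulus = 999L), tr),
               "no training history")
})

test_that("learning-curve summaries have the right cells and values", {
  tr <- block_table(stimulus = rep(c(0, 1), 9)[1:18], action = rep(0L, 18),
                    correct = rep(1L, 18))
  ft <- derive_training_features(tr)
  curve <- summarize_learning_curves(ft)
  expect_true(all(curve$accuracy == 1))
  expect_equal(nrow(curve), 9L)           # 1 set size x 9 iterations
  expect_equal(curve$n, rep(2L, 9))
  # uniform-random agent sits near 1/3 in every cell
  set.seed(63)
  rnd <- sim_one(default_params(rho = 0, alpha_rl = 0, nu = 1))$training
  cr <- summarize_learning_curves(derive_training_features(rnd))
  expect_true(all(abs(cr$accuracy - 1 / 3) < 4 * sqrt(2 / 9 / cr$n) + 1e-9))
  expect_equal(nrow(cr), 4 * 9)
})

test_that("logistic fits match the closed-form log odds ratio", {
  counts <- expand.grid(y = c(0, 1), x = c(0, 1))
  counts$n <- c(100, 100, 50, 150)        # odds 1 at x=0, odds 3 at x=1
  df <- counts[rep(seq_len(4), counts$n), c("y", "x")]
  co <- fit_logistic(df, y ~ x, standardize = FALSE)
  expect_lt(abs(co$estimate[co$term == "x"] - log(3)), 1e-6)
  expect_false(attr(co, "ridge"))
})

test_that("null predictors yield near-zero slopes and separation is flagged", {
  set.seed(64)
  df <- data.frame(y = rbinom(10000, 1, 0.5), x1 = rnorm(10000),
                   x2 = rnorm(10000))
  co <- fit_logistic(df, y ~ x1 + x2)
  slopes <- co[co$term != "(Intercept)", ]
  expect_true(all(abs(slopes$estimate) < 3 * slopes$se))
  # perfectly separated toy input: ridge fallback, finite coefficients
  sep <- data.frame(y = rep(c(0, 1), each = 10), x = c(rnorm(10), rnorm(10) + 50))
  co2 <- fit_logistic(sep, y ~ x, standardize = FALSE)
  expect_true(attr(co2, "ridge"))
  expect_true(all(is.finite(co2$estimate)) && all(is.finite(co2$se)))
})
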