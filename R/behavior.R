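#' Derive trial-level training features
#'
#' Adds, per subject-session and per stimulus within block: the number of
#' previous presentations (`previous_iterations`), previous correct responses
#' (`previous_correct`), the delay in trials since the stimulus's last
#' correct response (`delay`, NA before the first correct response), and
#' early/late flags. Two early/late definitions are available: `"iteration"`
#' (default) marks the first two and last two iterations of each stimulus;
#' `"pcor"` marks trials with fewer than three previous correct responses as
#' early and the rest as late.
#'
#' @param training Time-ordered training trial table (`subject_id`,
#'   `session_label`, `block_id`, `trial_index`, `stimulus_id`, `correct`).
#' @param early_late Which definition drives the flags.
#' @return The table with feature columns appended. A pure per-session
#'   function: rows for one subject-session depend only on that session.
#' @export
derive_training_features <- function(training,
                                     early_late = c("iteration", "pcor")) {
  early_late <- match.arg(early_late)
  key <- interaction(training$subject_id, training$session_label,
                     training$block_id, drop = TRUE)
  ord <- order(key, training$trial_index)
  df <- training[ord, , drop = FALSE]
  n <- nrow(df)
  df$previous_iterations <- NA_integer_
  df$previous_correct <- NA_integer_
  df$delay <- NA_integer_
  key <- key[ord]
  for (g in split(seq_len(n), key)) {
    # trial position within block (1-based, in time order)
    pos <- seq_along(g)
    stim <- df$stimulus_id[g]
    corr <- df$correct[g]
    for (s in unique(stim)) {
      w <- which(stim == s)
      df$previous_iterations[g[w]] <- seq_along(w) - 1L
      cc <- cumsum(corr[w])
      df$previous_correct[g[w]] <- c(0L, cc[-length(cc)])
      last_cor <- NA_integer_
      for (j in seq_along(w)) {
        df$delay[g[w[j]]] <- if (is.na(last_cor)) NA_integer_ else
          pos[w[j]] - last_cor
        if (corr[w[j]] == 1) last_cor <- pos[w[j]]
      }
    }
  }
  n_iter <- stats::ave(df$previous_iterations,
                       interaction(df$subject_id, df$session_label,
                                   df$block_id, df$stimulus_id, drop = TRUE),
                       FUN = length)
  if (early_late == "iteration") {
    df$early_flag <- df$previous_iterations < 2
    df$late_flag <- df$previous_iterations >= n_iter - 2
  } else {
    df$early_flag <- df$previous_correct < 3
    df$late_flag <- !df$early_flag
  }
  df
}

#' Subject- and trial-level training exclusions
#'
#' Drops subjects whose late-block accuracy falls below `threshold` in every
#' (non-empty) session — poor performers who never learned the task — and
#' marks (without deleting) trials at or before each stimulus's first correct
#' response via `analysis_include`, since accuracy before the first correct
#' response is luck, not learning; model fitting can still use all trials.
#' Sessions with no trials are flagged incomplete and excluded from that
#' session only.
#'
#' @param features Output of [derive_training_features()].
#' @param threshold Late-accuracy criterion (default 0.53).
#' @return List with `data` (retained rows plus `analysis_include`),
#'   `excluded_subjects`, and `report` (per subject-session late accuracy and
#'   status).
#' @export
apply_training_exclusions <- function(features, threshold = 0.53) {
  stopifnot(all(c("late_flag", "previous_correct") %in% names(features)))
  late <- features[features$late_flag, , drop = FALSE]
  acc <- stats::aggregate(correct ~ subject_id + session_label, late, mean)
  names(acc)[names(acc) == "correct"] <- "late_accuracy"
  acc$below <- acc$late_accuracy < threshold
  all_below <- tapply(acc$below, acc$subject_id, all)
  excluded <- as.integer(names(all_below)[all_below])
  report <- acc
  report$subject_excluded <- report$subject_id %in% excluded
  out <- features[!features$subject_id %in% excluded, , drop = FALSE]
  out$analysis_include <- out$previous_correct >= 1
  list(data = out, excluded_subjects = excluded, report = report)
}

#' Test-phase exclusions
#'
#' Applies the test-phase data-quality rules: trials faster than `rt_min`
#' seconds are dropped (likely guesses); sessions where fewer than
#' `capture_min` of trials have a recorded choice are dropped (response
#' logging failure); sessions where strictly more than `alternation_max` of
#' consecutive recorded choices alternate left/right are dropped (button
#' alternation rather than task engagement).
#'
#' @param test Test trial table (`subject_id`, `session_label`, `choice`
#'   with NA for uncaptured responses, `rt`).
#' @param rt_min Seconds (default 0.25).
#' @param capture_min Minimum captured-response rate (default 0.80).
#' @param alternation_max Maximum alternation rate, strict (default 0.75).
#' @return List with `data` (retained trials) and `report` (per session:
#'   capture and alternation rates, trials dropped, status).
#' @export
apply_test_exclusions <- function(test, rt_min = 0.25, capture_min = 0.80,
                                  alternation_max = 0.75) {
  key <- interaction(test$subject_id, test$session_label, drop = TRUE)
  rows <- split(seq_len(nrow(test)), key)
  keep <- logical(nrow(test))
  rep_list <- list()
  for (g in rows) {
    ch <- test$choice[g]
    capture <- mean(!is.na(ch))
    rec <- ch[!is.na(ch)]
    altern <- if (length(rec) >= 2) mean(rec[-1] != rec[-length(rec)]) else 0
    session_ok <- capture >= capture_min && altern <= alternation_max
    fast <- !is.na(test$rt[g]) & test$rt[g] < rt_min
    if (session_ok) keep[g] <- !is.na(ch) & !fast
    rep_list[[length(rep_list) + 1L]] <- data.frame(
      subject_id = test$subject_id[g[1]],
      session_label = test$session_label[g[1]],
      capture_rate = capture, alternation_rate = altern,
      n_fast_trials = sum(fast), session_excluded = !session_ok)
  }
  list(data = test[keep, , drop = FALSE],
       report = do.call(rbind, rep_list))
}

#' Derive test-phase pair features
#'
#' For each test trial, computes the reward earned by each stimulus during
#' training (mean points per presentation by default, or the raw sum), then
#' orients the pair to its objectively more-rewarded member: `delta_v` is the
#' (non-negative) earning difference, `delta_ns` the set size of the
#' more-rewarded minus the less-rewarded stimulus, `mean_set_size` and
#' `mean_value` the pair averages, and `accuracy` whether the more-rewarded
#' stimulus was chosen. Pairs with exactly equal earnings are flagged `tie`
#' and get NA accuracy.
#'
#' @param test Test trial table (after exclusions).
#' @param training Training trial table supplying reward histories.
#' @param value `"rate"` (default, mean points per presentation) or `"sum"`.
#' @return The test table with feature columns appended.
#' @export
derive_test_features <- function(test, training, value = c("rate", "sum")) {
  value <- match.arg(value)
  agg_fun <- if (value == "rate") mean else sum
  earn <- stats::aggregate(points ~ subject_id + session_label + stimulus_id,
                           training, agg_fun)
  ns_tab <- unique(training[c("subject_id", "session_label", "stimulus_id",
                              "set_size")])
  look <- function(tab, col, sid, lab, stim) {
    idx <- match(paste(sid, lab, stim),
                 paste(tab$subject_id, tab$session_label, tab$stimulus_id))
    tab[[col]][idx]
  }
  v_l <- look(earn, "points", test$subject_id, test$session_label,
              test$left_stimulus)
  v_r <- look(earn, "points", test$subject_id, test$session_label,
              test$right_stimulus)
  ns_l <- look(ns_tab, "set_size", test$subject_id, test$session_label,
               test$left_stimulus)
  ns_r <- look(ns_tab, "set_size", test$subject_id, test$session_label,
               test$right_stimulus)
  if (anyNA(v_l) || anyNA(v_r)) {
    stop("test pair references a stimulus with no training history",
         call. = FALSE)
  }
  left_hi <- v_l >= v_r
  out <- test
  out$tie <- v_l == v_r
  out$delta_v <- abs(v_l - v_r)
  out$delta_ns <- ifelse(left_hi, ns_l - ns_r, ns_r - ns_l)
  out$mean_set_size <- (ns_l + ns_r) / 2
  out$mean_value <- (v_l + v_r) / 2
  out$accuracy <- ifelse(out$tie, NA_integer_,
                         as.integer((out$choice == "left") == left_hi))
  out
}

#' Accuracy learning-curve summary
#'
#' Cell means and standard errors of accuracy by set size and either
#' iteration number or previous-correct count, optionally split by grouping
#' covariates.
#'
#' @param features Output of [derive_training_features()] (exclusions
#'   applied as desired by the caller).
#' @param by `"iteration"` or `"previous_correct"`.
#' @param groups Character vector of additional grouping columns.
#' @return data.frame: grouping columns, `set_size`, `bin`, `accuracy`,
#'   `se`, `n` — one row per set size x bin x group cell present in the data.
#' @export
summarize_learning_curves <- function(features,
                                      by = c("iteration", "previous_correct"),
                                      groups = character()) {
  by <- match.arg(by)
  bin <- if (by == "iteration") features$previous_iterations + 1L else
    features$previous_correct
  cells <- c(list(set_size = features$set_size, bin = bin),
             lapply(stats::setNames(groups, groups),
                    function(g) features[[g]]))
  out <- stats::aggregate(features$correct, cells, function(x) {
    c(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
  })
  stats_mat <- out$x
  out$x <- NULL
  out$accuracy <- stats_mat[, 1]
  out$se <- stats_mat[, 2]
  out$n <- as.integer(stats_mat[, 3])
  out[order(out$set_size, out$bin), , drop = FALSE]
}

#' Fixed-effects logistic regression on trial features
#'
#' A fixed-effects stand-in for hierarchical trial-level regressions, used
#' for sign and qualitative checks only. Continuous predictors are z-scored
#' within the dataset before fitting (so coefficients are standardised);
#' fitting is maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`). Under complete separation the fit falls back to a lightly
#' ridge-penalised IRLS (flagged in the output).
#'
#' @param data Feature table.
#' @param formula Model formula with a binary response.
#' @param standardize z-score continuous predictors (default TRUE).
#' @param ridge_lambda Penalty used by the separation fallback.
#' @return data.frame of coefficients (`term`, `estimate`, `se`, `z`, `p`)
#'   with attribute `ridge` (TRUE if the fallback was used).
#' @export
fit_logistic <- function(data, formula, standardize = TRUE,
                         ridge_lambda = 1e-2) {
  vars <- all.vars(formula)
  resp <- vars[1]
  data <- data[stats::complete.cases(data[vars]), , drop = FALSE]
  if (standardize) {
    for (v in vars[-1]) {
      x <- data[[v]]
      if (is.numeric(x) && length(unique(x)) > 2 && stats::sd(x) > 0) {
        data[[v]] <- (x - mean(x)) / stats::sd(x)
      }
    }
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    X <- stats::model.matrix(formula, data)
    y <- as.numeric(data[[resp]])
    co <- ridge_irls(X, y, ridge_lambda)
    out <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                      z = co[, 1] / co[, 2],
                      p = 2 * stats::pnorm(-abs(co[, 1] / co[, 2])))
    attr(out, "ridge") <- TRUE
  } else {
    sm <- summary(fit)$coefficients
    out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4])
    attr(out, "ridge") <- FALSE
  }
  rownames(out) <- NULL
  out
}

# L2-penalised IRLS (intercept unpenalised); keeps coefficients finite under
# separation
ridge_irls <- function(X, y, lambda, maxit = 100, tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(rep(lambda, p))
  if ("(Intercept)" %in% colnames(X)) {
    pen[match("(Intercept)", colnames(X)), match("(Intercept)", colnames(X))] <- 0
  }
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + pen
    beta_new <- drop(solve(H, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  se <- sqrt(diag(solve(crossprod(X, X * w) + pen)))
  cbind(estimate = beta, se = se, deparse.level = 0) -> out
  rownames(out) <- colnames(X)
  out
}
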