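#' Default sampler over the range of fitted values
#'
#' Draws parameter sets uniformly from the range the MAP estimates occupied
#' after outlier removal: `alpha_rl` in `[0, 0.04]`, `gamma` in
#' `[0.039, 0.84]`, `phi` in `[0, 0.30]`, `rho` in `[0.62, 1]`, `wm_cap`
#' uniform on 2..5, `nu` in `[0.026, 0.14]`. Recoverability claims apply over
#' this region; pass `full_range = TRUE` for the complete parameter box.
#'
#' @param n Number of parameter sets.
#' @param full_range Sample the complete `[0, 1]` box instead.
#' @return List of `rlwm_params`.
#' @export
sample_fitted_range <- function(n, full_range = FALSE) {
  lo <- c(alpha_rl = 0, gamma = 0.039, phi = 0, rho = 0.62, nu = 0.026)
  hi <- c(alpha_rl = 0.04, gamma = 0.84, phi = 0.30, rho = 1, nu = 0.14)
  if (full_range) {
    lo[] <- 0
    hi[] <- 1
  }
  lapply(seq_len(n), function(i) {
    u <- stats::runif(5, lo, hi)
    model_params(alpha_rl = u[1], gamma = u[2], phi = u[3], rho = u[4],
                 wm_cap = sample(2:5, 1), nu = u[5])
  })
}

#' Parameter recovery exercise
#'
#' Samples generative parameter sets, simulates one subject-session per set
#' on a fresh task instance, refits each by MAP, and compares recovered to
#' true values: Pearson correlation, bias and RMSE per continuous parameter
#' and a confusion matrix for the integer capacity. Non-converged fits are
#' excluded from the summaries and counted.
#'
#' @param n_subjects Number of simulated subjects (the reference exercise
#'   uses 90).
#' @param config An `rlwm_task_config`.
#' @param fit_cfg An `rlwm_fit_config`.
#' @param sampler Function `n -> list of rlwm_params`; default
#'   [sample_fitted_range()].
#' @param pairs_per_stimulus Test pairs per stimulus.
#' @param seed Optional integer seed.
#' @return An `rlwm_recovery` report: `truth` and `recovered` tables,
#'   `summary` (r / bias / RMSE per parameter), `cap_confusion`,
#'   `cap_match_rate`, `n_nonconverged`, `seed`.
#' @export
run_recovery <- function(n_subjects = 90, config = task_config(),
                         fit_cfg = fit_config(), sampler = sample_fitted_range,
                         pairs_per_stimulus = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- sampler(n_subjects)
  fits <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    des <- build_test_pairs(generate_task(config), pairs_per_stimulus)
    sim <- simulate_subject(des, truth[[i]], subject_id = i)
    fits[[i]] <- fit_subject(sim$training, sim$test, fit_cfg)
  }
  ids <- data.frame(subject_id = seq_len(n_subjects))
  true_tab <- fits_to_table(lapply(truth, function(p) {
    list(params = p, log_posterior = NA_real_, log_likelihood = NA_real_,
         converged = TRUE)
  }), ids)
  rec_tab <- fits_to_table(fits, ids)
  ok <- rec_tab$converged
  summarise_par <- function(p) {
    x <- true_tab[[p]][ok]
    y <- rec_tab[[p]][ok]
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y)
    data.frame(parameter = p, r = r, bias = mean(y - x),
               rmse = sqrt(mean((y - x)^2)),
               degenerate = stats::sd(x) == 0)
  }
  summ <- do.call(rbind, lapply(PAR_NAMES, summarise_par))
  conf <- table(true = factor(true_tab$wm_cap[ok], levels = 2:5),
                recovered = factor(rec_tab$wm_cap[ok], levels = 2:5))
  structure(list(truth = true_tab, recovered = rec_tab, summary = summ,
                 cap_confusion = conf,
                 cap_match_rate = mean(true_tab$wm_cap[ok] == rec_tab$wm_cap[ok]),
                 n_nonconverged = sum(!ok), n_subjects = n_subjects,
                 seed = seed),
            class = "rlwm_recovery")
}

#' @export
print.rlwm_recovery <- function(x, ...) {
  cat(sprintf("parameter recovery over %d subjects (%d non-converged):\n",
              x$n_subjects, x$n_nonconverged))
  print(x$summary, row.names = FALSE)
  cat(sprintf("wm_cap exact-match rate: %.3f\n", x$cap_match_rate))
  invisible(x)
}

#' Posterior predictive check on learning curves
#'
#' For each session in a population with a matching fit, simulates
#' `n_ppc_draws` replicate sessions at the MAP parameters on the subject's
#' own realised task design (so design variance cannot masquerade as model
#' misfit), then compares observed to simulated accuracy in every
#' set size x iteration cell.
#'
#' @param population An `rlwm_population`.
#' @param fits List of `rlwm_fit`, parallel to `population$sessions`; `NULL`
#'   entries are skipped with a log entry in the report.
#' @param n_ppc_draws Replicates per session (must be >= 1).
#' @param kappa_effort Effort devaluation applied in the replicate test
#'   phases (default 0).
#' @return An `rlwm_ppc` report: `cells` (observed and simulated accuracy and
#'   absolute difference per set size x iteration), `max_abs_diff`,
#'   `n_ppc_draws`, `skipped`.
#' @export
run_ppc <- function(population, fits, n_ppc_draws = 20, kappa_effort = 0) {
  stopifnot(inherits(population, "rlwm_population"))
  if (n_ppc_draws < 1) stop("n_ppc_draws must be >= 1", call. = FALSE)
  if (length(fits) != length(population$sessions)) {
    stop("need one fit (or NULL) per session", call. = FALSE)
  }
  obs_n <- obs_k <- sim_n <- sim_k <- NULL
  skipped <- integer(0)
  acc_tab <- function(df) {
    it <- stats::ave(df$trial_index, df$block_id, df$stimulus_id,
                     FUN = seq_along)
    list(k = tapply(df$correct, list(df$set_size, it), sum),
         n = tapply(df$correct, list(df$set_size, it), length))
  }
  add <- function(a, b) if (is.null(a)) b else a + b
  for (i in seq_along(population$sessions)) {
    ses <- population$sessions[[i]]
    if (is.null(fits[[i]])) {
      skipped <- c(skipped, i)
      next
    }
    ob <- acc_tab(ses$training)
    obs_k <- add(obs_k, ob$k)
    obs_n <- add(obs_n, ob$n)
    for (d in seq_len(n_ppc_draws)) {
      rep_sim <- simulate_subject(ses$design, fits[[i]]$params,
                                  kappa_effort = kappa_effort,
                                  subject_id = ses$subject_id,
                                  session_label = ses$session_label)
      sm <- acc_tab(rep_sim$training)
      sim_k <- add(sim_k, sm$k)
      sim_n <- add(sim_n, sm$n)
    }
  }
  if (is.null(obs_n)) stop("no sessions with fits to check", call. = FALSE)
  obs <- obs_k / obs_n
  sim <- sim_k / sim_n
  cells <- data.frame(set_size = as.integer(rownames(obs)[row(obs)]),
                      iteration = as.integer(colnames(obs)[col(obs)]),
                      observed = as.vector(obs), simulated = as.vector(sim),
                      abs_diff = as.vector(abs(obs - sim)))
  cells <- cells[order(cells$set_size, cells$iteration), ]
  structure(list(cells = cells, max_abs_diff = max(cells$abs_diff),
                 n_ppc_draws = n_ppc_draws, skipped = skipped),
            class = "rlwm_ppc")
}

#' @export
print.rlwm_ppc <- function(x, ...) {
  cat(sprintf("posterior predictive check (%d draws/session): max |obs - sim| = %.4f\n",
              x$n_ppc_draws, x$max_abs_diff))
  if (length(x$skipped)) {
    cat("sessions skipped (no fit):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
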