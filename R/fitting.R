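#' Fitting configuration
#'
#' Hyperparameters for per-session MAP estimation. The five continuous
#' parameters are optimised within `[0, 1]` (shrunk inward by `bound_eps` so
#' the beta log-priors stay finite) by bounded quasi-Newton (L-BFGS-B) from
#' `n_restarts` starting points — one mid-range deterministic start plus
#' uniform random draws — for each integer capacity on the grid 2..5. Exact
#' ties across the capacity grid go to the smallest capacity (parsimony).
#'
#' @param n_restarts Number of optimisation starts per capacity (default 20).
#' @param include_test Include the test-phase choice likelihood in the MAP
#'   objective (default TRUE); FALSE gives a training-only ablation fit.
#' @param prior_shape1,prior_shape2 Beta prior shapes for `phi`, `gamma`,
#'   `nu` (default 1.05, 1.05 — very slightly informative, pulling estimates
#'   off the bounds). `alpha_rl`, `rho` and `wm_cap` get uniform priors.
#' @param decay_scope,delay_mode,critic_coding Model variant switches, as in
#'   [session_loglik()].
#' @param maxit L-BFGS-B iteration cap per start.
#' @param bound_eps Inward shrink of the box bounds.
#' @return An object of class `rlwm_fit_config`.
#' @export
fit_config <- function(n_restarts = 20, include_test = TRUE,
                       prior_shape1 = 1.05, prior_shape2 = 1.05,
                       decay_scope = c("pair", "stimulus"),
                       delay_mode = c("trials", "gap", "window"),
                       critic_coding = c("binary", "points"),
                       maxit = 500, bound_eps = 1e-5) {
  structure(list(n_restarts = as.integer(n_restarts),
                 include_test = include_test,
                 prior_shape1 = prior_shape1, prior_shape2 = prior_shape2,
                 decay_scope = match.arg(decay_scope),
                 delay_mode = match.arg(delay_mode),
                 critic_coding = match.arg(critic_coding),
                 maxit = maxit, bound_eps = bound_eps,
                 cap_grid = 2:5),
            class = "rlwm_fit_config")
}

#' Log-prior of the model parameters
#'
#' Independent beta(1.05, 1.05) densities on `phi`, `gamma` and `nu`;
#' uniform (zero log-density contribution) on `alpha_rl`, `rho` and the
#' capacity grid. Returns `-Inf` outside the parameter bounds.
#'
#' @param params An `rlwm_params`, or a plain list with the same fields.
#' @param shape1,shape2 Beta prior shapes.
#' @return Scalar log-prior.
#' @export
log_prior <- function(params, shape1 = 1.05, shape2 = 1.05) {
  unit <- c(params$alpha_rl, params$gamma, params$phi, params$rho, params$nu)
  if (any(!is.finite(unit)) || any(unit < 0) || any(unit > 1) ||
      params$wm_cap < 2 || params$wm_cap > 5) {
    return(-Inf)
  }
  sum(stats::dbeta(c(params$phi, params$gamma, params$nu),
                   shape1, shape2, log = TRUE))
}

# continuous parameter vector order used by the optimiser
PAR_NAMES <- c("alpha_rl", "gamma", "phi", "rho", "nu")

#' Fit one subject-session by MAP with a capacity grid search
#'
#' For each integer working-memory capacity in 2..5, maximises
#' `log-likelihood + log-prior` over the five continuous parameters with
#' multi-start L-BFGS-B, then selects the capacity with the highest
#' log-posterior (smallest capacity on exact ties). Deterministic given the
#' RNG state; pass `seed` to fix it.
#'
#' @param training,test Trial tables for one subject-session (see
#'   [session_loglik()]); `test` may be NULL.
#' @param config An `rlwm_fit_config`.
#' @param n_actions Response options (default 3).
#' @param seed Optional integer seed.
#' @return An object of class `rlwm_fit`: MAP `params`, `log_posterior`,
#'   `log_likelihood`, `capacity_profile` (best log-posterior per capacity),
#'   `n_restarts`, `converged`, `seed`.
#' @export
fit_subject <- function(training, test = NULL, config = fit_config(),
                        n_actions = 3, seed = NULL) {
  stopifnot(inherits(config, "rlwm_fit_config"))
  if (!is.null(seed)) set.seed(seed)
  if (!config$include_test) test <- NULL
  dat <- prep_session(training, test, n_actions, config$critic_coding)
  pair_decay <- config$decay_scope == "pair"
  dmode <- delay_mode_code(config$delay_mode)
  eps <- config$bound_eps
  lo <- rep(eps, 5)
  hi <- rep(1 - eps, 5)
  nll <- function(x, cap) {
    lp <- sum(stats::dbeta(x[c(3, 2, 5)], config$prior_shape1,
                           config$prior_shape2, log = TRUE))
    ll <- cpp_session_loglik(dat$block, dat$stim_local, dat$action,
                             dat$reward, dat$critic_reward, dat$block_ns,
                             dat$n_actions, dat$test_i, dat$test_j,
                             dat$test_choice,
                             c(x[1], x[2], x[3], x[4], x[5], cap, 50),
                             pair_decay, dmode)
    -(ll + lp)
  }
  nr <- config$n_restarts
  starts <- rbind(c(0.02, 0.45, 0.15, 0.80, 0.08),
                  matrix(stats::runif(5 * max(0, nr - 1), eps, 1 - eps),
                         ncol = 5))[seq_len(nr), , drop = FALSE]
  profile <- stats::setNames(rep(-Inf, length(config$cap_grid)),
                             config$cap_grid)
  best <- NULL
  any_conv <- FALSE
  for (cap in config$cap_grid) {
    cap_best <- NULL
    for (k in seq_len(nr)) {
      fit <- tryCatch(
        stats::optim(starts[k, ], nll, cap = cap, method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(maxit = config$maxit,
                                    ndeps = rep(1e-6, 5))),
        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$value)) next
      if (fit$convergence == 0) any_conv <- TRUE
      if (is.null(cap_best) || fit$value < cap_best$value) cap_best <- fit
    }
    if (is.null(cap_best)) next
    profile[as.character(cap)] <- -cap_best$value
    # strict improvement only: exact ties resolve to the smaller capacity
    if (is.null(best) || -cap_best$value > best$log_posterior) {
      x <- cap_best$par
      pars <- model_params(x[1], x[2], x[3], x[4], cap, x[5])
      ll <- cpp_session_loglik(dat$block, dat$stim_local, dat$action,
                               dat$reward, dat$critic_reward, dat$block_ns,
                               dat$n_actions, dat$test_i, dat$test_j,
                               dat$test_choice, par_vector(pars), pair_decay,
                               dmode)
      best <- list(params = pars, log_posterior = -cap_best$value,
                   log_likelihood = ll)
    }
  }
  if (is.null(best)) {
    stop("all optimisation restarts failed", call. = FALSE)
  }
  structure(c(best, list(capacity_profile = profile, n_restarts = nr,
                         converged = any_conv, seed = seed)),
            class = "rlwm_fit")
}

#' @export
print.rlwm_fit <- function(x, ...) {
  cat(sprintf("rlwm MAP fit: logpost = %.3f, loglik = %.3f, converged = %s\n",
              x$log_posterior, x$log_likelihood, x$converged))
  print(x$params)
  invisible(x)
}

#' Bayesian information criterion of a fit
#'
#' `BIC = -2 log L + k log n` with `k = 6` free parameters; `n` is the number
#' of choice observations the likelihood was evaluated on.
#'
#' @param fit An `rlwm_fit`.
#' @param n_obs Number of observations.
#' @return Scalar BIC.
#' @export
fit_bic <- function(fit, n_obs) {
  -2 * fit$log_likelihood + 6 * log(n_obs)
}

#' Collect fits into a table
#'
#' @param fits List of `rlwm_fit` objects.
#' @param ids data.frame of identifiers (e.g. `subject_id`, `session_label`)
#'   with one row per fit.
#' @return data.frame with one row per fit: identifiers, the six parameter
#'   estimates, `log_posterior`, `log_likelihood`, `converged`.
#' @export
fits_to_table <- function(fits, ids) {
  stopifnot(nrow(ids) == length(fits))
  est <- do.call(rbind, lapply(fits, function(f) {
    data.frame(alpha_rl = f$params$alpha_rl, gamma = f$params$gamma,
               phi = f$params$phi, rho = f$params$rho,
               wm_cap = f$params$wm_cap, nu = f$params$nu,
               log_posterior = f$log_posterior,
               log_likelihood = f$log_likelihood,
               converged = f$converged)
  }))
  cbind(ids, est)
}

#' Exclude parameter outliers within session groups
#'
#' Flags, within each session group and for each designated parameter,
#' subjects whose estimate lies more than `n_sd` standard deviations from the
#' group mean (mean and SD computed once on the unfiltered group — a single
#' pass). Groups with zero SD exclude nobody; groups smaller than 3 are
#' passed through with a warning flag. Exclusion is per session: a subject
#' can be kept in one session and dropped in another.
#'
#' @param fit_table Output of [fits_to_table()]; must contain `session_label`.
#' @param parameters Which parameters to screen (default all six).
#' @param n_sd Threshold in standard deviations (default 2).
#' @return List with `kept` (filtered table), `excluded` (rows removed), and
#'   `report` (data.frame: subject, session, parameter, value, z).
#' @export
exclude_param_outliers <- function(fit_table,
                                   parameters = c("alpha_rl", "gamma", "phi",
                                                  "rho", "wm_cap", "nu"),
                                   n_sd = 2) {
  stopifnot("session_label" %in% names(fit_table))
  report <- list()
  drop <- logical(nrow(fit_table))
  for (lab in unique(fit_table$session_label)) {
    sel <- which(fit_table$session_label == lab)
    if (length(sel) < 3) {
      warning(sprintf("session %s has fewer than 3 fits; no exclusion applied",
                      lab), call. = FALSE)
      next
    }
    for (p in parameters) {
      v <- fit_table[[p]][sel]
      m <- mean(v)
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) next
      z <- (v - m) / s
      out <- abs(z) > n_sd
      if (any(out)) {
        drop[sel[out]] <- TRUE
        report[[length(report) + 1L]] <- data.frame(
          subject_id = fit_table$subject_id[sel[out]], session_label = lab,
          parameter = p, value = v[out], z = z[out])
      }
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(subject_id = integer(0), session_label = character(0),
               parameter = character(0), value = numeric(0), z = numeric(0))
  list(kept = fit_table[!drop, , drop = FALSE],
       excluded = fit_table[drop, , drop = FALSE],
       report = report)
}
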