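#' Simulate one subject-session from the generative model
#'
#' Plays the task forward: actions are sampled from the mixture policy,
#' correct responses earn +2 points with probability 0.8 and +1 otherwise
#' (configurable in the design's `task_config`), incorrect responses earn 0,
#' and the binary correct/incorrect signal drives the RL, WM and critic
#' updates. Test-phase choices are sampled from the critic values, optionally
#' discounted by an implicit effort cost `kappa_effort * set_size` of the
#' block each stimulus was learned in — rewards earned under higher WM demand
#' are treated as subjectively less valuable. Response times are drawn from a
#' lognormal (so response-time filters are exercisable); they are not a
#' cognitive model.
#'
#' @param design An `rlwm_design`, with test pairs if a test phase is wanted.
#' @param params An `rlwm_params`.
#' @param kappa_effort Effort devaluation per unit set size applied to the
#'   simulated test-phase values only (default 0).
#' @param subject_id,session_label,session_number Identifiers stamped on the
#'   output tables.
#' @param rt_meanlog,rt_sdlog Lognormal response-time parameters; the default
#'   median is 1.07 s.
#' @param decay_scope,delay_mode,critic_coding As in [session_loglik()].
#' @return List with `training` and `test` trial data.frames.
#' @export
simulate_subject <- function(design, params, kappa_effort = 0,
                             subject_id = 1L, session_label = "PBO",
                             session_number = 1L,
                             rt_meanlog = log(1.07), rt_sdlog = 0.4,
                             decay_scope = c("pair", "stimulus"),
                             delay_mode = c("trials", "gap", "window"),
                             critic_coding = c("binary", "points")) {
  decay_scope <- match.arg(decay_scope)
  delay_mode <- match.arg(delay_mode)
  critic_coding <- match.arg(critic_coding)
  stopifnot(inherits(design, "rlwm_design"))
  tr <- design$trials
  cfg <- design$config
  skel <- data.frame(block_id = tr$block_id, stimulus_id = tr$stimulus_id,
                     action = tr$correct_action, correct = 1L)
  dat <- prep_session(skel, NULL, cfg$n_actions)
  pairs <- design$test_pairs
  if (is.null(pairs)) pairs <- data.frame(left_stimulus = integer(0),
                                          right_stimulus = integer(0))
  gi <- match(pairs$left_stimulus, dat$stim_global_id) - 1L
  gj <- match(pairs$right_stimulus, dat$stim_global_id) - 1L
  ns_of <- dat$set_size_of
  p_two <- unname(cfg$reward_points["2"])
  sim <- cpp_simulate_session(dat$block, dat$stim_local,
                              as.integer(tr$correct_action),
                              dat$block_ns, cfg$n_actions,
                              par_vector(params), p_two,
                              gi, gj, ns_of[gi + 1L], ns_of[gj + 1L],
                              kappa_effort, decay_scope == "pair",
                              critic_coding == "points",
                              delay_mode_code(delay_mode))
  training <- data.frame(
    subject_id = subject_id, session_label = session_label,
    session_number = session_number,
    block_id = tr$block_id, set_size = tr$set_size,
    trial_index = tr$trial_index, stimulus_id = tr$stimulus_id,
    action = sim$action, correct = sim$correct, points = sim$points,
    rt = stats::rlnorm(nrow(tr), rt_meanlog, rt_sdlog))
  test <- data.frame(
    subject_id = rep(subject_id, nrow(pairs)),
    session_label = rep(session_label, nrow(pairs)),
    trial_index = seq_len(nrow(pairs)),
    left_stimulus = pairs$left_stimulus,
    right_stimulus = pairs$right_stimulus,
    choice = ifelse(sim$test_choice == 0L, "left", "right"),
    rt = stats::rlnorm(nrow(pairs), rt_meanlog, rt_sdlog))
  list(training = training, test = test)
}

#' Specification of a synthetic cohort
#'
#' Defines how per-subject covariates map onto generative model parameters.
#' Each subject carries a standardised dopamine-synthesis-capacity proxy
#' (`da`, standard normal by default) and completes three drug sessions
#' (placebo `PBO`, methylphenidate `MPH`, sulpiride `SUL`) in counterbalanced
#' order. `effect_map` lists, per parameter, named linear coefficients on the
#' transformed scale; predictor names are `da`, `MPH`, `SUL` or interactions
#' such as `"MPH:da"`. Unit-interval parameters are shifted on the logit
#' scale; `wm_cap` is shifted additively and rounded into 2..5. The default
#' effects emulate the direction of the reported group-level findings —
#' higher dopamine synthesis capacity increases WM reliance, sulpiride
#' reduces WM reliance and speeds WM decay, methylphenidate boosts the
#' learning rate in proportion to synthesis capacity — with invented
#' magnitudes; they are for recovery exercises, not estimates.
#'
#' @param n_subjects Number of subjects.
#' @param base_params `rlwm_params` at covariate zero (placebo, average da).
#' @param effect_map Named list of named coefficient vectors (see above).
#' @param kappa_effort Implicit-effort devaluation passed to the simulated
#'   test phase (default 0 = off).
#' @param sessions Session labels (default PBO/MPH/SUL).
#' @param pairs_per_stimulus Test pairs per stimulus.
#' @param rt_meanlog,rt_sdlog Response-time distribution.
#' @return An object of class `rlwm_population_spec`.
#' @export
population_spec <- function(n_subjects,
                            base_params = model_params(alpha_rl = 0.02,
                                                       gamma = 0.4, phi = 0.1,
                                                       rho = 0.85, wm_cap = 3,
                                                       nu = 0.07),
                            effect_map = list(
                              rho = c(da = 0.5, SUL = -0.5),
                              alpha_rl = c("MPH:da" = 0.5),
                              phi = c(SUL = 0.5)),
                            kappa_effort = 0,
                            sessions = c("PBO", "MPH", "SUL"),
                            pairs_per_stimulus = 4,
                            rt_meanlog = log(1.07), rt_sdlog = 0.4) {
  stopifnot(n_subjects >= 1, inherits(base_params, "rlwm_params"))
  bad <- setdiff(names(effect_map),
                 c("alpha_rl", "gamma", "phi", "rho", "nu", "wm_cap"))
  if (length(bad)) stop("unknown parameter(s) in effect_map: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 base_params = base_params, effect_map = effect_map,
                 kappa_effort = kappa_effort, sessions = sessions,
                 pairs_per_stimulus = pairs_per_stimulus,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog),
            class = "rlwm_population_spec")
}

# linear predictor for one effect vector given the session's covariates
effect_lp <- function(coefs, covars) {
  if (is.null(coefs)) return(0)
  lp <- 0
  for (nm in names(coefs)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    val <- prod(vapply(parts, function(p) {
      if (!p %in% names(covars)) stop("unknown predictor: ", p, call. = FALSE)
      covars[[p]]
    }, numeric(1)))
    lp <- lp + coefs[[nm]] * val
  }
  lp
}

# map base params + session covariates to bound-respecting session params
session_params <- function(spec, covars) {
  bp <- spec$base_params
  em <- spec$effect_map
  shift_unit <- function(x, nm) {
    lp <- effect_lp(em[[nm]], covars)
    if (lp == 0) x else stats::plogis(stats::qlogis(x) + lp)
  }
  cap <- round(bp$wm_cap + effect_lp(em[["wm_cap"]], covars))
  model_params(alpha_rl = shift_unit(bp$alpha_rl, "alpha_rl"),
               gamma = shift_unit(bp$gamma, "gamma"),
               phi = shift_unit(bp$phi, "phi"),
               rho = shift_unit(bp$rho, "rho"),
               wm_cap = min(5, max(2, cap)),
               nu = shift_unit(bp$nu, "nu"),
               beta = bp$beta)
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject covariates once, derives per-session generative
#' parameters through the spec's effect map, builds a fresh task instance per
#' session, and simulates the training and test phases. Session order is
#' counterbalanced across subjects (the three cyclic orders in rotation).
#'
#' @param spec An `rlwm_population_spec`.
#' @param config An `rlwm_task_config`.
#' @return An object of class `rlwm_population`: list with `subjects`
#'   (covariate table), `sessions` (list of per-session records, each holding
#'   the design, the generative parameters and the simulated trial tables),
#'   and pooled `training` / `test` data.frames.
#' @export
generate_population <- function(spec, config = task_config()) {
  stopifnot(inherits(spec, "rlwm_population_spec"))
  n <- spec$n_subjects
  labs <- spec$sessions
  orders <- lapply(seq_along(labs) - 1L,
                   function(k) labs[(seq_along(labs) + k - 1L) %% length(labs) + 1L])
  subjects <- data.frame(subject_id = seq_len(n), da = stats::rnorm(n))
  sessions <- list()
  true_params <- list()
  for (i in seq_len(n)) {
    ord <- orders[[(i - 1L) %% length(orders) + 1L]]
    for (j in seq_along(ord)) {
      lab <- ord[j]
      covars <- list(da = subjects$da[i],
                     MPH = as.numeric(lab == "MPH"),
                     SUL = as.numeric(lab == "SUL"))
      pars <- session_params(spec, covars)
      des <- build_test_pairs(generate_task(config), spec$pairs_per_stimulus)
      sim <- simulate_subject(des, pars, kappa_effort = spec$kappa_effort,
                              subject_id = i, session_label = lab,
                              session_number = j,
                              rt_meanlog = spec$rt_meanlog,
                              rt_sdlog = spec$rt_sdlog)
      sessions[[length(sessions) + 1L]] <- list(
        subject_id = i, session_label = lab, session_number = j,
        design = des, params = pars,
        training = sim$training, test = sim$test)
      true_params[[length(true_params) + 1L]] <- data.frame(
        subject_id = i, session_label = lab,
        alpha_rl = pars$alpha_rl, gamma = pars$gamma, phi = pars$phi,
        rho = pars$rho, wm_cap = pars$wm_cap, nu = pars$nu)
    }
  }
  structure(list(
    spec = spec, config = config, subjects = subjects, sessions = sessions,
    params = do.call(rbind, true_params),
    training = do.call(rbind, lapply(sessions, `[[`, "training")),
    test = do.call(rbind, lapply(sessions, `[[`, "test"))),
    class = "rlwm_population")
}
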