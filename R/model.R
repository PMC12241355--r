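#' Model parameters
#'
#' The six free parameters of the working-memory / reinforcement-learning
#' mixture model, plus the fixed softmax inverse temperature. `alpha_rl` is
#' the RL learning rate; `gamma` discounts learning from incorrect feedback
#' (punishment neglect) in both systems; `phi` is the per-trial decay of
#' unobserved WM entries back to the uniform prior; `rho` is the baseline
#' propensity to rely on WM; `wm_cap` is the integer WM capacity whose ratio
#' to the per-stimulus delay scales WM reliance; `nu` is the guessing rate in
#' the test-phase choice rule. `beta` is fixed at 50 and is not fitted —
#' it trades off with the learning rate and WM reliance, so choices are
#' driven essentially deterministically by the larger value.
#'
#' @param alpha_rl,gamma,phi,rho,nu Numeric in `[0, 1]`.
#' @param wm_cap Integer in 2..5.
#' @param beta Softmax inverse temperature (fixed constant, default 50).
#' @return An object of class `rlwm_params`.
#' @export
model_params <- function(alpha_rl, gamma, phi, rho, wm_cap, nu, beta = 50) {
  unit <- c(alpha_rl = alpha_rl, gamma = gamma, phi = phi, rho = rho, nu = nu)
  if (any(!is.finite(unit)) || any(unit < 0) || any(unit > 1)) {
    stop("alpha_rl, gamma, phi, rho, nu must lie in [0, 1]", call. = FALSE)
  }
  if (wm_cap != round(wm_cap) || wm_cap < 2 || wm_cap > 5) {
    stop("wm_cap must be an integer in 2..5", call. = FALSE)
  }
  structure(list(alpha_rl = alpha_rl, gamma = gamma, phi = phi, rho = rho,
                 wm_cap = as.integer(wm_cap), nu = nu, beta = beta),
            class = "rlwm_params")
}

# compiled-core code for the delay-counting variants
delay_mode_code <- function(delay_mode) {
  match(delay_mode, c("gap", "window", "trials")) - 1L
}

# parameter vector layout shared with the compiled core
par_vector <- function(params) {
  c(params$alpha_rl, params$gamma, params$phi, params$rho, params$nu,
    params$wm_cap, params$beta)
}

#' @export
print.rlwm_params <- function(x, ...) {
  cat("rlwm model parameters:\n")
  cat(sprintf("  alpha_rl = %.4f  gamma = %.4f  phi = %.4f\n",
              x$alpha_rl, x$gamma, x$phi))
  cat(sprintf("  rho = %.4f  wm_cap = %d  nu = %.4f  (beta = %g, fixed)\n",
              x$rho, x$wm_cap, x$nu, x$beta))
  invisible(x)
}

#' Initialise the learner's state for one block
#'
#' All action values start uniform at `1/n_actions` for both the RL and WM
#' systems, the stimulus-level critic starts at the same prior, and the
#' per-stimulus delay counters (intervening stimuli since the last correct
#' response) start at zero.
#'
#' @param set_size Number of stimuli in the block.
#' @param n_actions Number of response options.
#' @return List with matrices `Q`, `WM` (`set_size` x `n_actions`), vector
#'   `V`, integer vectors `delay` (intervening count carried over from
#'   completed presentation gaps) and `pending` (count in the current gap),
#'   and logical matrix `seen` tracking which other stimuli have already been
#'   counted in each stimulus's current gap.
#' @export
init_state <- function(set_size, n_actions) {
  stopifnot(set_size >= 1, n_actions >= 1)
  q0 <- 1 / n_actions
  list(Q = matrix(q0, set_size, n_actions),
       WM = matrix(q0, set_size, n_actions),
       V = rep(q0, set_size),
       delay = rep(0L, set_size),
       pending = rep(0L, set_size),
       seen = matrix(FALSE, set_size, set_size))
}

#' Rescorla-Wagner value update with punishment neglect
#'
#' A correct outcome (`r = 1`) moves the value toward 1 at rate `alpha_rl`;
#' an incorrect outcome (`r = 0`) moves it toward 0 at the discounted rate
#' `alpha_rl * gamma`.
#'
#' @param q Current value in `[0, 1]`.
#' @param r Binary reward (1 correct, 0 incorrect).
#' @param params An `rlwm_params`.
#' @return Updated value.
#' @export
rl_update <- function(q, r, params) {
  if (!r %in% c(0, 1)) stop("reward must be 0 or 1", call. = FALSE)
  if (r == 1) q + params$alpha_rl * (1 - q)
  else q + params$alpha_rl * params$gamma * (0 - q)
}

#' One-shot working-memory update
#'
#' WM encodes a correct outcome perfectly in a single trial (`w <- 1`);
#' incorrect outcomes shrink the entry by the punishment-neglect factor:
#' `w <- (1 - gamma) * w`.
#'
#' @inheritParams rl_update
#' @param w Current WM entry in `[0, 1]`.
#' @return Updated entry.
#' @export
wm_update <- function(w, r, params) {
  if (!r %in% c(0, 1)) stop("reward must be 0 or 1", call. = FALSE)
  if (r == 1) 1 else (1 - params$gamma) * w
}

#' Decay unobserved working-memory entries toward the prior
#'
#' Every WM entry except the observed one relaxes toward the uniform prior
#' `1/n_actions` at rate `phi`. Under the default `scope = "pair"` only the
#' (stimulus, chosen action) entry is exempt — the literal reading of the
#' update rule; `scope = "stimulus"` exempts the current stimulus's whole row.
#'
#' @param state A block state from [init_state()].
#' @param stimulus 1-based stimulus index of the observed trial.
#' @param action 1-based index of the chosen action.
#' @param params An `rlwm_params`.
#' @param scope `"pair"` (default) or `"stimulus"`.
#' @return The state with decayed `WM`.
#' @export
wm_decay <- function(state, stimulus, action, params, scope = c("pair", "stimulus")) {
  scope <- match.arg(scope)
  q0 <- 1 / ncol(state$WM)
  keep <- state$WM[stimulus, ]
  state$WM <- state$WM + params$phi * (q0 - state$WM)
  if (scope == "stimulus") {
    state$WM[stimulus, ] <- keep
  } else {
    state$WM[stimulus, action] <- keep[action]
  }
  state
}

#' Stimulus-value critic update
#'
#' The critic tracks the expected reward of each stimulus (averaged over
#' actions) at the same learning rate as the RL actor, with the same
#' punishment-neglect discount on incorrect trials. Under point coding `r`
#' may be 0, 1 or 2; the trial counts as correct when `r > 0`.
#'
#' @param v Current stimulus value.
#' @param r Reward (0/1 binary, or 0/1/2 points).
#' @param params An `rlwm_params`.
#' @return Updated value.
#' @export
critic_update <- function(v, r, params) {
  if (r > 0) v + params$alpha_rl * (r - v)
  else v + params$alpha_rl * params$gamma * (0 - v)
}

#' Delay-modulated working-memory weight
#'
#' `omega = rho * min(1, wm_cap / n_delay)`: reliance on WM for a stimulus
#' falls below the baseline `rho` once more unique stimuli have intervened
#' since its last correct response than WM can hold. A delay of zero (block
#' start, or immediately after a correct response) leaves reliance at `rho`.
#'
#' @param params An `rlwm_params`.
#' @param n_delay Non-negative integer count of unique intervening stimuli.
#' @return The mixture weight in `[0, rho]`.
#' @export
wm_weight <- function(params, n_delay) {
  stopifnot(n_delay >= 0)
  m <- if (n_delay <= params$wm_cap) 1 else params$wm_cap / n_delay
  params$rho * m
}

# log-space softmax with max subtraction; finite for beta = 50, values in [0,1]
softmax_beta <- function(x, beta) {
  z <- beta * (x - max(x))
  e <- exp(z)
  e / sum(e)
}

#' Mixture choice probabilities for one training trial
#'
#' Converts the RL and WM action values for a stimulus into softmax policies
#' (inverse temperature `beta`) and mixes them linearly with the
#' delay-modulated weight from [wm_weight()]:
#' `p = (1 - omega) * p_rl + omega * p_wm`.
#'
#' @param state A block state from [init_state()].
#' @param stimulus 1-based stimulus index.
#' @param params An `rlwm_params`.
#' @return List with `p_rl`, `p_wm`, `omega`, and the mixed distribution `p`.
#' @export
policy_probs <- function(state, stimulus, params) {
  p_rl <- softmax_beta(state$Q[stimulus, ], params$beta)
  p_wm <- softmax_beta(state$WM[stimulus, ], params$beta)
  omega <- wm_weight(params, state$delay[stimulus] + state$pending[stimulus])
  list(p_rl = p_rl, p_wm = p_wm, omega = omega,
       p = (1 - omega) * p_rl + omega * p_wm)
}

#' Test-phase choice probability with guessing
#'
#' Probability of choosing the stimulus with value `v_a` over the one with
#' value `v_b`: a two-option softmax of the critic values (inverse
#' temperature `beta`) mixed with a uniform guess at rate `nu`, so the
#' probability is confined to `[nu/2, 1 - nu/2]`.
#'
#' @param v_a,v_b Stimulus values.
#' @param params An `rlwm_params`.
#' @return Probability of choosing the first stimulus.
#' @export
test_choice_prob <- function(v_a, v_b, params) {
  params$nu / 2 + (1 - params$nu) * stats::plogis(params$beta * (v_a - v_b))
}

# ---- session data preparation -------------------------------------------

# Convert trial tables for one subject-session into 0-based index arrays for
# the likelihood/simulation cores. Blocks are taken in order of appearance;
# within a block, stimuli are indexed by sorted stimulus_id.
prep_session <- function(training, test = NULL, n_actions = 3,
                         critic_coding = c("binary", "points")) {
  critic_coding <- match.arg(critic_coding)
  req <- c("block_id", "stimulus_id", "action", "correct")
  miss <- setdiff(req, names(training))
  if (length(miss)) {
    stop("training table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bl <- training$block_id
  block_ids <- rle(as.vector(bl))$values
  if (anyDuplicated(block_ids)) {
    stop("training trials are not time-ordered: block ids are not contiguous",
         call. = FALSE)
  }
  if ("trial_index" %in% names(training)) {
    ok <- tapply(training$trial_index, bl, function(ti) all(diff(ti) > 0))
    if (!all(ok)) stop("training trials are not time-ordered within block",
                       call. = FALSE)
  }
  block_idx <- match(bl, block_ids) - 1L
  stim_by_block <- lapply(split(training$stimulus_id, block_idx), function(s) sort(unique(s)))
  block_ns <- vapply(stim_by_block, length, integer(1))
  offsets <- c(0L, cumsum(block_ns))[seq_along(block_ns)]
  stim_local <- integer(nrow(training))
  for (b in seq_along(block_ids)) {
    sel <- block_idx == (b - 1L)
    stim_local[sel] <- match(training$stimulus_id[sel], stim_by_block[[b]]) - 1L
  }
  stim_global_id <- unlist(stim_by_block, use.names = FALSE)
  reward <- as.integer(training$correct)
  critic_reward <- if (critic_coding == "points") {
    as.numeric(training$points)
  } else {
    as.numeric(reward)
  }
  out <- list(block = block_idx, stim_local = stim_local,
              action = as.integer(training$action),
              reward = reward, critic_reward = critic_reward,
              block_ns = as.integer(block_ns), n_actions = n_actions,
              stim_global_id = stim_global_id,
              set_size_of = rep(block_ns, block_ns),
              test_i = integer(0), test_j = integer(0),
              test_choice = integer(0))
  if (!is.null(test) && nrow(test) > 0) {
    gi <- match(test$left_stimulus, stim_global_id) - 1L
    gj <- match(test$right_stimulus, stim_global_id) - 1L
    if (anyNA(gi) || anyNA(gj)) {
      bad <- which(is.na(gi) | is.na(gj))[1]
      stop(sprintf("test trial %d references a stimulus not in training", bad),
           call. = FALSE)
    }
    out$test_i <- gi
    out$test_j <- gj
    if ("choice" %in% names(test)) {
      out$test_choice <- ifelse(test$choice == "left", 0L, 1L)
    }
  }
  out
}

#' Session log-likelihood
#'
#' Log-likelihood of one subject-session's observed choices under the mixture
#' model: learner state resets at every block start; each training trial
#' contributes `log p(action)` from [policy_probs()]; after each trial the
#' delay counters, the RL/WM/critic values for the observed pair, and finally
#' WM decay are applied, in that order. Test-phase trials (if supplied)
#' contribute `log p(choice)` from [test_choice_prob()] using the
#' end-of-training critic values.
#'
#' @param training Time-ordered trial table with columns `block_id`,
#'   `stimulus_id`, `action` (0-based), `correct` (and `points` under point
#'   coding).
#' @param params An `rlwm_params`.
#' @param test Optional test trial table (`left_stimulus`, `right_stimulus`,
#'   `choice` in `"left"`/`"right"`).
#' @param n_actions Number of response options (default 3).
#' @param decay_scope Passed to [wm_decay()].
#' @param delay_mode How the per-stimulus delay driving [wm_weight()] is
#'   counted since the stimulus's last correct response. `"trials"`
#'   (default): all intervening trials, the same clock as the behavioural
#'   delay regressor; this keeps every capacity on the 2..5 grid
#'   behaviourally distinct. `"gap"`: unique intervening stimuli within each
#'   gap between successive presentations, accumulated across gaps.
#'   `"window"`: unique intervening stimuli over the whole window (bounded
#'   by set size - 1, making capacities above the largest set size
#'   indistinguishable and saturating the delay modulation).
#' @param critic_coding `"binary"` (default: the critic learns from
#'   correct/incorrect) or `"points"` (learns the 0/1/2 point outcomes).
#' @param engine `"cpp"` (compiled, default) or `"r"` (plain-R trace built
#'   from the scalar update functions; identical by construction and kept as
#'   a readable reference).
#' @return The log-likelihood (scalar).
#' @export
session_loglik <- function(training, params, test = NULL, n_actions = 3,
                           decay_scope = c("pair", "stimulus"),
                           delay_mode = c("trials", "gap", "window"),
                           critic_coding = c("binary", "points"),
                           engine = c("cpp", "r")) {
  decay_scope <- match.arg(decay_scope)
  delay_mode <- match.arg(delay_mode)
  critic_coding <- match.arg(critic_coding)
  engine <- match.arg(engine)
  dat <- prep_session(training, test, n_actions, critic_coding)
  if (engine == "cpp") {
    cpp_session_loglik(dat$block, dat$stim_local, dat$action, dat$reward,
                       dat$critic_reward, dat$block_ns, dat$n_actions,
                       dat$test_i, dat$test_j, dat$test_choice,
                       par_vector(params), decay_scope == "pair",
                       delay_mode_code(delay_mode))
  } else {
    loglik_trace(dat, params, decay_scope, delay_mode)
  }
}

# step-by-step R trace over the exported scalar operations
loglik_trace <- function(dat, params, decay_scope, delay_mode = "trials") {
  nB <- length(dat$block_ns)
  offsets <- c(0L, cumsum(dat$block_ns))
  V_glob <- rep(1 / dat$n_actions, sum(dat$block_ns))
  ll <- 0
  state <- NULL
  cur <- -1L
  for (t in seq_along(dat$block)) {
    b <- dat$block[t]
    if (b != cur) {
      state <- init_state(dat$block_ns[b + 1L], dat$n_actions)
      cur <- b
    }
    s <- dat$stim_local[t] + 1L
    a <- dat$action[t] + 1L
    r <- dat$reward[t]
    pr <- policy_probs(state, s, params)
    ll <- ll + log(pr$p[a])
    # delay counters: the current stimulus becomes an intervening item for
    # every other stimulus; a correct response resets the current stimulus
    ns <- nrow(state$Q)
    if (delay_mode == "trials") {
      if (r == 1) state$delay[s] <- 0L
      state$delay <- state$delay + 1L
    } else {
      if (delay_mode == "gap") {
        state$delay[s] <- state$delay[s] + state$pending[s]
        state$pending[s] <- 0L
        state$seen[s, ] <- FALSE
      }
      if (r == 1) {
        state$delay[s] <- 0L
        state$pending[s] <- 0L
        state$seen[s, ] <- FALSE
      }
      for (k in seq_len(ns)) {
        if (k != s && !state$seen[k, s]) {
          state$seen[k, s] <- TRUE
          state$pending[k] <- state$pending[k] + 1L
        }
      }
    }
    state$Q[s, a] <- rl_update(state$Q[s, a], r, params)
    state$WM[s, a] <- wm_update(state$WM[s, a], r, params)
    state$V[s] <- critic_update(state$V[s], dat$critic_reward[t], params)
    state <- wm_decay(state, s, a, params, decay_scope)
    V_glob[offsets[b + 1L] + s] <- state$V[s]
  }
  for (t in seq_along(dat$test_i)) {
    pa <- test_choice_prob(V_glob[dat$test_i[t] + 1L],
                           V_glob[dat$test_j[t] + 1L], params)
    ll <- ll + log(if (dat$test_choice[t] == 0L) pa else 1 - pa)
  }
  ll
}
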