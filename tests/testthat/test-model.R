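test_that("scalar update rules match their closed forms", {
  p <- default_params(alpha_rl = 0.03, gamma = 0.4)
  # RL: one delta-rule step toward 1 on reward, discounted step toward 0 on error
  expect_equal(rl_update(1 / 3, 1, p), 1 / 3 + 0.03 * 2 / 3)
  expect_equal(rl_update(0.5, 0, default_params(gamma = 0)), 0.5)
  expect_equal(rl_update(1, 1, p), 1)
  # WM: one-shot encoding, multiplicative shrink on error
  expect_equal(wm_update(0.5, 1, p), 1)
  expect_equal(wm_update(0.5, 0, p), 0.3)
  expect_equal(wm_update(1 / 3, 0, default_params(gamma = 0)), 1 / 3)
  expect_error(wm_update(0.5, 2, p), "0 or 1")
  expect_error(rl_update(0.5, -1, p), "0 or 1")
  # critic: same form as RL, supports point-valued rewards
  expect_equal(critic_update(1 / 3, 1, p), 1 / 3 + 0.03 * 2 / 3)
  expect_equal(critic_update(0.7, 0, default_params(gamma = 0)), 0.7)
  expect_equal(critic_update(0.5, 2, default_params(alpha_rl = 0.1)), 0.65)
})

test_that("WM decay relaxes unobserved entries toward the uniform prior", {
  p <- default_params(phi = 0.3)
  st <- init_state(2, 3)
  st$WM[1, 1] <- 1
  st$WM[2, 2] <- 0.9
  out <- wm_decay(st, stimulus = 1, action = 1, p)
  expect_equal(out$WM[1, 1], 1)                   # observed pair exempt
  expect_equal(out$WM[2, 2], 0.9 + 0.3 * (1 / 3 - 0.9))
  expect_equal(out$WM[1, 2], 1 / 3)               # fixed point at prior
  # stimulus-level scope exempts the whole row
  st$WM[1, 2] <- 0.8
  out2 <- wm_decay(st, 1, 1, p, scope = "stimulus")
  expect_equal(out2$WM[1, 2], 0.8)
  # phi = 0 leaves everything unchanged
  expect_equal(wm_decay(st, 1, 1, default_params(phi = 0))$WM, st$WM)
  # single decayed entry: 1 -> 0.8 at phi = 0.3, three actions
  st3 <- init_state(2, 3); st3$WM[2, 1] <- 1
  expect_equal(wm_decay(st3, 1, 1, p)$WM[2, 1], 0.8)
})

test_that("repeated decay converges geometrically at rate 1 - phi", {
  p <- default_params(phi = 0.25)
  st <- init_state(2, 3)
  st$WM[2, 3] <- 1
  dev0 <- 1 - 1 / 3
  for (t in 1:12) {
    st <- wm_decay(st, 1, 1, p)
    expect_equal(st$WM[2, 3] - 1 / 3, dev0 * 0.75^t)
  }
})

test_that("the WM weight follows the capacity-to-delay ratio", {
  expect_equal(wm_weight(default_params(rho = 0.8, wm_cap = 3), 6), 0.4)
  p <- default_params(rho = 0.6, wm_cap = 4)
  for (nd in 0:4) expect_equal(wm_weight(p, nd), 0.6)
  expect_equal(wm_weight(p, 8), 0.3)
  expect_equal(wm_weight(default_params(rho = 0), 17), 0)
})

test_that("initial state is uniform and rng-independent", {
  st <- init_state(5, 3)
  expect_true(all(st$Q == 1 / 3) && all(st$WM == 1 / 3) && all(st$V == 1 / 3))
  expect_true(all(init_state(2, 4)$Q == 0.25))
  set.seed(1); a <- init_state(3, 3); set.seed(999); b <- init_state(3, 3)
  expect_identical(a, b)
})

test_that("policy probabilities mix softmax policies and stay normalised", {
  p <- default_params(rho = 1, wm_cap = 5)
  st <- init_state(3, 3)
  pr <- policy_probs(st, 1, p)
  expect_equal(pr$p, rep(1 / 3, 3))
  # saturated WM entry: closed-form softmax with beta = 50
  st$WM[1, ] <- c(1, 1 / 3, 1 / 3)
  pr <- policy_probs(st, 1, p)
  expect_equal(pr$p[1], exp(50) / (exp(50) + 2 * exp(50 / 3)))
  expect_gte(pr$p[1], 1 - 2 * exp(-100 / 3))
  # omega = 0 collapses the mixture onto the RL policy
  p0 <- default_params(rho = 0)
  st$Q[1, ] <- c(0.9, 0.2, 0.4)
  pr0 <- policy_probs(st, 1, p0)
  expect_identical(pr0$p, pr0$p_rl)
  # normalisation and omega bounds over random states and parameters
  set.seed(42)
  for (i in 1:200) {
    ns <- sample(2:5, 1)
    st <- init_state(ns, 3)
    st$Q[] <- runif(ns * 3); st$WM[] <- runif(ns * 3)
    st$delay <- sample(0:12, ns, replace = TRUE)
    pp <- default_params(rho = runif(1), wm_cap = sample(2:5, 1))
    pr <- policy_probs(st, sample(ns, 1), pp)
    expect_equal(sum(pr$p), 1, tolerance = 1e-12)
    expect_equal(sum(pr$p_rl), 1, tolerance = 1e-12)
    expect_lte(pr$omega, pp$rho)
  }
})

test_that("test-phase choice rule bounds probabilities by the guess rate", {
  expect_equal(test_choice_prob(0.9, 0.1, default_params(nu = 1)), 0.5)
  expect_equal(test_choice_prob(0.4, 0.4, default_params(nu = 0.3)), 0.5)
  p <- default_params(nu = 0.1)
  expect_equal(test_choice_prob(0.8, 0.2, p),
               0.05 + 0.9 * stats::plogis(50 * 0.6))
  expect_gte(test_choice_prob(1, 0, p), 0.05)
  expect_lte(test_choice_prob(0, 1, p), 0.95)
})

test_that("values stay in [0, 1] under arbitrary update sequences", {
  set.seed(7)
  p <- default_params(alpha_rl = runif(1), gamma = runif(1), phi = runif(1))
  q <- w <- v <- 1 / 3
  for (i in 1:10000) {
    r <- rbinom(1, 1, 0.5)
    q <- rl_update(q, r, p)
    w <- wm_update(w, r, p)
    v <- critic_update(v, r, p)
    if (i %% 3 == 0) w <- w + p$phi * (1 / 3 - w)
    expect_true(q >= 0 && q <= 1 && w >= 0 && w <= 1 && v >= 0 && v <= 1)
  }
})

test_that("compiled and plain-R likelihoods agree in every model variant", {
  set.seed(14)
  cfg <- mini_config()
  p <- default_params()
  des <- build_test_pairs(generate_task(cfg), 3)
  for (dm in c("trials", "gap", "window")) {
    for (ds in c("pair", "stimulus")) {
      sim <- simulate_subject(des, p, delay_mode = dm, decay_scope = ds)
      a <- session_loglik(sim$training, p, sim$test, delay_mode = dm,
                          decay_scope = ds)
      b <- session_loglik(sim$training, p, sim$test, delay_mode = dm,
                          decay_scope = ds, engine = "r")
      expect_lt(abs(a - b), 1e-10)
    }
  }
  sim <- simulate_subject(des, p, critic_coding = "points")
  a <- session_loglik(sim$training, p, sim$test, critic_coding = "points")
  b <- session_loglik(sim$training, p, sim$test, critic_coding = "points",
                      engine = "r")
  expect_lt(abs(a - b), 1e-10)
})

test_that("a frozen uniform policy yields N log(1/3) and nu = 1 adds log(1/2)", {
  p <- default_params(rho = 0, alpha_rl = 0)
  tr <- block_table(stimulus = c(0, 1, 0, 1, 1, 0),
                    action = c(0, 1, 2, 0, 1, 2),
                    correct = c(1, 0, 0, 1, 1, 0))
  expect_equal(session_loglik(tr, p), 6 * log(1 / 3))
  te <- data.frame(left_stimulus = 0L, right_stimulus = 1L, choice = "left")
  p1 <- default_params(rho = 0, alpha_rl = 0, nu = 1)
  expect_equal(session_loglik(tr, p1, te), 6 * log(1 / 3) + log(1 / 2))
})

test_that("likelihood validates its inputs", {
  p <- default_params()
  tr <- block_table(stimulus = c(0, 1, 0), action = c(0, 1, 2),
                    correct = c(1, 0, 1))
  te_bad <- data.frame(left_stimulus = 0L, right_stimulus = 99L,
                       choice = "left")
  expect_error(session_loglik(tr, p, te_bad), "not in training")
  tr_bad <- tr; tr_bad$trial_index <- c(3, 2, 1)
  expect_error(session_loglik(tr_bad, p), "time-ordered")
  tr_noncontig <- rbind(tr, transform(tr, block_id = 2,
                                      stimulus_id = stimulus_id + 10), tr)
  tr_noncontig$trial_index <- NULL
  expect_error(session_loglik(tr_noncontig, p), "contiguous")
})

test_that("with rho = 0 the likelihood is exactly invariant to phi and wm_cap", {
  set.seed(5)
  sim <- sim_one(default_params(rho = 0, alpha_rl = 0.05), mini_config())
  ref <- session_loglik(sim$training, default_params(rho = 0, alpha_rl = 0.05,
                                                     phi = 0, wm_cap = 2),
                        sim$test)
  for (phi in c(0.2, 0.9)) {
    for (cap in 2:5) {
      ll <- session_loglik(sim$training,
                           default_params(rho = 0, alpha_rl = 0.05,
                                          phi = phi, wm_cap = cap), sim$test)
      expect_identical(ll, ref)
    }
  }
})
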