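# shared builders for small, fully controlled fixtures

mini_config <- function(...) {
  task_config(set_sizes = c(2, 3),
              blocks_per_set_size = c("2" = 1, "3" = 1), ...)
}

default_params <- function(...) {
  args <- utils::modifyList(
    list(alpha_rl = 0.03, gamma = 0.4, phi = 0.1, rho = 0.85,
         wm_cap = 3, nu = 0.07),
    list(...))
  do.call(model_params, args)
}

# one simulated subject on a design of the given config
sim_one <- function(params = default_params(), config = task_config(),
                    pairs_per_stimulus = 4, ...) {
  des <- build_test_pairs(generate_task(config), pairs_per_stimulus)
  c(simulate_subject(des, params, ...), list(design = des))
}

# hand-built single-block training table from explicit vectors
block_table <- function(stimulus, action, correct, block_id = 1,
                        set_size = length(unique(stimulus))) {
  data.frame(subject_id = 1L, session_label = "PBO", block_id = block_id,
             set_size = set_size, trial_index = seq_along(stimulus),
             stimulus_id = stimulus, action = action, correct = correct,
             points = ifelse(correct == 1, 2L, 0L))
}
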