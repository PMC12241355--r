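#' Task configuration for the set-size learning paradigm
#'
#' Describes the block and reward structure of the stimulus-response learning
#' task: blocks of 2-5 novel stimuli, each presented for a fixed number of
#' iterations in pseudo-random order, with one of `n_actions` responses correct
#' per stimulus and probabilistic +1/+2 point feedback on correct responses.
#'
#' @param set_sizes Integer vector of block set sizes (each in 2..5).
#' @param blocks_per_set_size Named integer vector: number of blocks at each
#'   set size. Names must match `set_sizes`. Between 2 and 3 blocks per set
#'   size is typical; the default uses more blocks for the smaller sets.
#' @param iterations Number of presentations of every stimulus within its
#'   block (default 9).
#' @param n_actions Number of response options (default 3).
#' @param reward_points Named probability vector over the points awarded on a
#'   correct trial. Default `c("1" = 0.2, "2" = 0.8)`: +2 with probability
#'   0.8, +1 with probability 0.2. Incorrect trials always earn 0.
#' @param seed Optional integer seed making `generate_task()` deterministic.
#'
#' @return An object of class `rlwm_task_config`.
#' @export
task_config <- function(set_sizes = 2:5,
                        blocks_per_set_size = c("2" = 3, "3" = 3, "4" = 2, "5" = 2),
                        iterations = 9,
                        n_actions = 3,
                        reward_points = c("1" = 0.2, "2" = 0.8),
                        seed = NULL) {
  stopifnot(length(set_sizes) >= 1, iterations >= 1, n_actions >= 2)
  if (any(set_sizes < 2 | set_sizes > 5)) {
    stop("set_sizes must lie in [2, 5]", call. = FALSE)
  }
  if (!all(as.character(set_sizes) %in% names(blocks_per_set_size))) {
    stop("blocks_per_set_size must name every set size", call. = FALSE)
  }
  if (abs(sum(reward_points) - 1) > 1e-12 || any(reward_points < 0)) {
    stop("reward_points must be a probability distribution", call. = FALSE)
  }
  structure(
    list(set_sizes = as.integer(set_sizes),
         blocks_per_set_size = blocks_per_set_size,
         iterations = as.integer(iterations),
         n_actions = as.integer(n_actions),
         reward_points = reward_points,
         seed = seed),
    class = "rlwm_task_config"
  )
}

# one pseudo-random sequence: `iterations` balanced sweeps over the stimuli,
# each sweep shuffled, with immediate repeats across sweep boundaries rejected
make_sequence <- function(set_size, iterations) {
  if (set_size < 2) {
    stop("cannot build a no-repeat sequence with fewer than 2 stimuli",
         call. = FALSE)
  }
  seq_out <- integer(0)
  last <- NA_integer_
  for (it in seq_len(iterations)) {
    repeat {
      sweep <- sample.int(set_size)
      if (is.na(last) || sweep[1L] != last) break
    }
    seq_out <- c(seq_out, sweep)
    last <- sweep[set_size]
  }
  seq_out
}

#' Generate a task instance
#'
#' Builds the full training design: block order shuffled across set sizes,
#' fresh stimuli for every block (opaque integer IDs, unique across blocks),
#' a random correct action per stimulus (several stimuli may share an action),
#' and a pseudo-random trial sequence in which every stimulus appears exactly
#' `iterations` times with no immediate repeats.
#'
#' @param config An `rlwm_task_config`.
#' @return An `rlwm_design`: list with `config`, `blocks` (data.frame:
#'   `block_id`, `set_size`, `stimulus_id`, `correct_action`), and `trials`
#'   (data.frame: `block_id`, `set_size`, `trial_index`, `stimulus_id`,
#'   `correct_action`). Action indices are 0-based.
#' @export
generate_task <- function(config) {
  stopifnot(inherits(config, "rlwm_task_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sizes <- rep(config$set_sizes,
               times = config$blocks_per_set_size[as.character(config$set_sizes)])
  sizes <- sizes[sample.int(length(sizes))]
  n_blocks <- length(sizes)
  next_stim <- 0L
  blocks <- vector("list", n_blocks)
  trials <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    ns <- sizes[b]
    stim <- next_stim + seq_len(ns) - 1L
    next_stim <- next_stim + ns
    ca <- sample.int(config$n_actions, ns, replace = TRUE) - 1L
    blocks[[b]] <- data.frame(block_id = b, set_size = ns,
                              stimulus_id = stim, correct_action = ca)
    idx <- make_sequence(ns, config$iterations)
    trials[[b]] <- data.frame(block_id = b, set_size = ns,
                              trial_index = seq_along(idx),
                              stimulus_id = stim[idx],
                              correct_action = ca[idx])
  }
  structure(
    list(config = config,
         blocks = do.call(rbind, blocks),
         trials = do.call(rbind, trials),
         test_pairs = NULL),
    class = "rlwm_design"
  )
}

#' Build surprise test-phase pairs
#'
#' Samples stimulus pairs from across all training blocks, without replacement
#' from the set of all unordered pairs, until every stimulus appears in at
#' least `pairs_per_stimulus` pairs. Left/right screen side is randomised.
#'
#' @param design An `rlwm_design`.
#' @param pairs_per_stimulus Minimum number of pairs each stimulus must
#'   appear in (default 4).
#' @return The design with a `test_pairs` data.frame added: `pair_id`,
#'   `left_stimulus`, `right_stimulus`.
#' @export
build_test_pairs <- function(design, pairs_per_stimulus = 4) {
  stopifnot(inherits(design, "rlwm_design"))
  stim <- design$blocks$stimulus_id
  if (length(stim) < 2) stop("need at least 2 stimuli to form pairs", call. = FALSE)
  all_pairs <- utils::combn(stim, 2)
  ord <- sample.int(ncol(all_pairs))
  need <- stats::setNames(rep(pairs_per_stimulus, length(stim)), stim)
  keep <- logical(ncol(all_pairs))
  for (k in ord) {
    a <- as.character(all_pairs[1, k]); b <- as.character(all_pairs[2, k])
    if (need[a] > 0 || need[b] > 0) {
      keep[k] <- TRUE
      need[a] <- need[a] - 1L
      need[b] <- need[b] - 1L
    }
    if (all(need <= 0)) break
  }
  sel <- all_pairs[, ord[keep[ord]], drop = FALSE]
  flip <- sample(c(TRUE, FALSE), ncol(sel), replace = TRUE)
  left <- ifelse(flip, sel[2, ], sel[1, ])
  right <- ifelse(flip, sel[1, ], sel[2, ])
  design$test_pairs <- data.frame(pair_id = seq_along(left),
                                  left_stimulus = left, right_stimulus = right)
  design
}

#' Write / read a task design as delimited text
#'
#' The trial table (one row per trial) and the pairs table round-trip through
#' CSV with a header row; action indices are 0-based.
#'
#' @param design An `rlwm_design`.
#' @param trials_path,pairs_path Output CSV paths (`pairs_path` optional).
#' @return `write_design` returns the paths invisibly.
#' @export
write_design <- function(design, trials_path, pairs_path = NULL) {
  utils::write.csv(design$trials, trials_path, row.names = FALSE)
  if (!is.null(pairs_path) && !is.null(design$test_pairs)) {
    utils::write.csv(design$test_pairs, pairs_path, row.names = FALSE)
  }
  invisible(c(trials_path, pairs_path))
}
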