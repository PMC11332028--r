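#' Task configuration for the two-arm reversal bandit
#'
#' Defaults encode the reference design: 60 trials, win probabilities 0.8/0.2
#' yoked across the two arms, reversing 4 times every 12 +/- 1 trials, with
#' wins worth 100 points (stored internally on a 0/1 scale).
#'
#' @param n_trials number of decision trials
#' @param n_reversals number of unsignalled probability reversals
#' @param block_length_mean mean trials per block between reversals
#' @param block_length_jitter uniform jitter (in trials) around the mean
#' @param p_win_good win probability of the currently good arm
#' @param p_win_bad win probability of the currently bad arm
#' @param reward_points points displayed for a win (cosmetic; rewards are 0/1)
#' @param seed integer seed controlling schedule randomness
#' @return an object of class `task_config`
#' @export
task_config <- function(n_trials = 60, n_reversals = 4,
                        block_length_mean = 12, block_length_jitter = 1,
                        p_win_good = 0.8, p_win_bad = 0.2,
                        reward_points = 100, seed = 1L) {
  stopifnot(n_trials >= n_reversals + 1,
            p_win_bad > 0, p_win_good < 1, p_win_bad < p_win_good,
            block_length_jitter >= 0, block_length_mean >= 1)
  structure(list(n_trials = as.integer(n_trials),
                 n_reversals = as.integer(n_reversals),
                 block_length_mean = block_length_mean,
                 block_length_jitter = block_length_jitter,
                 p_win_good = p_win_good, p_win_bad = p_win_bad,
                 reward_points = reward_points, seed = as.integer(seed)),
            class = "task_config")
}

#' Generate a reversal schedule
#'
#' Block lengths are drawn uniformly from
#' `block_length_mean +/- block_length_jitter`; the final block absorbs the
#' remainder so the schedule has exactly `n_trials` trials and exactly
#' `n_reversals` reversals. The identity of the initially good arm is
#' randomized. Deterministic given `config$seed`.
#'
#' @param config a [task_config()]
#' @return an object of class `task_schedule` with elements `good_arm`
#'   (0/1 per trial), `p_win` (trials x 2 matrix), `within_block_trial`
#'   (restarting at 1 after every reversal), `reversal_trials` (first trial
#'   of each post-reversal block), and the generating `config`
#' @export
generate_task_schedule <- function(config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  n_blocks <- config$n_reversals + 1L
  min_len <- max(1, config$block_length_mean - config$block_length_jitter)
  if ((n_blocks - 1L) * min_len + 1L > config$n_trials) {
    stop("schedule infeasible: minimal blocks exceed n_trials")
  }
  set.seed(config$seed)
  lens <- NULL
  for (attempt in 1:100) {
    cand <- sample(seq(config$block_length_mean - config$block_length_jitter,
                       config$block_length_mean + config$block_length_jitter),
                   n_blocks, replace = TRUE)
    cand[n_blocks] <- config$n_trials - sum(cand[-n_blocks])
    if (cand[n_blocks] >= 1) { lens <- cand; break }
  }
  if (is.null(lens)) stop("schedule infeasible: could not place final block")
  start_arm <- sample(0:1, 1)
  block_id <- rep(seq_len(n_blocks), times = lens)
  good_arm <- (start_arm + block_id - 1L) %% 2L
  within <- unlist(lapply(lens, seq_len), use.names = FALSE)
  p_win <- matrix(config$p_win_bad, nrow = config$n_trials, ncol = 2)
  p_win[cbind(seq_len(config$n_trials), good_arm + 1L)] <- config$p_win_good
  reversal_trials <- if (n_blocks > 1) cumsum(lens)[-n_blocks] + 1L
                     else integer(0)
  structure(list(good_arm = good_arm, p_win = p_win,
                 within_block_trial = within,
                 reversal_trials = as.integer(reversal_trials),
                 config = config),
            class = "task_schedule")
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("Reversal bandit schedule: %d trials, %d reversals at trials %s\n",
              length(x$good_arm), length(x$reversal_trials),
              paste(x$reversal_trials, collapse = ", ")))
  invisible(x)
}
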