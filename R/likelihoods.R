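#' Rescorla-Wagner log-likelihood and value trajectory
#'
#' Evaluates per-trial softmax choice probabilities under the delta-rule
#' learner: values of both arms start at `q0` (0.5, the midpoint of the 0/1
#' reward scale), the chosen arm's value is updated after each trial by
#' `alpha * (r - Q)`, and choice probabilities follow a softmax with inverse
#' temperature `beta`.
#'
#' @param params list with `alpha` in \[0,1\] and `beta` >= 0
#' @param data data.frame with integer `choice` (0/1) and `reward` (0/1)
#' @param q0 initial option value
#' @return list with `loglik` (total), `logp` (per trial), `Q` (trials x 2
#'   pre-update values), `rpe`, and `q_chosen`
#' @export
rw_loglik <- function(params, data, q0 = 0.5) {
  check_choice_data(data)
  stopifnot(params$alpha >= 0, params$alpha <= 1, params$beta >= 0)
  tr <- rw_trace_cpp(params$alpha, params$beta,
                     as.integer(data$choice), as.integer(data$reward), q0)
  list(loglik = sum(tr$logp), logp = tr$logp, Q = tr$Q,
       rpe = tr$rpe, q_chosen = tr$q_chosen)
}

#' Win-stay/lose-shift log-likelihood
#'
#' The first trial has probability 0.5; thereafter the rule-consistent action
#' (repeat after a win, switch after a loss) is emitted with probability
#' `epsilon`.
#'
#' @param params list with `epsilon` in \[0,1\]
#' @param data data.frame with `choice` and `reward` columns
#' @return list with `loglik` and per-trial `logp`
#' @export
wsls_loglik <- function(params, data) {
  check_choice_data(data)
  stopifnot(params$epsilon >= 0, params$epsilon <= 1)
  logp <- wsls_pointwise_one_cpp(params$epsilon,
                                 as.integer(data$choice),
                                 as.integer(data$reward))
  list(loglik = sum(logp), logp = logp)
}

#' Bayesian two-state filter log-likelihood
#'
#' A forward filter over the two hidden task states ("arm 0 is good" / "arm 1
#' is good"). Each trial the previous posterior is mixed by the symmetric
#' transition matrix with switch probability `p_switch`; the action
#' probability of the chosen arm is the transitioned prior probability that
#' that arm is state-correct (probability matching); the reward observation
#' then updates the posterior through `p_reward`.
#'
#' @param params list with `p_reward` in (0.5, 1) and `p_switch` in (0, 0.5)
#' @param data data.frame with `choice` and `reward` columns
#' @return list with `loglik`, per-trial `logp`, and the `prior` and
#'   `posterior` state-probability trajectories (trials x 2)
#' @export
bayes_filter_loglik <- function(params, data) {
  check_choice_data(data)
  stopifnot(params$p_reward >= 0.5, params$p_reward < 1,
            params$p_switch >= 0, params$p_switch <= 0.5)
  tr <- bayes_trace_cpp(params$p_reward, params$p_switch,
                        as.integer(data$choice), as.integer(data$reward))
  list(loglik = sum(tr$logp), logp = tr$logp,
       prior = tr$prior, posterior = tr$posterior)
}

check_choice_data <- function(data) {
  stopifnot(is.data.frame(data), all(c("choice", "reward") %in% names(data)))
  if (!all(data$choice %in% 0:1)) stop("choices must be coded 0/1")
  if (!all(data$reward %in% 0:1)) {
    stop("rewards must be coded 0/1 (divide point totals by reward_points)")
  }
  invisible(TRUE)
}
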