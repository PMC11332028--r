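#' Specify a generative decision agent
#'
#' Three agent families are supported: a Rescorla-Wagner learner (`"rw"`,
#' parameters `alpha` in \[0,1\] and `beta` >= 0), a win-stay/lose-shift
#' heuristic (`"wsls"`, rule-adherence probability `epsilon` in \[0,1\]), and
#' a two-state Bayesian filter (`"bayes"`, `p_reward` in (0.5, 1) and
#' `p_switch` in (0, 0.5)).
#'
#' @param model one of `"rw"`, `"wsls"`, `"bayes"`
#' @param ... named parameters for the chosen model
#' @return an object of class `agent_spec`
#' @export
agent_spec <- function(model = c("rw", "wsls", "bayes"), ...) {
  model <- match.arg(model)
  p <- list(...)
  if (model == "rw") {
    stopifnot(is.numeric(p$alpha), p$alpha >= 0, p$alpha <= 1,
              is.numeric(p$beta), p$beta >= 0)
    p <- p[c("alpha", "beta")]
  } else if (model == "wsls") {
    stopifnot(is.numeric(p$epsilon), p$epsilon >= 0, p$epsilon <= 1)
    p <- p["epsilon"]
  } else {
    stopifnot(is.numeric(p$p_reward), p$p_reward > 0.5, p$p_reward < 1,
              is.numeric(p$p_switch), p$p_switch > 0, p$p_switch < 0.5)
    p <- p[c("p_reward", "p_switch")]
  }
  structure(list(model = model, params = p), class = "agent_spec")
}

# Memorability ratings emulate a pool of highly memorable face stimuli:
# normed d-prime scores from a truncated normal with high mean and modest
# spread.
draw_pm_scores <- function(n, mean = 2, sd = 0.3, lower = 0.5, upper = 3.5) {
  out <- rnorm(n, mean, sd)
  bad <- out < lower | out > upper
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < lower | out > upper
  }
  out
}

#' Simulate one agent on a bandit schedule
#'
#' Choices follow the named agent's action rule; rewards are drawn from the
#' scheduled arm win probabilities; each trial carries a unique stimulus with
#' a memorability d-prime score. For Rescorla-Wagner agents the generative
#' value trajectory and trial-level reward prediction errors are returned as
#' columns (`q_chosen`, `rpe`); for the other agents these are `NA`.
#'
#' @param spec an [agent_spec()]
#' @param schedule a [generate_task_schedule()] result
#' @param seed integer seed
#' @param subject subject identifier stored in the output
#' @return a data.frame with one row per trial: `subject`, `trial`, `choice`
#'   (0/1), `reward` (0/1), `pm`, `within_block_trial`, `q_chosen`, `rpe`;
#'   the schedule is attached as attribute `"schedule"`
#' @export
simulate_agent <- function(spec, schedule, seed = 1L, subject = 1L) {
  stopifnot(inherits(spec, "agent_spec"), inherits(schedule, "task_schedule"))
  set.seed(seed)
  n <- length(schedule$good_arm)
  choice <- integer(n); reward <- integer(n)
  q_chosen <- rep(NA_real_, n); rpe <- rep(NA_real_, n)
  if (spec$model == "rw") {
    q <- c(0.5, 0.5)
    alpha <- spec$params$alpha; beta <- spec$params$beta
    for (t in seq_len(n)) {
      p1 <- plogis(beta * (q[2] - q[1]))
      choice[t] <- rbinom(1, 1, p1)
      reward[t] <- rbinom(1, 1, schedule$p_win[t, choice[t] + 1])
      q_chosen[t] <- q[choice[t] + 1]
      rpe[t] <- reward[t] - q[choice[t] + 1]
      q[choice[t] + 1] <- q[choice[t] + 1] + alpha * rpe[t]
    }
  } else if (spec$model == "wsls") {
    eps <- spec$params$epsilon
    for (t in seq_len(n)) {
      if (t == 1) {
        choice[t] <- rbinom(1, 1, 0.5)
      } else {
        rule <- if (reward[t - 1] == 1) choice[t - 1] else 1 - choice[t - 1]
        choice[t] <- if (runif(1) < eps) rule else 1 - rule
      }
      reward[t] <- rbinom(1, 1, schedule$p_win[t, choice[t] + 1])
    }
  } else {
    pr <- spec$params$p_reward; ps <- spec$params$p_switch
    pri <- c(0.5, 0.5) # P(arm 0 is good), P(arm 1 is good)
    for (t in seq_len(n)) {
      choice[t] <- rbinom(1, 1, pri[2]) # probability matching on the posterior
      reward[t] <- rbinom(1, 1, schedule$p_win[t, choice[t] + 1])
      lik <- vapply(0:1, function(s) {
        p <- if (choice[t] == s) pr else 1 - pr
        if (reward[t] == 1) p else 1 - p
      }, numeric(1))
      post <- pri * lik
      post <- post / sum(post)
      pri <- c((1 - ps) * post[1] + ps * post[2],
               (1 - ps) * post[2] + ps * post[1])
    }
  }
  out <- data.frame(subject = subject, trial = seq_len(n),
                    choice = choice, reward = reward,
                    pm = draw_pm_scores(n),
                    within_block_trial = schedule$within_block_trial,
                    q_chosen = q_chosen, rpe = rpe)
  attr(out, "schedule") <- schedule
  attr(out, "spec") <- spec
  out
}

#' Simulate a cohort of agents
#'
#' Each subject receives its own jittered schedule and an independent random
#' stream, both derived deterministically from `seed`.
#'
#' @param specs list of [agent_spec()] objects, one per subject
#' @param config a [task_config()] shared by the cohort
#' @param seed master integer seed
#' @return a data.frame stacking per-subject trials; per-subject schedules are
#'   attached as attribute `"schedules"`
#' @export
simulate_cohort <- function(specs, config = task_config(), seed = 1L) {
  stopifnot(length(specs) >= 1)
  schedules <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, 1L, i)
    schedules[[i]] <- generate_task_schedule(cfg)
    rows[[i]] <- simulate_agent(specs[[i]], schedules[[i]],
                                seed = derive_seed(seed, 2L, i), subject = i)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "schedules") <- schedules
  out
}
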