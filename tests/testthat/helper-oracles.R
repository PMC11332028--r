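# Independent (slow, R-native) likelihood oracles used to cross-check the
# compiled implementations by brute-force per-trial enumeration.

oracle_rw <- function(alpha, beta, choice, reward, q0 = 0.5) {
  q <- c(q0, q0)
  lp <- numeric(length(choice))
  rpe <- numeric(length(choice))
  for (t in seq_along(choice)) {
    num <- exp(beta * q)
    p <- num / sum(num)
    lp[t] <- log(p[choice[t] + 1])
    rpe[t] <- reward[t] - q[choice[t] + 1]
    q[choice[t] + 1] <- q[choice[t] + 1] + alpha * rpe[t]
  }
  list(logp = lp, rpe = rpe)
}

oracle_wsls <- function(eps, choice, reward) {
  lp <- numeric(length(choice))
  lp[1] <- log(0.5)
  for (t in seq_along(choice)[-1]) {
    rule <- if (reward[t - 1] == 1) choice[t - 1] else 1 - choice[t - 1]
    lp[t] <- log(if (choice[t] == rule) eps else 1 - eps)
  }
  lp
}

oracle_bayes <- function(p_reward, p_switch, choice, reward) {
  prior <- c(0.5, 0.5)
  trans <- matrix(c(1 - p_switch, p_switch, p_switch, 1 - p_switch), 2, 2)
  lp <- numeric(length(choice))
  for (t in seq_along(choice)) {
    lp[t] <- log(prior[choice[t] + 1])
    lik <- vapply(0:1, function(s) {
      pr <- if (choice[t] == s) p_reward else 1 - p_reward
      if (reward[t] == 1) pr else 1 - pr
    }, numeric(1))
    post <- prior * lik / sum(prior * lik)
    prior <- as.vector(trans %*% post)
  }
  lp
}

# Direct WAIC evaluation from a pointwise log-likelihood table.
oracle_waic <- function(ll) {
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(apply(ll, 2, var))
  -2 * (lppd - p)
}

# Shared small fixtures (built once per test run).
fixture_env <- new.env(parent = emptyenv())

fixture_rw_cohort <- function() {
  if (is.null(fixture_env$rw_cohort)) {
    set.seed(401)
    specs <- lapply(1:10, function(i)
      agent_spec("rw", alpha = runif(1, 0.5, 0.9), beta = runif(1, 3, 8)))
    fixture_env$rw_cohort <- simulate_cohort(specs, task_config(), seed = 402)
  }
  fixture_env$rw_cohort
}
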