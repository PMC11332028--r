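test_that("the posterior recovers generating parameters on a long series", {
  cfg <- task_config(n_trials = 500, n_reversals = 40, seed = 61)
  sch <- generate_task_schedule(cfg)
  dat <- simulate_agent(agent_spec("rw", alpha = 0.7, beta = 5), sch,
                        seed = 62)
  fit <- fit_model("rw", dat, chains = 2, draws = 2000, warmup = 2000,
                   seed = 63)
  alpha_draws <- as.vector(fit$draws[, , "alpha"])
  ci <- quantile(alpha_draws, c(0.025, 0.975))
  expect_gt(0.7, ci[1])
  expect_lt(0.7, ci[2])
  expect_lt(abs(fit$point_estimate[["alpha"]] - 0.7), 0.15)
})

test_that("degenerate constant-choice data are refused", {
  d <- data.frame(choice = rep(1, 30), reward = rbinom(30, 1, 0.5))
  expect_error(fit_model("rw", d), "degenerate")
})

test_that("WAIC reduces to the plug-in deviance for a single draw", {
  ll <- matrix(log(c(0.5, 0.25, 0.8)), nrow = 1)
  w <- waic(ll)
  expect_equal(w$waic, -2 * sum(ll))
  expect_equal(w$p_waic, 0)
})

test_that("WAIC matches direct formula evaluation on a toy table", {
  set.seed(64)
  ll <- matrix(log(runif(6, 0.2, 0.9)), nrow = 3) # 3 draws x 2 trials
  expect_equal(waic(ll)$waic, oracle_waic(ll))
  # invariant to reordering of posterior draws
  expect_equal(waic(ll[c(3, 1, 2), ])$waic, waic(ll)$waic)
})

test_that("a Rescorla-Wagner cohort is won by the Rescorla-Wagner model", {
  ch <- fixture_rw_cohort()
  ids <- unique(ch$subject)
  fits <- lapply(ids, function(s) {
    d <- ch[ch$subject == s, ]
    list(rw = fit_model("rw", d, chains = 2, draws = 800, warmup = 800,
                        seed = 65 + s),
         wsls = fit_model("wsls", d, chains = 2, draws = 800, warmup = 800,
                          seed = 165 + s),
         bayes = fit_model("bayes", d, chains = 2, draws = 800,
                           warmup = 800, seed = 265 + s))
  })
  cmp <- compare_models(fits)
  expect_equal(names(which.max(cmp$counts)), "rw")
  expect_s3_class(cmp$chisq, "htest")
  # comparison refuses fits on different trial sets
  short <- fits
  short[[1]]$wsls <- fit_model("wsls", ch[ch$subject == ids[1], ][1:30, ],
                               chains = 2, draws = 200, warmup = 200,
                               seed = 66)
  expect_error(compare_models(short), "different trial counts")
})

test_that("extracted RPEs reproduce the forward pass at the posterior mean", {
  d <- data.frame(choice = c(0, 0, 1), reward = c(1, 0, 1))
  fake <- structure(list(model = "rw",
                         point_estimate = c(alpha = 0.5, beta = 2)),
                    class = "rl_fit")
  r <- extract_rpes(fake, d)
  expect_equal(r$rpe, c(0.5, -0.75, 0.5))
  wrong <- structure(list(model = "wsls"), class = "rl_fit")
  expect_error(extract_rpes(wrong, d), "Rescorla-Wagner")
  # first trial with a win from the midpoint initialization
  d1 <- data.frame(choice = 0, reward = 1)
  expect_error(fit_model("rw", d1), "degenerate")
  expect_equal(extract_rpes(fake, d1)$rpe, 0.5)
})

test_that("recovery reports undefined correlations for constant parameters", {
  rec <- parameter_recovery("rw", 3,
                            function(n) data.frame(alpha = rep(0.6, n),
                                                   beta = rep(4, n)),
                            seed = 67, chains = 2, draws = 300, warmup = 300)
  expect_true(all(is.na(rec$correlation)))
})

test_that("longer series recover parameters better than the task length", {
  short <- parameter_recovery(
    "rw", 12, function(n) data.frame(alpha = runif(n, 0.3, 0.9),
                                     beta = runif(n, 1, 10)),
    seed = 68, chains = 2, draws = 500, warmup = 500)
  long <- parameter_recovery(
    "rw", 12, function(n) data.frame(alpha = runif(n, 0.3, 0.9),
                                     beta = runif(n, 1, 10)),
    seed = 68, config = task_config(n_trials = 600, n_reversals = 48),
    chains = 2, draws = 500, warmup = 500)
  expect_gt(long$correlation[["alpha"]], short$correlation[["alpha"]])
})

test_that("the reward landscape behaves like its Monte-Carlo definition", {
  cfg <- task_config()
  # random choice earns n_trials * mean win probability
  rl0 <- reward_landscape(0.5, 0, n_sims = 300, config = cfg, seed = 69)
  expect_lt(abs(rl0[1, 1] - 30), 1)
  # a single cell equals simulate-and-average of that cell
  one <- reward_landscape(0.8, 5, n_sims = 20, config = cfg, seed = 70)
  tot <- numeric(20)
  for (s in 1:20) {
    c2 <- cfg; c2$seed <- derive_seed(70, 31L, s)
    sch <- generate_task_schedule(c2)
    tot[s] <- sum(simulate_agent(agent_spec("rw", alpha = 0.8, beta = 5),
                                 sch, seed = derive_seed(70, 32L, 1, 1, s))$reward)
  }
  expect_equal(one[1, 1], mean(tot))
  # the high-alpha/high-beta corner beats the low corner
  grid <- reward_landscape(c(0.1, 0.9), c(0.5, 8), n_sims = 150,
                           config = cfg, seed = 71)
  expect_gt(grid["0.9", "8"], grid["0.1", "0.5"])
})
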