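test_that("default schedules have the study's design across many seeds", {
  for (s in seq_len(500)) {
    sch <- generate_task_schedule(task_config(seed = s))
    expect_length(sch$good_arm, 60)
    expect_length(sch$reversal_trials, 4)
    expect_true(all(sort(unique(as.vector(sch$p_win))) == c(0.2, 0.8)))
    # yoked: one arm at 0.8, the other at 0.2, every trial
    expect_true(all(rowSums(sch$p_win) == 1.0))
    # the good arm swaps at every reversal and nowhere else
    flips <- which(diff(sch$good_arm) != 0) + 1L
    expect_identical(flips, sch$reversal_trials)
    # within-block counter restarts at 1 after each reversal
    expect_identical(which(sch$within_block_trial == 1L),
                     c(1L, sch$reversal_trials))
    # block lengths respect the 12 +/- 1 jitter except the absorbing final one
    lens <- diff(c(1L, sch$reversal_trials, 61L))
    expect_true(all(lens[-5] %in% 11:13))
  }
})

test_that("no reversals means one constant block", {
  sch <- generate_task_schedule(task_config(n_reversals = 0, seed = 3))
  expect_length(unique(sch$good_arm), 1)
  expect_identical(sch$within_block_trial, 1:60)
  expect_length(sch$reversal_trials, 0)
})

test_that("infeasible configurations are rejected", {
  expect_error(task_config(n_trials = 3, n_reversals = 4))
  expect_error(
    generate_task_schedule(task_config(n_trials = 40, n_reversals = 4,
                                       block_length_mean = 12,
                                       block_length_jitter = 1)),
    "infeasible")
})

test_that("schedule generation is deterministic given the seed", {
  a <- generate_task_schedule(task_config(seed = 11))
  b <- generate_task_schedule(task_config(seed = 11))
  expect_identical(a, b)
})

test_that("a zero-temperature learner chooses arms uniformly", {
  sch <- generate_task_schedule(task_config(n_trials = 4000, n_reversals = 0,
                                            block_length_mean = 4000,
                                            seed = 21))
  dat <- simulate_agent(agent_spec("rw", alpha = 0.5, beta = 0), sch,
                        seed = 22)
  expect_lt(abs(mean(dat$choice) - 0.5), 0.03)
})

test_that("a fully rule-following win-stay agent repeats rewarded choices", {
  sch <- generate_task_schedule(task_config(seed = 23))
  dat <- simulate_agent(agent_spec("wsls", epsilon = 1), sch, seed = 24)
  wins <- which(dat$reward[-nrow(dat)] == 1)
  expect_true(all(dat$choice[wins + 1] == dat$choice[wins]))
  losses <- which(dat$reward[-nrow(dat)] == 0)
  expect_true(all(dat$choice[losses + 1] != dat$choice[losses]))
})

test_that("simulated choices are calibrated to the softmax rule", {
  # reconstruct the per-trial choice probability from the agent's own value
  # trajectory and compare binned empirical frequencies against it
  set.seed(25)
  p_hat <- c(); chosen <- c()
  for (i in 1:150) {
    sch <- generate_task_schedule(task_config(seed = 1000 + i))
    dat <- simulate_agent(agent_spec("rw", alpha = 0.6, beta = 4), sch,
                          seed = 2000 + i)
    tr <- rw_loglik(list(alpha = 0.6, beta = 4), dat)
    p1 <- plogis(4 * (tr$Q[, 2] - tr$Q[, 1]))
    p_hat <- c(p_hat, p1)
    chosen <- c(chosen, dat$choice)
  }
  bins <- cut(p_hat, breaks = seq(0, 1, 0.25))
  emp <- tapply(chosen, bins, mean)
  pred <- tapply(p_hat, bins, mean)
  keep <- !is.na(emp)
  expect_lt(max(abs(emp[keep] - pred[keep])), 0.03)
})

test_that("high learning rate plus decisive choice earns more reward", {
  good <- agent_spec("rw", alpha = 0.9, beta = 8)
  poor <- agent_spec("rw", alpha = 0.1, beta = 0.5)
  tot <- matrix(NA_real_, 400, 2)
  for (s in seq_len(400)) {
    sch <- generate_task_schedule(task_config(seed = 3000 + s))
    tot[s, 1] <- sum(simulate_agent(good, sch, seed = 4000 + s)$reward)
    tot[s, 2] <- sum(simulate_agent(poor, sch, seed = 5000 + s)$reward)
  }
  expect_gt(mean(tot[, 1]), mean(tot[, 2]))
})

test_that("agent_spec enforces parameter bounds", {
  expect_error(agent_spec("rw", alpha = 1.2, beta = 3))
  expect_error(agent_spec("rw", alpha = 0.5, beta = -1))
  expect_error(agent_spec("wsls", epsilon = -0.1))
  expect_error(agent_spec("bayes", p_reward = 0.4, p_switch = 0.1))
  expect_error(agent_spec("bayes", p_reward = 0.8, p_switch = 0.6))
})

test_that("recognition sets pair every encoding trial with a matched lure", {
  ch <- fixture_rw_cohort()
  rec <- simulate_recognition(ch, params = memory_gen_params(), seed = 31)
  for (s in unique(rec$subject)) {
    sub <- rec[rec$subject == s, ]
    expect_equal(sum(sub$is_old), 60)
    expect_equal(sum(!sub$is_old), 60)
  }
  expect_true(all(rec$rt > 0))
  expect_true(all(is.na(rec$rpe[!rec$is_old])))
  # lure memorability drawn from the same pool: similar location/scale
  expect_lt(abs(mean(rec$pm[rec$is_old]) - mean(rec$pm[!rec$is_old])), 0.1)
})

test_that("null memory parameters give chance-level correctness", {
  ch <- fixture_rw_cohort()
  p <- memory_gen_params(b0 = 0, b_rpe = 0, b_pm = 0, b_trial = 0,
                         subject_sd = 0)
  rec <- simulate_recognition(ch, params = p, seed = 32)
  expect_lt(abs(mean(rec$correct) - 0.5), 0.03)
})

test_that("a saturated intercept yields perfect accuracy and a clamped d-prime", {
  ch <- fixture_rw_cohort()
  p <- memory_gen_params(b0 = 20, b_rpe = 0, b_pm = 0, b_trial = 0,
                         subject_sd = 0)
  rec <- categorize_responses(simulate_recognition(ch, params = p, seed = 33))
  expect_true(all(rec$correct))
  one <- rec[rec$subject == rec$subject[1], ]
  expect_equal(compute_dprime(one),
               qnorm(1 - 1 / 120) - qnorm(1 / 120))
})

test_that("the generative log-odds slope on RPE is recovered at scale", {
  set.seed(34)
  specs <- lapply(1:180, function(i)
    agent_spec("rw", alpha = runif(1, 0.5, 0.9), beta = runif(1, 3, 8)))
  ch <- simulate_cohort(specs, task_config(), seed = 35)
  p <- memory_gen_params(b0 = 1, b_rpe = 0.5, b_pm = 0.16, b_trial = -0.12,
                         subject_sd = 0)
  rec <- simulate_recognition(ch, params = p, seed = 36)
  fit <- glm(correct ~ rpe_std + pm_std + trial_std, binomial, rec)
  expect_lt(abs(coef(fit)[["rpe_std"]] - 0.5), 0.15)
})

test_that("hit rate rises monotonically with the RPE coefficient", {
  ch <- fixture_rw_cohort()
  rates <- vapply(c(0, 0.5, 1, 2), function(b) {
    p <- memory_gen_params(b0 = 0.3, b_rpe = b, b_pm = 0, b_trial = 0,
                           subject_sd = 0)
    rec <- simulate_recognition(ch, params = p, seed = 37)
    old <- rec[rec$is_old, ]
    mean(old$correct[old$rpe_std > 0])
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("survey item correlations reproduce the latent structure", {
  L <- default_survey_loadings()
  phi <- matrix(c(1, -0.4, -0.4, -0.4, 1, -0.4, -0.4, -0.4, 1), 3, 3)
  sp <- survey_gen_params(loadings = L, factor_corr = phi,
                          n_respondents = 100000, seed = 41)
  sv <- generate_surveys(sp)
  cont <- attr(sv, "continuous")
  target <- L %*% phi %*% t(L)
  diag(target) <- 1
  expect_lt(max(abs(cor(cont) - target)), 0.02)
})

test_that("zero loadings give an identity item correlation matrix", {
  L <- matrix(0, 12, 3)
  rownames(L) <- sprintf("item%02d", 1:12)
  sv <- generate_surveys(survey_gen_params(loadings = L,
                                           n_respondents = 20000, seed = 42))
  R <- cor(attr(sv, "continuous"))
  expect_lt(max(abs(R - diag(12))), 0.03)
})

test_that("a single strong factor gives the closed-form correlations", {
  L <- matrix(0.8, 15, 1)
  rownames(L) <- sprintf("item%02d", 1:15)
  sp <- survey_gen_params(loadings = L, factor_corr = matrix(1, 1, 1),
                          n_respondents = 100000, seed = 43)
  sv <- generate_surveys(sp)
  R <- cor(attr(sv, "continuous"))
  off <- R[upper.tri(R)]
  expect_lt(max(abs(off - 0.64)), 0.02)
})

test_that("non-positive-definite factor correlations are rejected", {
  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.9, -0.99, 0.9, 1), 3, 3)
  expect_error(survey_gen_params(factor_corr = bad), "positive definite")
})

test_that("datasets round-trip through the CSV dialect with their sidecar", {
  ch <- fixture_rw_cohort()
  p <- memory_gen_params()
  rec <- simulate_recognition(ch[ch$subject <= 2, ], params = p, seed = 44)
  path <- file.path(tempdir(), "recog.csv")
  write_dataset(rec, path)
  back <- read_dataset(path)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$rt, rec$rt)
  expect_equal(attr(back, "params")$b_rpe, p$b_rpe)
})

test_that("reverse-coded items are emitted flipped and recode back exactly", {
  L <- default_survey_loadings()
  rev_flag <- rep(FALSE, nrow(L)); rev_flag[c(3, 10, 40)] <- TRUE
  plain <- generate_surveys(survey_gen_params(loadings = L,
                                              n_respondents = 200,
                                              seed = 45))
  flipped <- generate_surveys(survey_gen_params(loadings = L,
                                                n_respondents = 200,
                                                seed = 45,
                                                reverse_coded = rev_flag))
  expect_false(identical(unclass(plain)[, 3], unclass(flipped)[, 3]))
  back <- recode_reversed(flipped)
  expect_equal(unclass(back)[, ], unclass(plain)[, ],
               ignore_attr = TRUE)
})
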