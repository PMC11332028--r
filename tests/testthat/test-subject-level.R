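test_that("OLS recovers a generating interaction on synthetic tables", {
  set.seed(101)
  n <- 200
  tab <- data.frame(subject = 1:n,
                    beta_rpe = rnorm(n),
                    f1 = rnorm(n))
  tab$dprime <- 0.5 + 0.3 * tab$beta_rpe + 0.2 * tab$f1 +
    1.0 * tab$beta_rpe * tab$f1 + rnorm(n, 0, 0.5)
  res <- interaction_regression(tab, "dprime", "beta_rpe", "f1",
                                standardize = FALSE)
  inter <- res[res$term == "beta_rpe:f1", ]
  expect_lt(abs(inter$B - 1.0), 0.2)
  expect_lt(inter$p, 0.001)
  # confidence interval consistent with B +/- t * SE
  expect_equal(inter$ci_upper - inter$B,
               qt(0.975, inter$df) * inter$SE)
})

test_that("an outcome identical to the slope loads only on the slope", {
  set.seed(102)
  n <- 60
  tab <- data.frame(subject = 1:n, s = rnorm(n), m = rnorm(n))
  tab$y <- tab$s
  res <- interaction_regression(tab, "y", "s", "m", standardize = FALSE)
  expect_equal(res$B[res$term == "s"], 1, tolerance = 1e-10)
  expect_lt(max(abs(res$B[res$term != "s"])), 1e-10)
})

test_that("permuting the moderator gives uniform interaction p-values", {
  set.seed(103)
  n <- 80
  base <- data.frame(subject = 1:n, s = rnorm(n), m0 = rnorm(n))
  base$y <- 0.4 * base$s + rnorm(n, 0, 0.6)
  ps <- vapply(1:200, function(i) {
    base$m <- sample(base$m0)
    r <- interaction_regression(base, "y", "s", "m", standardize = FALSE)
    r$p[r$term == "s:m"]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("small tables are refused", {
  tab <- data.frame(subject = 1:5, y = rnorm(5), s = rnorm(5), m = rnorm(5))
  expect_error(interaction_regression(tab, "y", "s", "m"), ">= 10")
})

test_that("TOST equivalence reproduces its t-distribution oracle", {
  # worked example: B = 0.05, SE = 0.02, df = 100, bounds +/- 0.1
  eq <- tost_equivalence(0.05, 0.02, 100)
  expect_equal(eq$t_lower, 7.5)
  expect_equal(eq$t_upper, -2.5)
  expect_equal(eq$p_eq, pt(-2.5, 100))
  expect_equal(round(eq$p_eq, 4), 0.007)
  expect_true(eq$equivalent)
  # an estimate at the center with negligible error is clearly equivalent
  expect_lt(tost_equivalence(0, 0.001, 100)$p_eq, 1e-10)
  # an estimate beyond the bound is clearly not
  expect_gt(tost_equivalence(0.2, 0.01, 100)$p_eq, 0.999)
})

test_that("TOST is symmetric in the sign of the estimate", {
  for (B in c(0, 0.03, 0.08, 0.2)) {
    expect_equal(tost_equivalence(B, 0.04, 60)$p_eq,
                 tost_equivalence(-B, 0.04, 60)$p_eq)
  }
})

test_that("widening the equivalence bounds never increases p_eq", {
  widths <- seq(0.05, 0.5, by = 0.05)
  ps <- vapply(widths, function(w)
    tost_equivalence(0.04, 0.03, 80, bounds = c(-w, w))$p_eq, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("equivalence conclusions appear at the rate noncentral t predicts", {
  set.seed(104)
  B <- 0; SE <- 0.03; df <- 120; bound <- 0.1
  # analytic acceptance rate: with a fixed SE the two one-sided tests reject
  # jointly iff the estimate falls inside (-bound + t* SE, bound - t* SE)
  tcrit <- qt(0.95, df)
  power <- pnorm(bound / SE - tcrit) - pnorm(-bound / SE + tcrit)
  hits <- vapply(1:2000, function(i) {
    Bhat <- rnorm(1, B, SE)
    tost_equivalence(Bhat, SE, df)$equivalent
  }, logical(1))
  expect_lt(abs(mean(hits) - power), 0.05)
})

test_that("the subject table assembles one aligned row per subject", {
  ch <- fixture_rw_cohort()
  p <- memory_gen_params(subject_sd_rpe = 0.3)
  rec <- categorize_responses(simulate_recognition(ch, params = p,
                                                   seed = 105))
  fit <- fit_memory_glm(rec, chains = 2, draws = 400, warmup = 400,
                        seed = 106)
  fs <- matrix(rnorm(length(fit$subject_ids) * 3),
               ncol = 3)
  rl <- data.frame(subject = fit$subject_ids,
                   alpha = runif(length(fit$subject_ids)),
                   beta = runif(length(fit$subject_ids), 1, 8))
  tab <- build_subject_table(rec, fit, factor_scores = fs,
                             rl_estimates = rl, choices = ch)
  expect_equal(nrow(tab), length(fit$subject_ids))
  expect_true(all(c("memory_accuracy", "dprime", "beta_rpe", "beta_pm",
                    "f1", "f2", "f3", "alpha", "beta", "total_reward",
                    "mean_rt") %in% names(tab)))
  s1 <- fit$subject_ids[1]
  expect_equal(tab$memory_accuracy[tab$subject == s1],
               mean(rec$correct[rec$subject == s1]))
  expect_equal(tab$total_reward[tab$subject == s1],
               sum(ch$reward[ch$subject == s1]))
})
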