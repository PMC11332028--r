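test_that("no density mass sits below the non-decision time", {
  expect_equal(wfpt_density(c(0.1, 0.29, 0.3), "upper", v = 1, a = 1.5,
                            z = 0.5, t = 0.3), c(0, 0, 0))
  expect_gt(wfpt_density(0.31, "upper", v = 1, a = 1.5, z = 0.5, t = 0.3), 0)
})

test_that("first-passage mass sums to one over both boundaries", {
  for (v in c(-0.5, 1)) for (z in c(0.35, 0.6)) {
    mass <- integrate(function(rt)
      wfpt_density(rt, "upper", v, 1.5, z, 0.3) +
      wfpt_density(rt, "lower", v, 1.5, z, 0.3),
      0.3, Inf, rel.tol = 1e-9)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
})

test_that("upper and lower boundaries are relabelling-symmetric", {
  rt <- seq(0.35, 4, length.out = 40)
  up <- wfpt_density(rt, "upper", v = 0.8, a = 2, z = 0.4, t = 0.3)
  lo <- wfpt_density(rt, "lower", v = -0.8, a = 2, z = 0.6, t = 0.3)
  expect_equal(up, lo, tolerance = 1e-12)
})

test_that("small- and large-time series agree in the crossover region", {
  for (rt in seq(0.45, 1.2, length.out = 12)) {
    s <- wfpt_density_series_cpp(rt, 1L, 0.5, 1.5, 0.45, 0.3, "small", 80)
    l <- wfpt_density_series_cpp(rt, 1L, 0.5, 1.5, 0.45, 0.3, "large", 80)
    expect_lt(abs(s - l) / max(l, 1e-12), 1e-6)
    auto <- wfpt_density(rt, "upper", 0.5, 1.5, 0.45, 0.3)
    expect_lt(abs(auto - l) / max(l, 1e-12), 1e-6)
  }
})

test_that("density non-negative and parameters validated", {
  rt <- seq(0.21, 6, length.out = 100)
  for (v in c(-2, 0, 2)) {
    expect_true(all(wfpt_density(rt, "upper", v, 0.8, 0.3, 0.2) >= 0))
  }
  expect_error(wfpt_density(1, "upper", 1, -1, 0.5, 0.3))
  expect_error(wfpt_density(1, "upper", 1, 1, 1.5, 0.3))
})

test_that("RT exclusions follow the absolute and 3-SD rules", {
  # nothing to filter
  clean <- data.frame(subject = rep(1:2, each = 20),
                      rt = runif(40, 0.4, 2))
  f <- filter_rts(clean)
  expect_equal(f$report$n_retained, 40)
  expect_equal(f$report$n_excluded_fast + f$report$n_excluded_slow +
               f$report$n_excluded_sd, 0)
  # absolute bounds
  d <- data.frame(subject = 1, rt = c(0.1, 0.5, 0.6, 11))
  f <- filter_rts(d)
  expect_equal(f$report$n_excluded_fast, 1)
  expect_equal(f$report$n_excluded_slow, 1)
  # 29 tight trials plus one 5 s outlier: the outlier is beyond 3 SD
  d <- data.frame(subject = 1, rt = c(rep(0.5, 29), 5))
  mu <- mean(d$rt); sdv <- sd(d$rt)
  expect_true(abs(5 - mu) > 3 * sdv) # direct mean/SD oracle
  f <- filter_rts(d)
  expect_equal(f$report$n_excluded_sd, 1)
  expect_false(5 %in% f$data$rt)
  # a subject left with fewer than 2 trials is flagged
  d <- data.frame(subject = c(1, 1, 1, 2, 2),
                  rt = c(0.5, 0.55, 0.6, 0.2, 0.5))
  f <- filter_rts(d)
  expect_true("2" %in% f$report$flagged_subjects)
})

test_that("the shifted log link keeps signed covariates in domain", {
  x <- c(-2, 0, 3)
  g <- rpemem:::ddm_link(x, "log")
  expect_equal(g, log(x - min(x) + 1))
  expect_true(all(is.finite(g)))
  expect_equal(rpemem:::ddm_link(x, "quadratic"), x^2)
})

test_that("identical fits compare with zero WAIC difference", {
  set.seed(71)
  sim <- simulate_ddm(400, v = 0.7, a = 1.5, z = 0.5, t = 0.3, dt = 1e-3,
                      seed = 72)
  d <- data.frame(subject = rep(1:4, each = 100), rt = sim$rt,
                  response = ifelse(sim$boundary == "upper", "old", "new"),
                  is_old = TRUE, rpe_std = rnorm(400, 0, 0.5),
                  pm_std = rnorm(400, 0, 0.5))
  fit <- fit_hier_ddm(d, "rpe", chains = 2, draws = 300, warmup = 300,
                      seed = 73)
  cmp <- compare_ddm_models(list(a = fit, b = fit))
  expect_equal(cmp$d_waic[2], 0)
  fit2 <- fit_hier_ddm(d[1:200, ], "rpe", chains = 2, draws = 200,
                       warmup = 200, seed = 74)
  expect_error(compare_ddm_models(list(a = fit, b = fit2)), "different")
})

test_that("WAIC prefers the covariate that truly drives drift", {
  set.seed(75)
  specs <- lapply(1:12, function(i)
    agent_spec("rw", alpha = runif(1, 0.5, 0.9), beta = runif(1, 3, 8)))
  ch <- simulate_cohort(specs, task_config(), seed = 76)
  p <- memory_gen_params(ddm = list(a = 1.5, z = 0.5, t = 0.3, v0 = 0.8,
                                    v_rpe = 0.35, v_pm = 0,
                                    sv_int = 0.15, sv_rpe = 0.05,
                                    sv_pm = 0.02))
  rec <- categorize_responses(
    simulate_recognition(ch, params = p, seed = 77, response_mode = "ddm"))
  filt <- filter_rts(rec)
  fits <- list(
    rpe = suppressWarnings(fit_hier_ddm(filt$data, "rpe", chains = 2,
                                        draws = 700, warmup = 700,
                                        seed = 78)),
    pm = suppressWarnings(fit_hier_ddm(filt$data, "pm", chains = 2,
                                       draws = 700, warmup = 700,
                                       seed = 79)))
  cmp <- compare_ddm_models(fits)
  expect_equal(cmp$model[1], "rpe")
})
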