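test_that("KMO worked examples match hand computation", {
  # two items: the partial correlation equals the correlation, so KMO = 0.5
  R2 <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  expect_equal(kmo(R2)$overall, 0.5)
  # three equicorrelated items: analytic inverse of the 3x3 matrix
  r <- 0.6
  R3 <- matrix(r, 3, 3); diag(R3) <- 1
  Ri <- solve(R3)
  d <- 1 / sqrt(diag(Ri))
  Q <- -Ri * outer(d, d); diag(Q) <- 0
  R0 <- R3; diag(R0) <- 0
  expect_equal(kmo(R3)$overall, sum(R0^2) / (sum(R0^2) + sum(Q^2)))
  # strong one-factor data are adequate
  L <- matrix(0.8, 12, 1)
  rownames(L) <- sprintf("i%02d", 1:12)
  sv <- generate_surveys(survey_gen_params(
    loadings = L, factor_corr = matrix(1, 1, 1),
    n_respondents = 10000, seed = 91))
  expect_gt(kmo(sv)$overall, 0.7)
  expect_true(all(kmo(sv)$msa >= 0 & kmo(sv)$msa <= 1))
})

test_that("Bartlett sphericity follows the determinant formula", {
  expect_equal(bartlett_sphericity(diag(3), n = 50)$chisq, 0)
  # p = 3, n = 101, |R| = 0.5: direct arithmetic gives 68.04
  rho <- uniroot(function(r) (1 - r)^2 * (1 + 2 * r) - 0.5, c(0, 0.9),
                 tol = 1e-12)$root
  R <- matrix(rho, 3, 3); diag(R) <- 1
  b <- bartlett_sphericity(R, n = 101)
  expect_equal(b$chisq, -(100 - 11 / 6) * log(0.5), tolerance = 1e-8)
  expect_lt(abs(b$chisq - 68.044), 0.001)
  expect_equal(b$df, 3)
  # correlated data at n = 1000 reject sphericity decisively
  sv <- generate_surveys(survey_gen_params(n_respondents = 1000, seed = 92))
  expect_lt(bartlett_sphericity(sv)$p_value, 0.001)
})

test_that("CNG elbow selection matches its slope-difference definition", {
  ev <- c(10, 9, 1, 0.9, 0.8, 0.7, 0.6)
  # frozen from the implemented (published) rule: windows [i..i+2] vs
  # [i+3..i+5], k = argmax + 2
  slopes <- vapply(1:5, function(i) (ev[i + 2] - ev[i]) / 2, numeric(1))
  diffs <- slopes[4:5] - slopes[1:2]
  expect_equal(cng_nfactors(ev)$diffs, diffs)
  expect_equal(cng_nfactors(ev)$k, which.max(diffs) + 2L)
  expect_equal(cng_nfactors(ev)$k, 3L)
  expect_error(cng_nfactors(c(3, 2, 1)), "at least 6")
  # perfectly linear decay has no distinguished elbow
  expect_warning(flat <- cng_nfactors(seq(6, 1, by = -1)), "flat")
  expect_true(flat$flat)
})

test_that("CNG recovers three factors from block-structured surveys", {
  sv <- generate_surveys(survey_gen_params(n_respondents = 10000, seed = 93))
  ev <- eigen(cor(sv), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(cng_nfactors(ev)$k, 3L)
})

test_that("one-factor loadings are recovered to within 0.05", {
  L <- matrix(0.7, 15, 1)
  rownames(L) <- sprintf("i%02d", 1:15)
  sv <- generate_surveys(survey_gen_params(
    loadings = L, factor_corr = matrix(1, 1, 1),
    n_respondents = 10000, seed = 94))
  sol <- fit_factor_model(attr(sv, "continuous"), 1)
  expect_lt(max(abs(abs(sol$loadings[, 1]) - 0.7)), 0.05)
})

test_that("oblique three-factor structure is recovered after alignment", {
  sp <- survey_gen_params(n_respondents = 10000, seed = 95)
  sv <- generate_surveys(sp)
  sol <- fit_factor_model(sv, 3)
  al <- align_loadings(sol$loadings, sp$loadings)
  expect_true(all(al$congruence > 0.9))
  phi_al <- sol$factor_corr[al$permutation, al$permutation] *
    outer(al$signs, al$signs)
  expect_lt(max(abs(phi_al - sp$factor_corr)), 0.12)
  # reconstruction: Lambda Phi Lambda' + Psi approximates the sample
  # correlations (attenuated by discretization, hence on the model scale)
  Rhat <- sol$loadings %*% sol$factor_corr %*% t(sol$loadings) +
    diag(sol$uniqueness)
  rmsr <- sqrt(mean((Rhat - sol$correlation)[upper.tri(Rhat)]^2))
  expect_lt(rmsr, 0.05)
  # promax leaves communalities unchanged
  fa0 <- factanal(covmat = sol$correlation, factors = 3,
                  n.obs = 10000, rotation = "none")
  h_unrot <- rowSums(unclass(fa0$loadings)^2)
  h_rot <- diag(sol$loadings %*% sol$factor_corr %*% t(sol$loadings))
  expect_lt(max(abs(h_unrot - h_rot)), 1e-8)
})

test_that("uncorrelated items yield near-zero communalities", {
  set.seed(96)
  m <- matrix(rnorm(5000 * 10), 5000, 10)
  colnames(m) <- sprintf("i%02d", 1:10)
  sol <- fit_factor_model(m, 1)
  # ML extraction on noise is barely identified and can latch a single
  # variable onto the largest sample correlation; the check is that the
  # factor explains almost none of the total variance
  expect_lt(mean(1 - sol$uniqueness), 0.05)
})

test_that("ten Berge scores preserve the factor correlations", {
  sp <- survey_gen_params(n_respondents = 10000, seed = 97)
  sv <- generate_surveys(sp)
  sol <- fit_factor_model(sv, 3)
  sc <- score_tenberge(sol, sv)
  expect_lt(max(abs(cor(sc) - sol$factor_corr)), 0.05)
  # scores regress strongly on the true latent factors after alignment
  al <- align_loadings(sol$loadings, sp$loadings)
  f <- attr(sv, "factors")
  for (j in 1:3) {
    slope <- coef(lm(al$signs[j] * sc[, al$permutation[j]] ~ f[, j]))[2]
    expect_gt(slope, 0.8)
  }
  # an orthogonal solution scores to near-identity correlations
  L <- matrix(0, 20, 2); L[1:10, 1] <- 0.7; L[11:20, 2] <- 0.7
  rownames(L) <- sprintf("i%02d", 1:20)
  sv2 <- generate_surveys(survey_gen_params(
    loadings = L, factor_corr = diag(2), n_respondents = 10000, seed = 98))
  sol2 <- fit_factor_model(sv2, 2)
  sc2 <- score_tenberge(sol2, sv2)
  expect_lt(max(abs(cor(sc2) - sol2$factor_corr)), 0.05)
  expect_lt(max(abs(sol2$factor_corr - diag(2))), 0.15)
})
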