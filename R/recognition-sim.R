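#' Generative parameters for recognition outcomes and reaction times
#'
#' Houses the generative counterparts of the memory regression coefficients
#' (log-odds of a correct old/new judgement per standardized unit of RPE,
#' memorability, and within-block trial) and of the drift regression
#' (baseline drift plus RPE/PM drift slopes). Defaults sit at the scale of
#' the cohort-level estimates reported for this task family: modest positive
#' RPE and memorability effects on accuracy, a small negative within-block
#' trial effect, and drift slopes of a few hundredths per standardized unit.
#'
#' @param b0 log-odds intercept of a correct response
#' @param b_rpe log-odds per standardized-RPE unit
#' @param b_pm log-odds per standardized-memorability unit
#' @param b_trial log-odds per standardized within-block-trial unit
#' @param subject_sd SD of subject random intercepts
#' @param subject_sd_rpe,subject_sd_pm SDs of subject random slopes (default 0)
#' @param ddm list with boundary separation `a` > 0, relative start point `z`
#'   in (0,1), non-decision time `t` >= 0 seconds, baseline drift `v0`, drift
#'   slopes `v_rpe`, `v_pm`, and between-subject SDs `sv_int`, `sv_rpe`,
#'   `sv_pm` of the drift intercept and slopes
#' @return object of class `memory_gen_params`
#' @export
memory_gen_params <- function(b0 = 1.0, b_rpe = 0.17, b_pm = 0.16,
                              b_trial = -0.12, subject_sd = 0.5,
                              subject_sd_rpe = 0, subject_sd_pm = 0,
                              ddm = list(a = 1.5, z = 0.5, t = 0.3,
                                         v0 = 0.8, v_rpe = 0.046,
                                         v_pm = 0.038, sv_int = 0.2,
                                         sv_rpe = 0.05, sv_pm = 0.05)) {
  for (nm in c("sv_int", "sv_rpe", "sv_pm")) {
    if (is.null(ddm[[nm]])) ddm[[nm]] <- 0
  }
  stopifnot(ddm$a > 0, ddm$z > 0, ddm$z < 1, ddm$t >= 0,
            ddm$sv_int >= 0, ddm$sv_rpe >= 0, ddm$sv_pm >= 0,
            subject_sd >= 0, subject_sd_rpe >= 0, subject_sd_pm >= 0)
  structure(list(b0 = b0, b_rpe = b_rpe, b_pm = b_pm, b_trial = b_trial,
                 subject_sd = subject_sd, subject_sd_rpe = subject_sd_rpe,
                 subject_sd_pm = subject_sd_pm, ddm = ddm),
            class = "memory_gen_params")
}

#' Simulate the recognition test for a simulated cohort
#'
#' Every decision trial contributes one old probe; an equal number of lures
#' is drawn from the same memorability distribution. Covariates are put on
#' the 2-SD standardized scale (RPE and encoding trial over old probes, with
#' lures zero-imputed, i.e. held at the old-probe mean; memorability over all
#' probes). Two response-generation modes are available:
#'
#' * `"logistic"` (default): correctness is Bernoulli with logit equal to the
#'   linear predictor plus subject random effects; the old/new response
#'   follows from correctness and probe status; the reaction time is the
#'   first-passage time of a diffusion with drift
#'   `s * (v0_i + v_rpe_i * RPE + v_pm_i * PM)` (subject-level intercept and
#'   slopes drawn around the group values; `s` = +1 for old probes, -1 for
#'   lures, so baseline evidence points toward the correct answer),
#'   resimulated until the path absorbs at the boundary matching the emitted
#'   response.
#' * `"ddm"`: response and reaction time are drawn jointly from the first
#'   passage (upper boundary = "old"), so the data are exactly
#'   diffusion-generated; used for drift-regression recovery studies.
#'
#' @param choices cohort data.frame from [simulate_cohort()]
#' @param rpes per-trial signed RPE vector aligned to `choices`; defaults to
#'   the generative `rpe` column (Rescorla-Wagner agents)
#' @param params a [memory_gen_params()]
#' @param seed integer seed
#' @param response_mode `"logistic"` or `"ddm"`
#' @param dt Euler step (seconds) of the path simulator
#' @return data.frame with one row per probe: `subject`, `probe`, `is_old`,
#'   `pm`, `rpe`, `encoding_trial`, `response`, `rt`, `confidence`, `correct`,
#'   plus standardized covariate columns `rpe_std`, `pm_std`, `trial_std`;
#'   subject-level generative effects are attached as attribute
#'   `"subject_effects"`
#' @export
simulate_recognition <- function(choices, rpes = NULL,
                                 params = memory_gen_params(), seed = 1L,
                                 response_mode = c("logistic", "ddm"),
                                 dt = 1e-3) {
  response_mode <- match.arg(response_mode)
  stopifnot(inherits(params, "memory_gen_params"))
  if (is.null(rpes)) rpes <- choices$rpe
  if (length(rpes) != nrow(choices)) {
    stop("rpes must align with choices (one value per decision trial)")
  }
  if (anyNA(rpes)) stop("rpes contain NA; supply model-derived RPEs")
  subjects <- unique(choices$subject)
  set.seed(derive_seed(seed, 41L))
  sub_eff <- data.frame(
    subject = subjects,
    b0 = rnorm(length(subjects), params$b0, params$subject_sd),
    b_rpe = rnorm(length(subjects), params$b_rpe, params$subject_sd_rpe),
    b_pm = rnorm(length(subjects), params$b_pm, params$subject_sd_pm),
    v0 = rnorm(length(subjects), params$ddm$v0, params$ddm$sv_int),
    v_rpe = rnorm(length(subjects), params$ddm$v_rpe, params$ddm$sv_rpe),
    v_pm = rnorm(length(subjects), params$ddm$v_pm, params$ddm$sv_pm))

  rows <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    old <- choices[choices$subject == s, ]
    n <- nrow(old)
    set.seed(derive_seed(seed, 42L, k))
    lure_pm <- draw_pm_scores(n)
    df <- data.frame(
      subject = s,
      probe = c(sprintf("s%s_old%03d", s, old$trial),
                sprintf("s%s_lure%03d", s, seq_len(n))),
      is_old = rep(c(TRUE, FALSE), each = n),
      pm = c(old$pm, lure_pm),
      rpe = c(rpes[choices$subject == s], rep(NA_real_, n)),
      encoding_trial = c(old$within_block_trial, rep(NA_integer_, n)))
    rows[[k]] <- df
  }
  probes <- do.call(rbind, rows)
  rownames(probes) <- NULL

  # standardized covariates; lure RPE / encoding trial imputed at the
  # (standardized) old-probe mean, i.e. zero
  old_idx <- probes$is_old
  rpe_std <- rep(0, nrow(probes))
  rpe_std[old_idx] <- standardize_2sd(probes$rpe[old_idx])
  trial_std <- rep(0, nrow(probes))
  trial_std[old_idx] <- standardize_2sd(probes$encoding_trial[old_idx])
  pm_std <- as.numeric(standardize_2sd(probes$pm))
  probes$rpe_std <- rpe_std
  probes$pm_std <- pm_std
  probes$trial_std <- trial_std

  eff <- sub_eff[match(probes$subject, sub_eff$subject), ]
  eta <- eff$b0 + eff$b_rpe * rpe_std + eff$b_pm * pm_std +
    params$b_trial * trial_std
  drift_mag <- eff$v0 + eff$v_rpe * rpe_std + eff$v_pm * pm_std
  drift <- ifelse(probes$is_old, drift_mag, -drift_mag)

  set.seed(derive_seed(seed, 43L))
  if (response_mode == "logistic") {
    correct <- rbinom(nrow(probes), 1, plogis(eta)) == 1
    response <- ifelse(probes$is_old == correct, "old", "new")
    rt <- numeric(nrow(probes))
    for (i in seq_len(nrow(probes))) {
      want_upper <- response[i] == "old"
      for (try in 1:200) {
        sim <- simulate_ddm_paths_cpp(drift[i], params$ddm$a, params$ddm$z,
                                      params$ddm$t, dt, 30,
                                      derive_seed(seed, 44L, i, try))
        if (!is.na(sim$boundary[1]) &&
            (sim$boundary[1] == 1) == want_upper) break
      }
      rt[i] <- sim$rt[1]
    }
  } else {
    rt <- numeric(nrow(probes))
    response <- character(nrow(probes))
    for (i in seq_len(nrow(probes))) {
      sim <- simulate_ddm_paths_cpp(drift[i], params$ddm$a, params$ddm$z,
                                    params$ddm$t, dt, 30,
                                    derive_seed(seed, 45L, i))
      if (is.na(sim$boundary[1])) { # rerun with a fresh stream (rare)
        sim <- simulate_ddm_paths_cpp(drift[i], params$ddm$a, params$ddm$z,
                                      params$ddm$t, dt, 60,
                                      derive_seed(seed, 46L, i))
      }
      rt[i] <- sim$rt[1]
      response[i] <- if (sim$boundary[1] == 1) "old" else "new"
    }
    correct <- (response == "old") == probes$is_old
  }
  probes$response <- response
  probes$rt <- rt
  probes$confidence <- sample(1:4, nrow(probes), replace = TRUE)
  probes$correct <- correct
  # randomized probe order within subject
  probes <- probes[order(probes$subject,
                         sample(seq_len(nrow(probes)))), ]
  rownames(probes) <- NULL
  attr(probes, "subject_effects") <- sub_eff
  attr(probes, "params") <- params
  probes
}
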