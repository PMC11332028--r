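#' Configuration for an end-to-end synthetic run
#'
#' Bundles cohort sizes, the task design, the generative memory parameters,
#' the survey generator, sampler settings per stage, and the chance-exclusion
#' threshold. The configuration round-trips through JSON.
#'
#' @param seed master integer seed
#' @param n_subjects cohort size for the bandit/recognition stages
#' @param task a [task_config()]
#' @param memory a [memory_gen_params()]
#' @param surveys a [survey_gen_params()] (`n_respondents` should be at least
#'   `n_subjects`; extra rows act as survey-only respondents pooled into the
#'   factor solution)
#' @param rl_sampler,glm_sampler,ddm_sampler lists with `chains`, `draws`,
#'   `warmup`
#' @param exclusion_p one-sided binomial threshold for chance-level exclusion
#' @param cohort_alpha_mean,cohort_alpha_sd,cohort_beta_mean,cohort_beta_sd
#'   distribution of generative Rescorla-Wagner parameters across subjects
#' @return object of class `run_config`
#' @export
run_config <- function(seed = 1L, n_subjects = 20,
                       task = task_config(),
                       memory = memory_gen_params(),
                       surveys = survey_gen_params(),
                       rl_sampler = list(chains = 2, draws = 1000,
                                         warmup = 1000),
                       glm_sampler = list(chains = 2, draws = 1000,
                                          warmup = 1000),
                       ddm_sampler = list(chains = 2, draws = 800,
                                          warmup = 800),
                       exclusion_p = 0.05,
                       cohort_alpha_mean = 0.73, cohort_alpha_sd = 0.19,
                       cohort_beta_mean = 4.9, cohort_beta_sd = 2.9) {
  stopifnot(n_subjects >= 2, surveys$n_respondents >= n_subjects)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 task = task, memory = memory, surveys = surveys,
                 rl_sampler = rl_sampler, glm_sampler = glm_sampler,
                 ddm_sampler = ddm_sampler, exclusion_p = exclusion_p,
                 cohort_alpha_mean = cohort_alpha_mean,
                 cohort_alpha_sd = cohort_alpha_sd,
                 cohort_beta_mean = cohort_beta_mean,
                 cohort_beta_sd = cohort_beta_sd),
            class = "run_config")
}

#' Sample cohort-level Rescorla-Wagner parameters
#'
#' Truncated-normal draws around the cohort means (learning rate kept inside
#' (0.05, 0.98), inverse temperature positive).
#'
#' @param n number of agents
#' @param config a [run_config()] (only the cohort fields are used)
#' @return data.frame with `alpha` and `beta`
#' @export
sample_cohort_params <- function(n, config = run_config()) {
  draw_trunc <- function(n, mean, sd, lo, hi) {
    out <- rnorm(n, mean, sd)
    bad <- out < lo | out > hi
    while (any(bad)) {
      out[bad] <- rnorm(sum(bad), mean, sd)
      bad <- out < lo | out > hi
    }
    out
  }
  data.frame(
    alpha = draw_trunc(n, config$cohort_alpha_mean, config$cohort_alpha_sd,
                       0.05, 0.98),
    beta = draw_trunc(n, config$cohort_beta_mean, config$cohort_beta_sd,
                      0.5, 20))
}

#' Exclude subjects performing at chance on the decision task
#'
#' Accuracy is the proportion of higher-probability-arm choices; subjects are
#' retained when a one-sided exact binomial test rejects chance (0.5) in the
#' above-chance direction at `p <= threshold`.
#'
#' @param choices cohort choice data with per-subject schedules attached (as
#'   from [simulate_cohort()]), or containing a `good_arm` column
#' @param threshold one-sided p-value threshold (default 0.05)
#' @return list with `retained` (choice rows of retained subjects),
#'   `log` (per-subject accuracy, p-value, retained flag)
#' @export
exclude_at_chance <- function(choices, threshold = 0.05) {
  if (!"good_arm" %in% names(choices)) {
    schedules <- attr(choices, "schedules")
    if (is.null(schedules)) stop("need a good_arm column or schedules attribute")
    ids <- unique(choices$subject)
    choices$good_arm <- NA_integer_
    for (i in seq_along(ids)) {
      rows <- choices$subject == ids[i]
      choices$good_arm[rows] <- schedules[[i]]$good_arm
    }
  }
  ids <- unique(choices$subject)
  log <- do.call(rbind, lapply(ids, function(s) {
    rows <- choices[choices$subject == s, ]
    k <- sum(rows$choice == rows$good_arm)
    n <- nrow(rows)
    p <- binom.test(k, n, 0.5, alternative = "greater")$p.value
    data.frame(subject = s, n_correct = k, n_trials = n, accuracy = k / n,
               p_value = p, retained = p <= threshold)
  }))
  retained_ids <- log$subject[log$retained]
  retained <- choices[choices$subject %in% retained_ids, ]
  sched <- attr(choices, "schedules")
  if (!is.null(sched)) {
    attr(retained, "schedules") <- sched[match(retained_ids,
                                               unique(choices$subject))]
  }
  list(retained = retained, log = log)
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort, applies chance-level exclusion, fits and compares the
#' three decision models, extracts RPEs from the winning-family
#' Rescorla-Wagner fit, simulates and analyses the recognition stage
#' (RT filtering, hierarchical drift regressions for RPE and memorability,
#' mixed-effects memory regression), generates and factor-analyses surveys,
#' scores task subjects, and runs the subject-level moderation and
#' equivalence analyses. Every stage is seeded from `config$seed`; artifacts
#' are written under `out_dir` when given.
#'
#' @param config a [run_config()]
#' @param out_dir optional directory for stage artifacts (CSV/JSON)
#' @param verbose print stage progress
#' @return a `report_bundle` list with the stage outputs and the exclusion
#'   log
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  artifacts <- character(0)
  save_art <- function(obj, name, params = NULL) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, name)
    if (is.data.frame(obj) || is.matrix(obj)) write_dataset(obj, p, params)
    else jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, force = TRUE)
    artifacts <<- c(artifacts, p)
  }

  say("stage 1: simulating decision cohort")
  set.seed(derive_seed(config$seed, 101L))
  true_rl <- sample_cohort_params(config$n_subjects, config)
  specs <- lapply(seq_len(config$n_subjects), function(i)
    agent_spec("rw", alpha = true_rl$alpha[i], beta = true_rl$beta[i]))
  choices <- simulate_cohort(specs, config$task,
                             seed = derive_seed(config$seed, 102L))
  save_art(choices, "choices.csv", params = list(task = unclass(config$task)))

  say("stage 2: chance-level exclusion")
  excl <- exclude_at_chance(choices, config$exclusion_p)
  choices <- excl$retained
  save_art(excl$log, "exclusion_log.csv")
  kept <- unique(choices$subject)
  if (length(kept) < 2) stop("pipeline aborted at exclusion: <2 subjects kept")

  say("stage 3: decision-model fitting and comparison")
  rl <- config$rl_sampler
  fits <- lapply(kept, function(s) {
    dat <- choices[choices$subject == s, ]
    setNames(lapply(c("rw", "wsls", "bayes"), function(m)
      fit_model(m, dat, chains = rl$chains, draws = rl$draws,
                warmup = rl$warmup,
                seed = derive_seed(config$seed, 103L, s))),
      c("rw", "wsls", "bayes"))
  })
  comparison <- compare_models(fits)
  rl_estimates <- do.call(rbind, lapply(seq_along(kept), function(i)
    data.frame(subject = kept[i],
               alpha = fits[[i]]$rw$point_estimate[["alpha"]],
               beta = fits[[i]]$rw$point_estimate[["beta"]])))
  save_art(rl_estimates, "rl_estimates.csv")
  save_art(list(waic = as.data.frame(comparison$waic),
                counts = as.list(comparison$counts),
                chisq_stat = unname(comparison$chisq$statistic),
                chisq_p = comparison$chisq$p.value),
           "model_comparison.json")

  say("stage 4: recognition simulation and RT filtering")
  rpes <- unlist(lapply(seq_along(kept), function(i)
    extract_rpes(fits[[i]]$rw, choices[choices$subject == kept[i], ])$rpe))
  recog <- simulate_recognition(choices, rpes = rpes, params = config$memory,
                                seed = derive_seed(config$seed, 104L))
  recog <- categorize_responses(recog)
  filt <- filter_rts(recog)
  save_art(recog, "recognition.csv", params = unclass(config$memory))

  say("stage 5: hierarchical drift regressions")
  dd <- config$ddm_sampler
  ddm_fits <- list(
    rpe = fit_hier_ddm(filt$data, "rpe", chains = dd$chains,
                       draws = dd$draws, warmup = dd$warmup,
                       seed = derive_seed(config$seed, 105L)),
    pm = fit_hier_ddm(filt$data, "pm", chains = dd$chains, draws = dd$draws,
                      warmup = dd$warmup,
                      seed = derive_seed(config$seed, 106L)))
  ddm_comparison <- compare_ddm_models(ddm_fits)
  save_art(ddm_comparison, "ddm_comparison.csv")

  say("stage 6: survey generation and factor analysis")
  sv <- config$surveys
  sv$seed <- derive_seed(config$seed, 107L)
  surveys <- generate_surveys(sv)
  adequacy <- list(kmo = kmo(surveys)$overall,
                   bartlett = bartlett_sphericity(surveys))
  k <- cng_nfactors(eigen(cor(surveys), symmetric = TRUE,
                          only.values = TRUE)$values)$k
  sol <- fit_factor_model(surveys, k)
  scores <- score_tenberge(sol, surveys)
  task_scores <- scores[seq_along(kept), , drop = FALSE]
  save_art(surveys, "surveys.csv")
  save_art(as.data.frame(unclass(sol$loadings)), "factor_loadings.csv")
  save_art(adequacy, "factor_adequacy.json")

  say("stage 7: mixed-effects memory regression")
  gs <- config$glm_sampler
  subject_covariates <- cbind(rl_estimates,
                              as.data.frame(task_scores))
  glm_fit <- fit_memory_glm(recog, subject_covariates = subject_covariates,
                            chains = gs$chains, draws = gs$draws,
                            warmup = gs$warmup,
                            seed = derive_seed(config$seed, 108L))
  save_art(glm_fit$fixed, "glm_fixed_effects.csv")

  say("stage 8: subject-level moderation and equivalence")
  table <- build_subject_table(recog, glm_fit,
                               factor_scores = task_scores,
                               rl_estimates = rl_estimates,
                               choices = choices)
  moderation <- interaction_regression(table, "dprime", "beta_rpe", "f1")
  inter <- moderation[moderation$term == "beta_rpe:f1", ]
  equivalence <- tost_equivalence(inter$B, inter$SE, inter$df)
  save_art(moderation, "moderation.csv")
  save_art(table, "subject_table.csv")

  structure(list(
    config = config,
    exclusion = excl$log,
    rl_comparison = comparison,
    rl_estimates = rl_estimates,
    true_rl = true_rl,
    rt_filter = filt$report,
    ddm_fits = ddm_fits,
    ddm_comparison = ddm_comparison,
    factor_adequacy = adequacy,
    factor_solution = sol,
    glm_fit = glm_fit,
    subject_table = table,
    moderation = moderation,
    equivalence = equivalence,
    artifacts = artifacts), class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Synthetic pipeline report\n")
  cat(sprintf("  subjects retained: %d of %d\n", sum(x$exclusion$retained),
              nrow(x$exclusion)))
  cat("  decision-model winners: ",
      paste(names(x$rl_comparison$counts), as.integer(x$rl_comparison$counts),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  drift-regression ranking: %s\n",
              paste(x$ddm_comparison$model, collapse = " > ")))
  cat(sprintf("  factor adequacy: KMO %.2f\n", x$factor_adequacy$kmo))
  cat(sprintf("  moderation interaction p = %.3g; TOST p_eq = %.3g\n",
              x$moderation$p[4], x$equivalence$p_eq))
  invisible(x)
}
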