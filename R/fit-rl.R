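rl_model_info <- function(model) {
  switch(model,
    rw = list(id = 0L, pars = c("alpha", "beta")),
    wsls = list(id = 1L, pars = "epsilon"),
    bayes = list(id = 2L, pars = c("p_reward", "p_switch")),
    stop("unknown model: ", model))
}

#' Fit a decision model to one subject's choices
#'
#' Posterior sampling by adaptive Metropolis on transformed (unconstrained)
#' parameter scales, with weakly informative bound-respecting priors:
#' `alpha ~ Beta(1,1)`, `beta ~ half-Normal(10)`, `epsilon ~ Beta(1,1)`,
#' `p_reward ~ U(0.5, 1)`, `p_switch ~ U(0, 0.5)`. Defaults are deliberately
#' generous (4 chains, 4000 posterior draws each after 4000 warm-up
#' iterations); tests and large batch jobs can reduce them.
#'
#' @param model one of `"rw"`, `"wsls"`, `"bayes"`
#' @param data data.frame with `choice` (0/1) and `reward` (0/1)
#' @param chains number of chains (>= 2 for convergence diagnostics)
#' @param draws posterior draws per chain
#' @param warmup warm-up (adaptation) iterations per chain, discarded
#' @param seed integer seed
#' @param rhat_limit convergence bound; any parameter at or above it raises a
#'   warning flag on the returned fit
#' @return an object of class `rl_fit`: `draws` (chains x draws x parameter
#'   array), `point_estimate` (posterior means), `rhat`, `waic`,
#'   `pointwise_loglik`, `converged`
#' @export
fit_model <- function(model = c("rw", "wsls", "bayes"), data,
                      chains = 4, draws = 4000, warmup = 4000, seed = 1L,
                      rhat_limit = 1.05) {
  model <- match.arg(model)
  check_choice_data(data)
  if (length(unique(data$choice)) < 2) {
    stop("degenerate data: fewer than 2 distinct choices")
  }
  stopifnot(chains >= 2, draws >= 10, warmup >= 10)
  info <- rl_model_info(model)
  set.seed(seed)
  res <- rl_mcmc_cpp(info$id, as.integer(data$choice),
                     as.integer(data$reward), chains, warmup, draws)
  d <- length(info$pars)
  arr <- array(NA_real_, dim = c(chains, draws, d),
               dimnames = list(NULL, NULL, info$pars))
  for (ch in seq_len(chains)) arr[ch, , ] <- res$chains[[ch]]
  rh <- vapply(seq_len(d), function(j) rhat_split(t(arr[, , j])),
               numeric(1))
  names(rh) <- info$pars
  flat <- apply(arr, 3, c) # (chains*draws) x d
  if (is.null(dim(flat))) flat <- matrix(flat, ncol = d)
  colnames(flat) <- info$pars
  pw <- switch(model,
    rw = rw_pointwise_cpp(flat[, "alpha"], flat[, "beta"],
                          as.integer(data$choice), as.integer(data$reward)),
    wsls = wsls_pointwise_cpp(flat[, "epsilon"],
                              as.integer(data$choice),
                              as.integer(data$reward)),
    bayes = bayes_pointwise_cpp(flat[, "p_reward"], flat[, "p_switch"],
                                as.integer(data$choice),
                                as.integer(data$reward)))
  w <- waic(pw)
  converged <- all(rh < rhat_limit)
  if (!converged) {
    warning(sprintf("fit_model(%s): max R-hat %.3f >= %.3f", model,
                    max(rh), rhat_limit))
  }
  structure(list(model = model, draws = arr,
                 point_estimate = colMeans(flat),
                 rhat = rh, waic = w, pointwise_loglik = pw,
                 n_trials = nrow(data), converged = converged,
                 warmup_accept = res$warmup_accept),
            class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s fit: %d trials\n", x$model, x$n_trials))
  est <- sprintf("%s = %.3f (R-hat %.3f)", names(x$point_estimate),
                 x$point_estimate, x$rhat)
  cat(" ", paste(est, collapse = "; "), "\n")
  cat(sprintf("  WAIC %.1f (SE %.1f)\n", x$waic$waic, x$waic$se))
  invisible(x)
}

#' Compare decision models across a cohort
#'
#' Computes WAIC (deviance scale) per subject and model, the per-subject
#' winner, and a chi-square test of the winner proportions against a uniform
#' split across models.
#'
#' @param fits a list over subjects; each element a named list of `rl_fit`
#'   objects for the same data
#' @return list with `waic` (subjects x models matrix), `winner`, `counts`,
#'   and `chisq` (an `htest`)
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  models <- names(fits[[1]])
  stopifnot(!is.null(models), length(models) >= 2)
  n_trials <- vapply(fits, function(f) {
    nt <- unique(vapply(f, function(x) x$n_trials, numeric(1)))
    if (length(nt) != 1) stop("fits within a subject use different trial counts")
    nt
  }, numeric(1))
  w <- t(vapply(fits, function(f)
    vapply(f[models], function(x) x$waic$waic, numeric(1)),
    numeric(length(models))))
  colnames(w) <- models
  winner <- models[apply(w, 1, which.min)]
  counts <- table(factor(winner, levels = models))
  chisq <- suppressWarnings(chisq.test(as.vector(counts)))
  list(waic = w, winner = winner, counts = counts, chisq = chisq,
       n_trials = n_trials)
}

#' Extract trial-level reward prediction errors from a Rescorla-Wagner fit
#'
#' Runs the delta-rule forward pass at the posterior-mean learning rate and
#' returns the continuous signed prediction error `r_t - Q_t` (chosen option,
#' pre-update) for every trial.
#'
#' @param fit an `rl_fit` with `model == "rw"`
#' @param data the choice data the model was fit to
#' @return data.frame with `trial`, `rpe`, `q_chosen`
#' @export
extract_rpes <- function(fit, data) {
  if (!inherits(fit, "rl_fit") || fit$model != "rw") {
    stop("extract_rpes requires a Rescorla-Wagner fit")
  }
  tr <- rw_loglik(list(alpha = fit$point_estimate[["alpha"]],
                       beta = fit$point_estimate[["beta"]]), data)
  data.frame(trial = seq_along(tr$rpe), rpe = tr$rpe,
             q_chosen = tr$q_chosen)
}

#' Simulate-and-refit parameter recovery
#'
#' Draws true parameters from `true_param_sampler`, simulates each agent on
#' its own schedule, refits the generating model, and reports the Pearson
#' correlation and mean bias between true and recovered (posterior mean)
#' parameters.
#'
#' @param model generative and fitting model name
#' @param n_agents number of simulated agents (>= 2)
#' @param true_param_sampler function(n) returning a data.frame of true
#'   parameters with the model's parameter names
#' @param seed integer seed
#' @param config task configuration for the simulated schedules
#' @param chains,draws,warmup sampler settings passed to [fit_model()]
#' @return list with `true`, `recovered`, `correlation`, `bias`, `max_rhat`
#' @export
parameter_recovery <- function(model, n_agents, true_param_sampler,
                               seed = 1L, config = task_config(),
                               chains = 4, draws = 1000, warmup = 1000) {
  stopifnot(n_agents >= 2)
  set.seed(seed)
  true <- true_param_sampler(n_agents)
  pars <- rl_model_info(model)$pars
  stopifnot(all(pars %in% names(true)))
  specs <- lapply(seq_len(n_agents), function(i)
    do.call(agent_spec, c(list(model = model), as.list(true[i, pars, drop = FALSE]))))
  rec <- matrix(NA_real_, n_agents, length(pars),
                dimnames = list(NULL, pars))
  max_rhat <- 0
  for (i in seq_len(n_agents)) {
    cfg <- config; cfg$seed <- derive_seed(seed, 11L, i)
    sched <- generate_task_schedule(cfg)
    dat <- simulate_agent(specs[[i]], sched, seed = derive_seed(seed, 12L, i))
    fit <- fit_model(model, dat, chains = chains, draws = draws,
                     warmup = warmup, seed = derive_seed(seed, 13L, i))
    rec[i, ] <- fit$point_estimate[pars]
    max_rhat <- max(max_rhat, fit$rhat)
  }
  correlation <- vapply(pars, function(p) {
    if (sd(true[[p]]) == 0) return(NA_real_)
    cor(true[[p]], rec[, p])
  }, numeric(1))
  bias <- vapply(pars, function(p) mean(rec[, p] - true[[p]]), numeric(1))
  list(true = true[, pars, drop = FALSE], recovered = as.data.frame(rec),
       correlation = correlation, bias = bias, max_rhat = max_rhat)
}

#' Model identifiability confusion matrix
#'
#' Simulates cohorts from each model, fits every model to every agent, and
#' counts which model wins the WAIC comparison.
#'
#' @param n_per_model agents simulated per generative model
#' @param param_samplers named list of functions(n) returning true-parameter
#'   data.frames, one per model
#' @param seed integer seed
#' @param config task configuration
#' @param chains,draws,warmup sampler settings
#' @return list with `counts` (generative x best-fitting matrix) and
#'   `max_rhat`
#' @export
identifiability_matrix <- function(n_per_model = 30,
                                   param_samplers = default_param_samplers(),
                                   seed = 1L, config = task_config(),
                                   chains = 2, draws = 1000, warmup = 1000) {
  models <- names(param_samplers)
  counts <- matrix(0L, length(models), length(models),
                   dimnames = list(generative = models, best = models))
  max_rhat <- 0
  for (gi in seq_along(models)) {
    gen <- models[gi]
    set.seed(derive_seed(seed, 20L, gi))
    true <- param_samplers[[gen]](n_per_model)
    pars <- rl_model_info(gen)$pars
    for (i in seq_len(n_per_model)) {
      cfg <- config; cfg$seed <- derive_seed(seed, 21L, gi, i)
      sched <- generate_task_schedule(cfg)
      spec <- do.call(agent_spec, c(list(model = gen), as.list(true[i, pars, drop = FALSE])))
      dat <- simulate_agent(spec, sched, seed = derive_seed(seed, 22L, gi, i))
      if (length(unique(dat$choice)) < 2) next
      ws <- vapply(models, function(m) {
        fit <- fit_model(m, dat, chains = chains, draws = draws,
                         warmup = warmup,
                         seed = derive_seed(seed, 23L, gi, i, match(m, models)))
        max_rhat <<- max(max_rhat, fit$rhat)
        fit$waic$waic
      }, numeric(1))
      best <- models[which.min(ws)]
      counts[gen, best] <- counts[gen, best] + 1L
    }
  }
  list(counts = counts, max_rhat = max_rhat)
}

#' Default generative parameter samplers for identifiability checks
#'
#' Ranges bracket the cohort-scale estimates (learning rates mostly above
#' 0.4, inverse temperatures of a few units) while keeping each family's
#' behaviour characteristic.
#'
#' @return named list of sampler functions
#' @export
default_param_samplers <- function() {
  list(
    rw = function(n) data.frame(alpha = runif(n, 0.4, 0.9),
                                beta = runif(n, 2, 8)),
    wsls = function(n) data.frame(epsilon = runif(n, 0.75, 0.95)),
    bayes = function(n) data.frame(p_reward = runif(n, 0.65, 0.9),
                                   p_switch = runif(n, 0.03, 0.15))
  )
}

#' Reward landscape over Rescorla-Wagner parameters
#'
#' Grid search over (alpha, beta): each cell's value is the mean total reward
#' (0/1 units) accumulated by simulated agents over `n_sims` freshly drawn
#' schedules.
#'
#' @param alpha_grid,beta_grid numeric grids
#' @param n_sims simulated schedules per cell
#' @param config task configuration
#' @param seed integer seed
#' @return matrix (alpha x beta) of mean accumulated reward
#' @export
reward_landscape <- function(alpha_grid, beta_grid, n_sims = 100,
                             config = task_config(), seed = 1L) {
  stopifnot(length(alpha_grid) >= 1, length(beta_grid) >= 1, n_sims >= 1)
  out <- matrix(NA_real_, length(alpha_grid), length(beta_grid),
                dimnames = list(alpha = signif(alpha_grid, 3),
                                beta = signif(beta_grid, 3)))
  for (ai in seq_along(alpha_grid)) {
    for (bi in seq_along(beta_grid)) {
      spec <- agent_spec("rw", alpha = alpha_grid[ai], beta = beta_grid[bi])
      tot <- numeric(n_sims)
      for (s in seq_len(n_sims)) {
        cfg <- config; cfg$seed <- derive_seed(seed, 31L, s)
        sched <- generate_task_schedule(cfg)
        dat <- simulate_agent(spec, sched,
                              seed = derive_seed(seed, 32L, ai, bi, s))
        tot[s] <- sum(dat$reward)
      }
      out[ai, bi] <- mean(tot)
    }
  }
  out
}
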