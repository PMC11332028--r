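#' Label recognition responses
#'
#' Hits (old probe called "old") and correct rejections (lure called "new")
#' are correct memory choices; misses and false alarms are incorrect. Rows
#' with a missing response are dropped with a message.
#'
#' @param data recognition data.frame with `is_old` (logical) and `response`
#'   ("old"/"new")
#' @return the data with `label` and `correct` columns added
#' @export
categorize_responses <- function(data) {
  stopifnot(all(c("is_old", "response") %in% names(data)))
  miss <- is.na(data$response)
  if (any(miss)) {
    message(sum(miss), " probes dropped for missing responses")
    data <- data[!miss, ]
  }
  said_old <- data$response == "old"
  data$label <- ifelse(data$is_old & said_old, "hit",
                ifelse(data$is_old & !said_old, "miss",
                ifelse(!data$is_old & !said_old, "correct_rejection",
                       "false_alarm")))
  data$correct <- data$label %in% c("hit", "correct_rejection")
  data
}

#' Signal-detection sensitivity
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`, with extreme rates
#' clamped to `[1/(2N), 1 - 1/(2N)]` (N the number of probes of that class)
#' so the quantile function stays finite.
#'
#' @param labels a labeled data.frame for one subject (see
#'   [categorize_responses()]), or a vector of labels
#' @return d-prime value
#' @export
compute_dprime <- function(labels) {
  lab <- if (is.data.frame(labels)) labels$label else labels
  n_old <- sum(lab %in% c("hit", "miss"))
  n_new <- sum(lab %in% c("correct_rejection", "false_alarm"))
  if (n_old == 0 || n_new == 0) stop("need both old and lure probes")
  clamp <- function(rate, n) min(max(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
  hr <- clamp(sum(lab == "hit") / n_old, n_old)
  far <- clamp(sum(lab == "false_alarm") / n_new, n_new)
  qnorm(hr) - qnorm(far)
}

#' Bayesian mixed-effects logistic regression of memory success
#'
#' Models the probability of a correct old/new judgement with a logit link:
#' fixed effects for the supplied trial- and subject-level predictors, a
#' random intercept per subject, and random RPE and memorability slopes per
#' subject. All numeric predictors are standardized by the 2-SD rule before
#' fitting (categorical predictors get sum-to-zero contrasts); lure rows
#' carry zero-imputed (mean) RPE and encoding-trial values. Priors are
#' weakly informative: `Normal(0, 2.5)` on fixed effects, `half-Normal(1)`
#' on random-effect SDs. Sampling is Gibbs/slice MCMC via JAGS.
#'
#' @param data labeled recognition data (see [categorize_responses()]) with
#'   `rpe_std`, `pm_std`, `trial_std` columns (as produced by
#'   [simulate_recognition()]); `correct` is the outcome
#' @param subject_covariates optional data.frame (one row per subject) of
#'   additional fixed effects, e.g. age, sex, RL parameters, total reward,
#'   factor scores; numeric columns are 2-SD standardized, factors/character
#'   columns contrast-coded
#' @param fixed character vector naming trial-level predictors to include
#' @param chains,draws,warmup sampler settings; defaults are reduced relative
#'   to [fit_model()] because each Gibbs update sweeps all subjects
#' @param seed integer seed
#' @param rhat_limit convergence bound
#' @return object of class `memory_glm_fit`: `fixed` (summary data.frame with
#'   posterior mean, 95% HDI and a `meaningful` flag set when the HDI
#'   excludes zero), `subject_beta_rpe`, `subject_beta_pm`,
#'   `subject_intercept`, `sd_posteriors`, `rhat`, `waic`, `draws`
#' @export
fit_memory_glm <- function(data, subject_covariates = NULL,
                           fixed = c("rpe_std", "pm_std", "trial_std"),
                           chains = 2, draws = 1500, warmup = 1500,
                           seed = 1L, rhat_limit = 1.05) {
  stopifnot(all(c("correct", "subject") %in% names(data)),
            all(fixed %in% names(data)))
  y <- as.integer(data$correct)
  if (all(y == 1) || all(y == 0)) {
    stop("degenerate outcome: all responses correct or all incorrect")
  }
  subj_ids <- sort(unique(data$subject))
  subj <- match(data$subject, subj_ids)
  X <- as.matrix(data[, fixed, drop = FALSE])
  if (!is.null(subject_covariates)) {
    stopifnot("subject" %in% names(subject_covariates))
    sc <- subject_covariates[match(subj_ids, subject_covariates$subject), ,
                             drop = FALSE]
    for (nm in setdiff(names(sc), "subject")) {
      v <- sc[[nm]]
      if (is.numeric(v)) {
        X <- cbind(X, setNames(data.frame(standardize_2sd(v)[subj]), nm))
      } else {
        f <- factor(v)
        contrasts(f) <- stats::contr.sum(nlevels(f))
        mm <- model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(nm, seq_len(ncol(mm)))
        X <- cbind(X, mm[subj, , drop = FALSE])
      }
    }
    X <- as.matrix(X)
  }
  p <- ncol(X)
  rpe_col <- if ("rpe_std" %in% names(data)) data$rpe_std else rep(0, nrow(data))
  pm_col <- if ("pm_std" %in% names(data)) data$pm_std else rep(0, nrow(data))

  model_str <- "
  model {
    for (i in 1:N) {
      y[i] ~ dbern(p[i])
      logit(p[i]) <- b0 + inprod(X[i,], beta[]) + u[subj[i],1] +
                     u[subj[i],2] * rpe[i] + u[subj[i],3] * pm[i]
    }
    b0 ~ dnorm(0, 0.16)
    for (j in 1:P) { beta[j] ~ dnorm(0, 0.16) }
    for (s in 1:S) {
      for (k in 1:3) { u[s,k] ~ dnorm(0, tau[k]) }
    }
    for (k in 1:3) {
      sigma[k] ~ dnorm(0, 1) T(0,)
      tau[k] <- 1 / (sigma[k] * sigma[k])
    }
  }"
  jdata <- list(y = y, X = X, subj = subj, rpe = rpe_col, pm = pm_col,
                N = length(y), P = p, S = length(subj_ids))
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, 51L, ch)))
  quiet <- function(expr) {
    out <- utils::capture.output(res <- expr)
    res
  }
  # the glm module provides efficient block samplers for the logistic layer
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  jm <- quiet(rjags::jags.model(textConnection(model_str), data = jdata,
                                inits = inits, n.chains = chains,
                                n.adapt = min(1000, warmup),
                                quiet = TRUE))
  quiet(stats::update(jm, warmup))
  samp <- quiet(rjags::coda.samples(jm, c("b0", "beta", "u", "sigma"),
                                    n.iter = draws))

  nm <- colnames(samp[[1]])
  get_cols <- function(pattern) grep(pattern, nm)
  fixed_names <- c("(intercept)", colnames(X))
  fixed_idx <- c(get_cols("^b0$"), get_cols("^beta\\["))
  chains_mat <- lapply(samp, as.matrix)
  all_draws <- do.call(rbind, chains_mat)

  rh <- vapply(seq_along(nm), function(j)
    rhat_split(vapply(chains_mat, function(m2) m2[, j],
                      numeric(nrow(chains_mat[[1]])))), numeric(1))
  names(rh) <- nm

  fixed_sum <- do.call(rbind, lapply(seq_along(fixed_idx), function(k) {
    dr <- all_draws[, fixed_idx[k]]
    h <- hdi(dr)
    data.frame(term = fixed_names[k], mean = mean(dr),
               hdi_lower = h[["lower"]], hdi_upper = h[["upper"]],
               meaningful = h[["lower"]] > 0 | h[["upper"]] < 0)
  }))

  u_mean <- function(k) vapply(seq_along(subj_ids), function(s)
    mean(all_draws[, sprintf("u[%d,%d]", s, k)]), numeric(1))
  # total subject slopes = fixed effect + subject deviation
  fix_of <- function(term) {
    i <- match(term, fixed_sum$term)
    if (is.na(i)) 0 else fixed_sum$mean[i]
  }

  # pointwise log-likelihood for WAIC (thinned for memory)
  thin_idx <- unique(round(seq(1, nrow(all_draws),
                               length.out = min(1000, nrow(all_draws)))))
  eta_fix <- all_draws[thin_idx, fixed_idx[1]] %o% rep(1, length(y)) +
    all_draws[thin_idx, fixed_idx[-1], drop = FALSE] %*% t(X)
  u1 <- all_draws[thin_idx, sprintf("u[%d,1]", subj), drop = FALSE]
  u2 <- all_draws[thin_idx, sprintf("u[%d,2]", subj), drop = FALSE]
  u3 <- all_draws[thin_idx, sprintf("u[%d,3]", subj), drop = FALSE]
  eta <- eta_fix + u1 +
    sweep(u2, 2, rpe_col, "*") + sweep(u3, 2, pm_col, "*")
  pr <- plogis(eta)
  ll <- log(ifelse(rep(y, each = nrow(pr)) == 1, pr, 1 - pr))
  dim(ll) <- dim(pr)
  w <- waic(ll)

  converged <- all(rh < rhat_limit)
  if (!converged) {
    warning(sprintf("fit_memory_glm: max R-hat %.3f >= %.3f",
                    max(rh), rhat_limit))
  }
  structure(list(
    fixed = fixed_sum,
    subject_ids = subj_ids,
    subject_intercept = u_mean(1),
    subject_beta_rpe = fix_of("rpe_std") + u_mean(2),
    subject_beta_pm = fix_of("pm_std") + u_mean(3),
    sd_posteriors = colMeans(all_draws[, get_cols("^sigma"), drop = FALSE]),
    rhat = rh, waic = w, draws = samp, converged = converged),
    class = "memory_glm_fit")
}

#' @export
print.memory_glm_fit <- function(x, ...) {
  cat("Bayesian mixed-effects logistic regression of memory success\n")
  print(transform(x$fixed, mean = round(mean, 3),
                  hdi_lower = round(hdi_lower, 3),
                  hdi_upper = round(hdi_upper, 3)), row.names = FALSE)
  cat(sprintf("WAIC %.1f; max R-hat %.3f\n", x$waic$waic, max(x$rhat)))
  invisible(x)
}
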