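#' Wiener first-passage-time density
#'
#' Density of the first-passage time of a unit-variance diffusion with drift
#' `v` between absorbing boundaries 0 and `a`, starting at relative position
#' `z`, shifted by non-decision time `t`. The upper boundary codes an "old"
#' response. Evaluated by the dual small-time/large-time series expansion
#' with automatic switching; the density is zero for `rt <= t`.
#'
#' @param rt reaction times (seconds); vectorized
#' @param boundary `"upper"` or `"lower"` (recycled)
#' @param v drift rate (scalar or per-rt vector)
#' @param a boundary separation (> 0)
#' @param z relative start point in (0, 1)
#' @param t non-decision time (>= 0 seconds)
#' @param log return log density
#' @return density values (1/seconds)
#' @export
wfpt_density <- function(rt, boundary = "upper", v, a, z, t, log = FALSE) {
  stopifnot(a > 0, z > 0, z < 1, t >= 0)
  n <- length(rt)
  up <- as.integer(rep_len(boundary, n) == "upper")
  vv <- rep_len(v, n)
  ld <- wfpt_logdensity_cpp(as.numeric(rt), up, vv, a, z, t)
  if (log) ld else exp(ld)
}

#' Simulate diffusion first passages
#'
#' Euler-Maruyama forward simulation; reproducible given `seed`.
#'
#' @param n number of paths (ignored when `v` is a vector)
#' @param v drift rate(s)
#' @param a,z,t diffusion parameters as in [wfpt_density()]
#' @param dt Euler time step (seconds)
#' @param max_t give up after this much decision time
#' @param seed integer seed
#' @return data.frame with `rt` and `boundary` ("upper"/"lower", NA if not
#'   absorbed)
#' @export
simulate_ddm <- function(n = 1, v, a, z, t, dt = 1e-4, max_t = 30,
                         seed = 1L) {
  if (length(v) == 1) v <- rep(v, n)
  sim <- simulate_ddm_paths_cpp(v, a, z, t, dt, max_t, as.integer(seed))
  data.frame(rt = sim$rt,
             boundary = c("lower", "upper")[sim$boundary + 1L])
}

#' Reaction-time exclusions for recognition data
#'
#' Drops trials faster than 300 ms or slower than 10 s, then trials beyond 3
#' subject-level standard deviations from the subject-level mean (computed on
#' the absolute-bound survivors). Subjects left with fewer than 2 trials are
#' flagged for exclusion from hierarchical fits.
#'
#' @param data recognition data.frame with `subject` and `rt` (seconds)
#' @param fast_cut,slow_cut absolute bounds (seconds)
#' @param sd_cut multiple of the subject SD
#' @return list with `data` (retained rows) and `report` (class
#'   `rt_filter_report`: `n_input`, `n_excluded_fast`, `n_excluded_slow`,
#'   `n_excluded_sd`, `subject_stats`, `flagged_subjects`)
#' @export
filter_rts <- function(data, fast_cut = 0.3, slow_cut = 10, sd_cut = 3) {
  stopifnot(all(c("subject", "rt") %in% names(data)), all(data$rt > 0,
            na.rm = TRUE))
  n_input <- nrow(data)
  fast <- data$rt < fast_cut
  slow <- data$rt > slow_cut
  keep <- data[!fast & !slow, ]
  stats <- aggregate(rt ~ subject, keep, function(x) c(mean(x), sd(x)))
  mu <- setNames(stats$rt[, 1], stats$subject)
  sdv <- setNames(stats$rt[, 2], stats$subject)
  sdv[is.na(sdv)] <- 0
  dev <- abs(keep$rt - mu[as.character(keep$subject)])
  out_sd <- dev > sd_cut * sdv[as.character(keep$subject)] &
    sdv[as.character(keep$subject)] > 0
  retained <- keep[!out_sd, ]
  counts <- table(retained$subject)
  flagged <- names(counts)[counts < 2]
  report <- structure(list(
    n_input = n_input,
    n_excluded_fast = sum(fast),
    n_excluded_slow = sum(slow),
    n_excluded_sd = sum(out_sd),
    n_retained = nrow(retained),
    subject_stats = data.frame(subject = stats$subject, mean = mu, sd = sdv),
    flagged_subjects = flagged), class = "rt_filter_report")
  list(data = retained, report = report)
}

#' @export
print.rt_filter_report <- function(x, ...) {
  cat(sprintf(
    "RT filter: %d trials in; %d fast (<300 ms), %d slow (>10 s), %d beyond 3 SD; %d retained\n",
    x$n_input, x$n_excluded_fast, x$n_excluded_slow, x$n_excluded_sd,
    x$n_retained))
  invisible(x)
}

ddm_link <- function(x, link) {
  switch(link,
    linear = x,
    quadratic = x^2,
    log = log(x - min(x) + 1),
    stop("unknown link: ", link))
}

#' Hierarchical drift-regression fit
#'
#' Fits a drift-diffusion model in which the per-trial drift rate is a linear
#' function of a standardized trial covariate (RPE or perceptual
#' memorability) with a random intercept and random slope per subject, while
#' boundary separation, start point, and non-decision time are pooled across
#' subjects:
#' `v_ij = (mu_v + u_i) + (b_v + w_i) * g(x_ij)`.
#' `g` is the identity, square, or shifted log (`log(x - min(x) + 1)`, so
#' signed covariates stay in the log's domain). By default only old-probe
#' trials enter (the RPE covariate is undefined for lures); set
#' `old_only = FALSE` to use all trials with zero-imputed lure covariates.
#' Sampling is Metropolis-within-Gibbs with adaptive proposals.
#'
#' @param data filtered, labeled recognition data with `rt`, `response`,
#'   `subject`, and the standardized covariate columns `rpe_std` / `pm_std`
#' @param covariate `"rpe"` or `"pm"`
#' @param link `"linear"`, `"quadratic"`, or `"log"`
#' @param old_only restrict to old probes (default TRUE)
#' @param chains,draws,warmup sampler settings
#' @param seed integer seed
#' @param rhat_limit convergence bound
#' @return object of class `hier_ddm_fit`: `summary` (posterior mean and 95%
#'   HDI for group intercept, group slope, SDs, `a`, `z`, `t`), `group_slope`
#'   draws, `subject_effects`, `rhat`, `waic`, `draws`
#' @export
fit_hier_ddm <- function(data, covariate = c("rpe", "pm"),
                         link = c("linear", "quadratic", "log"),
                         old_only = TRUE,
                         chains = 2, draws = 1500, warmup = 1500,
                         seed = 1L, rhat_limit = 1.05) {
  covariate <- match.arg(covariate)
  link <- match.arg(link)
  col <- paste0(covariate, "_std")
  stopifnot(all(c("rt", "response", "subject", col) %in% names(data)))
  if (old_only) data <- data[data$is_old, ]
  counts <- table(data$subject)
  good <- names(counts)[counts >= 2]
  data <- data[as.character(data$subject) %in% good, ]
  subj_ids <- sort(unique(data$subject))
  subj <- match(data$subject, subj_ids) - 1L
  x <- ddm_link(data[[col]], link)
  upper <- as.integer(data$response == "old")
  t0_hi <- max(0.06, min(data$rt) * 0.99)
  t0_lo <- min(0.05, t0_hi / 2)

  chain_draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(derive_seed(seed, 61L, ch))
    res <- ddm_hier_mcmc_cpp(data$rt, upper, subj, x, length(subj_ids),
                             warmup, draws, t0_lo, t0_hi)
    chain_draws[[ch]] <- res$draws
  }
  n_subj <- length(subj_ids)
  par_names <- c("mu_intercept", "mu_slope", "sigma_intercept", "sigma_slope",
                 "a", "z", "t",
                 paste0("u_int[", seq_len(n_subj), "]"),
                 paste0("u_slope[", seq_len(n_subj), "]"))
  rh <- vapply(seq_along(par_names), function(j)
    rhat_split(vapply(chain_draws, function(m) m[, j], numeric(draws))),
    numeric(1))
  names(rh) <- par_names
  all_draws <- do.call(rbind, chain_draws)
  colnames(all_draws) <- par_names

  summ <- do.call(rbind, lapply(1:7, function(j) {
    h <- hdi(all_draws[, j])
    data.frame(term = par_names[j], mean = mean(all_draws[, j]),
               hdi_lower = h[["lower"]], hdi_upper = h[["upper"]])
  }))

  thin_idx <- unique(round(seq(1, nrow(all_draws),
                               length.out = min(400, nrow(all_draws)))))
  pw <- ddm_hier_pointwise_cpp(all_draws[thin_idx, , drop = FALSE],
                               data$rt, upper, subj, x, n_subj)
  w <- waic(pw)
  converged <- all(rh[1:7] < rhat_limit)
  if (!converged) {
    warning(sprintf("fit_hier_ddm: max R-hat %.3f >= %.3f",
                    max(rh[1:7]), rhat_limit))
  }
  structure(list(
    covariate = covariate, link = link,
    summary = summ,
    group_slope = all_draws[, "mu_slope"],
    group_intercept = all_draws[, "mu_intercept"],
    subject_effects = data.frame(
      subject = subj_ids,
      intercept = colMeans(all_draws[, 7 + seq_len(n_subj), drop = FALSE]),
      slope = colMeans(all_draws[, 7 + n_subj + seq_len(n_subj),
                                 drop = FALSE])),
    rhat = rh, waic = w, draws = all_draws, n_trials = nrow(data),
    converged = converged), class = "hier_ddm_fit")
}

#' @export
print.hier_ddm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical DDM: drift ~ %s (%s link), %d trials\n",
              x$covariate, x$link, x$n_trials))
  print(transform(x$summary, mean = round(mean, 3),
                  hdi_lower = round(hdi_lower, 3),
                  hdi_upper = round(hdi_upper, 3)), row.names = FALSE)
  cat(sprintf("WAIC %.1f; max R-hat %.3f\n", x$waic$waic, max(x$rhat[1:7])))
  invisible(x)
}

#' Compare hierarchical DDM fits by WAIC
#'
#' @param fits named list of `hier_ddm_fit` objects fit to the same trials
#' @return data.frame ranked by WAIC with differences to the best model and
#'   the difference SE
#' @export
compare_ddm_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  nt <- unique(vapply(fits, function(f) f$n_trials, numeric(1)))
  if (length(nt) != 1) stop("fits use different trial sets")
  nms <- names(fits)
  if (is.null(nms)) nms <- paste0("model", seq_along(fits))
  wa <- vapply(fits, function(f) f$waic$waic, numeric(1))
  ord <- order(wa)
  best_pw <- fits[[ord[1]]]$waic$pointwise
  d_se <- vapply(fits, function(f) {
    d <- -2 * (f$waic$pointwise - best_pw)
    sqrt(length(d) * var(d))
  }, numeric(1))
  out <- data.frame(model = nms[ord], waic = wa[ord],
                    d_waic = wa[ord] - wa[ord[1]], d_se = d_se[ord])
  rownames(out) <- NULL
  out
}
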