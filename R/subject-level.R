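#' Assemble the subject-level analysis table
#'
#' One row per subject: memory accuracy and d-prime from the labeled
#' recognition data, subject random slopes from the fitted memory regression,
#' factor scores, RL point estimates, total reward, and mean recognition RT.
#'
#' @param recog labeled recognition data (see [categorize_responses()])
#' @param glm_fit a [fit_memory_glm()] result
#' @param factor_scores optional matrix of factor scores with rownames or
#'   rows aligned to `glm_fit$subject_ids`
#' @param rl_estimates optional data.frame with `subject`, `alpha`, `beta`
#' @param choices optional cohort choice data for total reward
#' @return data.frame of class `subject_table`
#' @export
build_subject_table <- function(recog, glm_fit, factor_scores = NULL,
                                rl_estimates = NULL, choices = NULL) {
  ids <- glm_fit$subject_ids
  acc <- vapply(ids, function(s)
    mean(recog$correct[recog$subject == s]), numeric(1))
  dp <- vapply(ids, function(s)
    compute_dprime(recog[recog$subject == s, ]), numeric(1))
  rt <- vapply(ids, function(s)
    mean(recog$rt[recog$subject == s]), numeric(1))
  out <- data.frame(subject = ids, memory_accuracy = acc, dprime = dp,
                    mean_rt = rt,
                    beta_rpe = glm_fit$subject_beta_rpe,
                    beta_pm = glm_fit$subject_beta_pm)
  if (!is.null(factor_scores)) {
    fs <- as.matrix(factor_scores)
    stopifnot(nrow(fs) == length(ids))
    colnames(fs) <- paste0("f", seq_len(ncol(fs)))
    out <- cbind(out, fs)
  }
  if (!is.null(rl_estimates)) {
    out <- merge(out, rl_estimates, by = "subject", all.x = TRUE, sort = TRUE)
  }
  if (!is.null(choices)) {
    tot <- aggregate(reward ~ subject, choices, sum)
    names(tot)[2] <- "total_reward"
    out <- merge(out, tot, by = "subject", all.x = TRUE, sort = TRUE)
  }
  class(out) <- c("subject_table", class(out))
  out
}

#' Subject-level moderation regression
#'
#' Ordinary least squares of a subject-level memory outcome on a subject
#' random slope, a moderator (e.g. a transdiagnostic factor score), and
#' their interaction. Numeric predictors are standardized by the 2-SD rule
#' before fitting.
#'
#' @param table a subject-level data.frame (>= 10 rows)
#' @param outcome outcome column name (e.g. `"dprime"` or
#'   `"memory_accuracy"`)
#' @param slope random-slope column name (e.g. `"beta_rpe"`)
#' @param moderator moderator column name (e.g. `"f1"`)
#' @param standardize standardize the two predictors (default TRUE)
#' @param condition_limit flag collinearity above this design condition
#'   number
#' @return data.frame of class `regression_result` with one row per term:
#'   `term`, `B`, `SE`, `t`, `df`, `p`, `ci_lower`, `ci_upper`; the fitted
#'   `lm` is attached as attribute `"fit"`
#' @export
interaction_regression <- function(table, outcome, slope, moderator,
                                   standardize = TRUE,
                                   condition_limit = 1e6) {
  stopifnot(nrow(table) >= 10,
            all(c(outcome, slope, moderator) %in% names(table)))
  d <- data.frame(y = table[[outcome]],
                  s = table[[slope]],
                  m = table[[moderator]])
  d <- d[complete.cases(d), ]
  if (standardize) {
    d$s <- as.numeric(standardize_2sd(d$s))
    d$m <- as.numeric(standardize_2sd(d$m))
  }
  X <- model.matrix(~ s * m, d)
  cn <- kappa(X, exact = TRUE)
  if (cn > condition_limit) {
    warning(sprintf("design condition number %.2g exceeds %g", cn,
                    condition_limit))
  }
  fit <- lm(y ~ s * m, data = d)
  sm <- summary(fit)$coefficients
  df <- fit$df.residual
  tcrit <- qt(0.975, df)
  terms <- c("(intercept)", slope, moderator,
             paste0(slope, ":", moderator))
  out <- data.frame(term = terms, B = sm[, 1], SE = sm[, 2], t = sm[, 3],
                    df = df, p = sm[, 4],
                    ci_lower = sm[, 1] - tcrit * sm[, 2],
                    ci_upper = sm[, 1] + tcrit * sm[, 2])
  rownames(out) <- NULL
  class(out) <- c("regression_result", class(out))
  attr(out, "fit") <- fit
  attr(out, "condition_number") <- cn
  out
}

#' Two one-sided tests of equivalence for a regression coefficient
#'
#' Tests whether a coefficient lies within the equivalence bounds: one-sided
#' t-tests against each bound, with the equivalence p-value the larger of the
#' two one-sided p-values. Equivalence is concluded at `p_eq < 0.05`.
#'
#' @param B coefficient estimate
#' @param SE its standard error (> 0)
#' @param df residual degrees of freedom
#' @param bounds length-2 equivalence bounds (default `c(-0.1, 0.1)`)
#' @return list of class `equivalence_result`: `t_lower`, `t_upper`, `df`,
#'   `p_eq`, `bounds`, `equivalent`
#' @export
tost_equivalence <- function(B, SE, df, bounds = c(-0.1, 0.1)) {
  stopifnot(SE > 0, df > 0, length(bounds) == 2, bounds[1] < bounds[2])
  t_lower <- (B - bounds[1]) / SE # H0: B <= lower bound
  t_upper <- (B - bounds[2]) / SE # H0: B >= upper bound
  p_lower <- pt(t_lower, df, lower.tail = FALSE)
  p_upper <- pt(t_upper, df, lower.tail = TRUE)
  p_eq <- max(p_lower, p_upper)
  structure(list(t_lower = t_lower, t_upper = t_upper, df = df,
                 t_eq = c(t_lower, t_upper)[which.max(c(p_lower, p_upper))],
                 p_eq = p_eq, bounds = bounds,
                 equivalent = p_eq < 0.05),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "TOST equivalence vs [%.3g, %.3g]: t_lower = %.2f, t_upper = %.2f, df = %d, p_eq = %.4g (%s)\n",
    x$bounds[1], x$bounds[2], x$t_lower, x$t_upper, as.integer(x$df), x$p_eq,
    if (x$equivalent) "equivalent" else "not equivalent"))
  invisible(x)
}
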