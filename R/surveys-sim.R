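#' Generative parameters for symptom survey matrices
#'
#' Defines an oblique latent-factor model for Likert item responses. The
#' default emulates the three-scale battery used with this task (a 20-item
#' trait-anxiety scale, a 20-item depression scale, and an 18-item
#' obsessive-compulsive inventory, all on 4-point Likert scales) loading on
#' three correlated factors, with the factor correlations set to the
#' cohort-level estimates (-0.62, -0.22, -0.38).
#'
#' @param loadings item x factor matrix
#' @param factor_corr factor correlation matrix (symmetric positive definite,
#'   unit diagonal)
#' @param uniqueness per-item unique variance; defaults to
#'   `1 - diag(L Phi L')` so items have unit variance on the continuous scale
#' @param likert_levels number of response levels
#' @param n_respondents rows to generate
#' @param seed integer seed
#' @param item_scale character vector labelling each item's scale of origin;
#'   defaults to STAI-T/SDS/OCI-R blocks for the default 58-item battery
#' @param reverse_coded logical per item: responses are emitted on the
#'   flipped Likert scale and must be recoded (see [recode_reversed()])
#'   before analysis
#' @return object of class `survey_gen_params`
#' @export
survey_gen_params <- function(loadings = default_survey_loadings(),
                              factor_corr = matrix(c(1, -0.62, -0.22,
                                                     -0.62, 1, -0.38,
                                                     -0.22, -0.38, 1), 3, 3),
                              uniqueness = NULL,
                              likert_levels = 4, n_respondents = 320,
                              seed = 1L, item_scale = NULL,
                              reverse_coded = NULL) {
  stopifnot(is.matrix(loadings), is.matrix(factor_corr),
            ncol(loadings) == ncol(factor_corr),
            isTRUE(all.equal(factor_corr, t(factor_corr))),
            isTRUE(all.equal(diag(factor_corr),
                             rep(1, ncol(factor_corr)))))
  ev <- eigen(factor_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("factor_corr must be positive definite")
  communality <- rowSums((loadings %*% factor_corr) * loadings)
  if (is.null(uniqueness)) uniqueness <- 1 - communality
  if (any(uniqueness <= 0)) stop("communalities must be below 1")
  if (is.null(item_scale)) {
    item_scale <- if (nrow(loadings) == 58) {
      rep(c("STAI-T", "SDS", "OCI-R"), c(20, 20, 18))
    } else rep("scale1", nrow(loadings))
  }
  if (is.null(reverse_coded)) reverse_coded <- rep(FALSE, nrow(loadings))
  stopifnot(length(item_scale) == nrow(loadings),
            length(reverse_coded) == nrow(loadings))
  structure(list(loadings = loadings, factor_corr = factor_corr,
                 uniqueness = uniqueness,
                 likert_levels = as.integer(likert_levels),
                 n_respondents = as.integer(n_respondents),
                 seed = as.integer(seed), item_scale = item_scale,
                 reverse_coded = as.logical(reverse_coded)),
            class = "survey_gen_params")
}

#' Default three-factor block loading structure
#'
#' 58 items in blocks of 20/20/18 with primary loadings of 0.7 and zero
#' cross-loadings.
#'
#' @return a 58 x 3 loading matrix
#' @export
default_survey_loadings <- function() {
  blocks <- c(20, 20, 18)
  L <- matrix(0, sum(blocks), 3)
  start <- 1
  for (j in seq_along(blocks)) {
    L[start:(start + blocks[j] - 1), j] <- 0.7
    start <- start + blocks[j]
  }
  rownames(L) <- sprintf("item%02d", seq_len(sum(blocks)))
  L
}

#' Generate a Likert survey matrix from the latent factor model
#'
#' Latent factors are multivariate normal with correlation `factor_corr`;
#' continuous item scores are `L f + sqrt(uniqueness) * e`; responses are
#' discretized into `likert_levels` categories by equal-probability normal
#' thresholds.
#'
#' @param params a [survey_gen_params()]
#' @return integer matrix (respondents x items, values `1..likert_levels`)
#'   with attributes `"factors"` (the latent scores), `"continuous"`, and
#'   `"params"`
#' @export
generate_surveys <- function(params = survey_gen_params()) {
  stopifnot(inherits(params, "survey_gen_params"))
  set.seed(params$seed)
  n <- params$n_respondents
  f <- MASS::mvrnorm(n, mu = rep(0, ncol(params$loadings)),
                     Sigma = params$factor_corr)
  cont <- f %*% t(params$loadings) +
    matrix(rnorm(n * nrow(params$loadings)), n) %*%
    diag(sqrt(params$uniqueness), nrow(params$loadings))
  cuts <- qnorm(seq_len(params$likert_levels - 1) / params$likert_levels)
  lik <- matrix(0L, n, ncol(cont))
  for (j in seq_len(ncol(cont))) {
    lik[, j] <- as.integer(findInterval(cont[, j], cuts) + 1L)
    if (params$reverse_coded[j]) {
      lik[, j] <- params$likert_levels + 1L - lik[, j]
    }
  }
  colnames(lik) <- rownames(params$loadings)
  attr(lik, "factors") <- f
  attr(lik, "continuous") <- cont
  attr(lik, "params") <- params
  lik
}

#' Recode reverse-keyed survey items
#'
#' Flips reverse-coded items back onto the common scale direction
#' (`response <- levels + 1 - response`) so all items align with their
#' latent factors before adequacy checks and factor extraction.
#'
#' @param m Likert survey matrix (respondents x items)
#' @param reverse_coded logical per item; defaults to the flag carried by
#'   the generator's parameter sidecar when present
#' @param likert_levels number of response levels
#' @return the recoded matrix
#' @export
recode_reversed <- function(m, reverse_coded = NULL, likert_levels = 4) {
  if (is.null(reverse_coded)) {
    p <- attr(m, "params")
    if (is.null(p)) stop("supply reverse_coded or a matrix with parameters")
    reverse_coded <- p$reverse_coded
    likert_levels <- p$likert_levels
  }
  stopifnot(length(reverse_coded) == ncol(m))
  out <- m
  for (j in which(reverse_coded)) {
    out[, j] <- likert_levels + 1L - out[, j]
  }
  out
}
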