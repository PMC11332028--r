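survey_cor <- function(m, ridge = 1e-8) {
  R <- cor(m)
  if (rcond(R) < 1e-12) {
    warning("near-singular correlation matrix; adding ridge")
    R <- R + diag(ridge, ncol(R))
    R <- cov2cor(R)
  }
  R
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Compares zero-order correlations with anti-image partial correlations:
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal entries, where
#' `q` are the partial correlations given all other items.
#'
#' @param m numeric matrix or data.frame of item responses, or a correlation
#'   matrix (square, unit diagonal)
#' @return list with `overall` and per-item `msa`
#' @export
kmo <- function(m) {
  R <- if (is.matrix(m) && nrow(m) == ncol(m) &&
           isTRUE(all.equal(diag(m), rep(1, ncol(m))))) m else survey_cor(m)
  Ri <- tryCatch(solve(R), error = function(e)
    stop("singular correlation matrix: ", conditionMessage(e)))
  d <- 1 / sqrt(diag(Ri))
  Q <- -Ri * outer(d, d) # anti-image partial correlations
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  overall <- sum(R0^2) / (sum(R0^2) + sum(Q^2))
  msa <- colSums(R0^2) / (colSums(R0^2) + colSums(Q^2))
  names(msa) <- colnames(R)
  list(overall = overall, msa = msa)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the item correlation matrix is an identity matrix:
#' `chi^2 = -(n - 1 - (2p + 5)/6) * ln|R|` with `p(p-1)/2` degrees of
#' freedom.
#'
#' @param m item response matrix (rows are respondents)
#' @param n number of respondents (required when `m` is a correlation matrix)
#' @return list with `chisq`, `df`, `p_value`
#' @export
bartlett_sphericity <- function(m, n = NULL) {
  if (is.matrix(m) && nrow(m) == ncol(m) &&
      isTRUE(all.equal(diag(m), rep(1, ncol(m))))) {
    R <- m
    if (is.null(n)) stop("supply n when passing a correlation matrix")
  } else {
    R <- survey_cor(m)
    n <- nrow(m)
  }
  p <- ncol(R)
  if (n <= p) stop("need more respondents than items")
  detR <- det(R)
  if (detR <= 0) stop("non-positive correlation determinant")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df, p_value = pchisq(chisq, df, lower.tail = FALSE))
}

#' Cattell-Nelson-Gorsuch factor-number selection
#'
#' Scree-based selection by slope differences: for every position `i` a
#' straight line is fit to the three eigenvalues starting there; the CNG
#' index compares the slope of the window starting at `i` with the window
#' starting at `i + 3`, and the retained factor count is `argmax + 2`
#' (the elbow sits between the two windows of the winning comparison).
#'
#' @param eigenvalues eigenvalues in descending order (>= 6 values; the
#'   comparison needs two non-overlapping 3-point fits)
#' @return list with `k`, the per-position slope differences `diffs`, and a
#'   `flat` flag raised when no elbow stands out
#' @export
cng_nfactors <- function(eigenvalues) {
  p <- length(eigenvalues)
  if (p < 6) stop("CNG needs at least 6 eigenvalues")
  if (is.unsorted(rev(eigenvalues))) {
    eigenvalues <- sort(eigenvalues, decreasing = TRUE)
  }
  slope3 <- function(i) {
    y <- eigenvalues[i:(i + 2)]
    # least-squares slope at x = 1,2,3
    (y[3] - y[1]) / 2
  }
  slopes <- vapply(seq_len(p - 2), slope3, numeric(1))
  idx <- seq_len(p - 5)
  diffs <- vapply(idx, function(i) slopes[i + 3] - slopes[i], numeric(1))
  k <- which.max(diffs) + 2L
  flat <- diff(range(diffs)) < 1e-10
  if (flat) warning("flat scree profile: no distinguished elbow")
  list(k = k, diffs = diffs, flat = flat)
}

#' Maximum-likelihood factor analysis with promax rotation
#'
#' Extracts `k` factors from the Pearson correlation matrix by maximum
#' likelihood, applies a varimax pre-rotation followed by an oblique promax
#' rotation (power 4), and returns the pattern loadings, factor correlations,
#' uniquenesses, and eigenvalues of the correlation matrix. Heywood-prone
#' solutions are kept away from zero uniqueness by the standard 0.005 lower
#' bound.
#'
#' @param m item response matrix (respondents x items)
#' @param k number of factors (`k < p`)
#' @param promax_power promax exponent (default 4)
#' @return object of class `factor_solution` with `loadings`, `factor_corr`,
#'   `uniqueness`, `k`, `eigenvalues`, `heywood` flag
#' @export
fit_factor_model <- function(m, k, promax_power = 4) {
  stopifnot(k >= 1, k < ncol(m))
  R <- survey_cor(m)
  eigenvalues <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  fa <- factanal(covmat = R, factors = k, n.obs = nrow(m),
                 rotation = "none", lower = 0.005)
  L <- unclass(fa$loadings)
  if (k > 1) {
    vm <- varimax(L)
    pm <- promax(vm$loadings, m = promax_power)
    L_rot <- unclass(pm$loadings)
    rot <- vm$rotmat %*% pm$rotmat
    phi <- solve(crossprod(rot))
    phi <- cov2cor(phi)
  } else {
    L_rot <- L
    phi <- matrix(1, 1, 1)
  }
  # orient each factor so its dominant loadings are positive
  signs <- sign(colSums(L_rot^3))
  signs[signs == 0] <- 1
  L_rot <- sweep(L_rot, 2, signs, "*")
  phi <- diag(signs, k) %*% phi %*% diag(signs, k)
  dimnames(L_rot) <- list(colnames(m), paste0("f", seq_len(k)))
  dimnames(phi) <- list(paste0("f", seq_len(k)), paste0("f", seq_len(k)))
  heywood <- any(fa$uniquenesses <= 0.005 + 1e-12)
  if (heywood) warning("Heywood case: uniqueness at the 0.005 bound")
  structure(list(loadings = L_rot, factor_corr = phi,
                 uniqueness = fa$uniquenesses, k = k,
                 eigenvalues = eigenvalues, correlation = R,
                 heywood = heywood, n_obs = nrow(m)),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("ML factor solution: %d factors, %d items\n",
              x$k, nrow(x$loadings)))
  cat("Factor correlations:\n")
  print(round(x$factor_corr, 2))
  invisible(x)
}

mat_pow <- function(S, p) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% diag(vals^p, length(vals)) %*% t(e$vectors)
}

#' Correlation-preserving (ten Berge) factor scores
#'
#' Computes factor scores whose sample correlations reproduce the factor
#' correlation matrix of the solution.
#'
#' @param sol a [fit_factor_model()] solution
#' @param m the item response matrix to score (items must match the solution)
#' @return respondents x k score matrix
#' @export
score_tenberge <- function(sol, m) {
  stopifnot(inherits(sol, "factor_solution"),
            ncol(m) == nrow(sol$loadings))
  R <- sol$correlation
  L <- sol$loadings %*% mat_pow(sol$factor_corr, 0.5)
  Rin <- mat_pow(R, -0.5)
  inner <- t(L) %*% solve(R, L)
  C <- Rin %*% L %*% mat_pow(inner, -0.5)
  W <- Rin %*% C %*% mat_pow(sol$factor_corr, 0.5)
  Z <- scale(m)
  scores <- Z %*% W
  colnames(scores) <- colnames(sol$loadings)
  scores
}

#' Tucker congruence alignment of a recovered solution to a target
#'
#' Searches sign flips and column permutations (brute force, k <= 4) for the
#' alignment maximizing mean Tucker congruence with the target loadings.
#'
#' @param loadings recovered loading matrix
#' @param target generating loading matrix of the same shape
#' @return list with the aligned `loadings`, the `permutation`, `signs`, and
#'   per-factor `congruence`
#' @export
align_loadings <- function(loadings, target) {
  k <- ncol(loadings)
  stopifnot(k == ncol(target), k <= 4)
  tucker <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  perms <- if (k == 1) matrix(1) else {
    pl <- list()
    gen <- function(v, acc) {
      if (length(v) == 0) pl[[length(pl) + 1]] <<- acc
      else for (i in seq_along(v)) gen(v[-i], c(acc, v[i]))
    }
    gen(seq_len(k), integer(0))
    do.call(rbind, pl)
  }
  best <- NULL
  for (r in seq_len(nrow(perms))) {
    perm <- perms[r, ]
    cong <- vapply(seq_len(k), function(j)
      tucker(loadings[, perm[j]], target[, j]), numeric(1))
    signs <- ifelse(cong < 0, -1, 1)
    score <- mean(abs(cong))
    if (is.null(best) || score > best$score) {
      best <- list(score = score, permutation = perm, signs = signs,
                   congruence = abs(cong))
    }
  }
  aligned <- sweep(loadings[, best$permutation, drop = FALSE], 2,
                   best$signs, "*")
  list(loadings = aligned, permutation = best$permutation,
       signs = best$signs, congruence = best$congruence)
}
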