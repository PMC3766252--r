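#' Loglinear coefficients of the latent class linkage model
#'
#' Container for the cell-mean parameterization
#' `log m(Y, M) = lam0 + lamM * M + sum_k lam_k y_k + sum_k lamM_k M y_k`
#' plus, for each pairwise interaction in the spec,
#' `lam_jl y_j y_l + lamM_jl M y_j y_l`. Structures with a constrained
#' coefficient store the implied value (e.g. `lam_jl = 0` for `match_only`).
#'
#' @param lam0 Intercept.
#' @param lamM Match-class main effect.
#' @param lam_k Numeric vector of `K` field main effects.
#' @param lamM_k Numeric vector of `K` field-by-class effects.
#' @param lam_jl,lamM_jl Numeric vectors, one entry per interaction term in
#'   the spec (0 where the structure fixes the coefficient).
#' @return An object of class `lc_lambda`.
#' @export
lambda_params <- function(lam0 = 0, lamM = 0, lam_k, lamM_k,
                          lam_jl = numeric(0), lamM_jl = numeric(0)) {
  x <- list(lam0 = as.numeric(lam0), lamM = as.numeric(lamM),
            lam_k = as.numeric(lam_k), lamM_k = as.numeric(lamM_k),
            lam_jl = as.numeric(lam_jl), lamM_jl = as.numeric(lamM_jl))
  if (length(x$lam_k) != length(x$lamM_k))
    stopf("lam_k and lamM_k must have equal length")
  if (length(x$lam_jl) != length(x$lamM_jl))
    stopf("lam_jl and lamM_jl must have equal length")
  structure(x, class = "lc_lambda")
}

check_lambda <- function(lambda, spec) {
  if (!inherits(lambda, "lc_lambda")) stopf("lambda must be a lambda_params object")
  vals <- unlist(lambda[c("lam0", "lamM", "lam_k", "lamM_k", "lam_jl", "lamM_jl")])
  if (any(!is.finite(vals))) stopf("invalid parameter: non-finite lambda coefficient")
  if (length(lambda$lam_k) != spec$K)
    stopf("lambda has %d field effects but spec has K=%d", length(lambda$lam_k), spec$K)
  if (length(lambda$lam_jl) != length(spec$interactions))
    stopf("lambda has %d interaction coefficients but spec has %d terms",
          length(lambda$lam_jl), length(spec$interactions))
  invisible(lambda)
}

#' Expected cell means of the loglinear model
#'
#' Evaluates `m(Y_d, M) = exp(linear predictor)` over all `2^K` agreement
#' patterns and both latent classes.
#'
#' @param lambda A [lambda_params()] object dimensioned for `spec`.
#' @param spec A [model_spec()].
#' @return A `2^K` by 2 matrix with columns `nonmatch` (M = 0) and
#'   `match` (M = 1); strictly positive.
#' @export
expected_cell_means <- function(lambda, spec) {
  check_lambda(lambda, spec)
  st <- spec_stats(spec)
  eta0 <- lambda$lam0 + drop(st$Y %*% lambda$lam_k)
  eta1 <- eta0 + lambda$lamM + drop(st$Y %*% lambda$lamM_k)
  if (length(lambda$lam_jl)) {
    eta0 <- eta0 + drop(st$YY %*% lambda$lam_jl)
    eta1 <- eta1 + drop(st$YY %*% (lambda$lam_jl + lambda$lamM_jl))
  }
  cells <- cbind(nonmatch = exp(eta0), match = exp(eta1))
  rownames(cells) <- apply(st$Y, 1L, paste, collapse = "")
  cells
}

#' Marginal agreement-pattern probabilities
#'
#' `P(Y_d)` is the two-class cell-mean sum normalized over all patterns; it
#' is invariant to adding a constant to the loglinear intercept.
#'
#' @inheritParams expected_cell_means
#' @return Numeric vector of `2^K` probabilities summing to 1.
#' @export
pattern_probabilities <- function(lambda, spec) {
  cells <- expected_cell_means(lambda, spec)
  tot <- rowSums(cells)
  unname(tot / sum(tot))
}

#' Interpretable parameters of a fitted loglinear model
#'
#' Maps loglinear coefficients to the classical linkage parameters: the
#' match prevalence `pi` (cell-sum ratio) and per-field m-/u-probabilities,
#' defined as class-conditional marginal agreement probabilities. For a
#' field involved in no interaction these reduce to the logistic identities
#' `u_k = plogis(lam_k)`, `m_k = plogis(lam_k + lamM_k)`.
#'
#' @inheritParams expected_cell_means
#' @return An object of class `lc_classical`: list with `pi`, `m`, `u`.
#' @export
lambda_to_classical <- function(lambda, spec) {
  cells <- expected_cell_means(lambda, spec)
  st <- spec_stats(spec)
  s1 <- sum(cells[, "match"]); s0 <- sum(cells[, "nonmatch"])
  classical_params(pi = s1 / (s1 + s0),
                   m = as.numeric(crossprod(st$Y, cells[, "match"])) / s1,
                   u = as.numeric(crossprod(st$Y, cells[, "nonmatch"])) / s0)
}

#' Classical Fellegi-Sunter parameters
#'
#' @param pi Match prevalence in (0, 1).
#' @param m,u Length-`K` vectors of agreement probabilities given match /
#'   non-match, all strictly in (0, 1).
#' @return An object of class `lc_classical`.
#' @export
classical_params <- function(pi, m, u) {
  if (length(m) != length(u)) stopf("m and u must have equal length")
  if (any(!is.finite(c(pi, m, u))) || pi <= 0 || pi >= 1 ||
      any(m <= 0) || any(m >= 1) || any(u <= 0) || any(u >= 1))
    stopf("classical parameters must lie strictly in (0, 1)")
  structure(list(pi = as.numeric(pi), m = as.numeric(m), u = as.numeric(u)),
            class = "lc_classical")
}

#' Loglinear coefficients of a conditional-independence model
#'
#' Inverse of [lambda_to_classical()] for the interaction-free model:
#' `lam_k = qlogis(u_k)`, `lamM_k = qlogis(m_k) - qlogis(u_k)`, with the
#' intercepts chosen so the cell means sum to `total`.
#'
#' @param classical A [classical_params()] object.
#' @param K Number of fields (defaults to `length(classical$m)`).
#' @param total Target sum of all cell means (1 gives probabilities; use the
#'   pair count `N` to match observed-scale expected counts).
#' @return A [lambda_params()] object for the CI spec with `K` fields.
#' @export
classical_to_lambda <- function(classical, K = length(classical$m), total = 1) {
  if (!inherits(classical, "lc_classical")) classical <- do.call(classical_params, classical)
  if (length(classical$m) != K) stopf("classical parameters have length %d, not K=%d",
                                      length(classical$m), K)
  lam_k <- stats::qlogis(classical$u)
  lamM_k <- stats::qlogis(classical$m) - lam_k
  # per-class normalizers of exp(sum lam y): prod(1 + exp(lam))
  lam0 <- log((1 - classical$pi) * total) - sum(log1p(exp(lam_k)))
  lamM <- log(classical$pi * total) - sum(log1p(exp(lam_k + lamM_k))) - lam0
  lambda_params(lam0 = lam0, lamM = lamM, lam_k = lam_k, lamM_k = lamM_k)
}

# lambda representation of a theta vector, normalized so cells sum to total
lambda_from_theta <- function(theta, spec, total = 1) {
  p <- theta_unpack(theta, spec)
  st <- spec_stats(spec)
  eta0 <- drop(st$Y %*% p$a0)
  eta1 <- drop(st$Y %*% p$a1)
  if (length(p$g0)) {
    eta0 <- eta0 + drop(st$YY %*% p$g0)
    eta1 <- eta1 + drop(st$YY %*% p$g1)
  }
  lam0 <- log((1 - p$pi) * total) - logsumexp(eta0)
  lamM <- log(p$pi * total) - logsumexp(eta1) - lam0
  lambda_params(lam0 = lam0, lamM = lamM,
                lam_k = p$a0, lamM_k = p$a1 - p$a0,
                lam_jl = p$g0, lamM_jl = p$g1 - p$g0)
}

# minimal free parameterization of a lambda object
theta_from_lambda <- function(lambda, spec) {
  check_lambda(lambda, spec)
  cells <- expected_cell_means(lambda, spec)
  pi <- sum(cells[, "match"]) / sum(cells)
  g0 <- lambda$lam_jl
  g1 <- lambda$lam_jl + lambda$lamM_jl
  c(stats::qlogis(pi), lambda$lam_k, lambda$lam_k + lambda$lamM_k,
    gammas_to_theta_block(g0, g1, spec))
}

#' Multinomial log-likelihood of a pattern table
#'
#' `l = sum_d f_d log P(Y_d)`; unchanged when a constant is added to the
#' loglinear intercept.
#'
#' @inheritParams expected_cell_means
#' @param table An [agreement_table()] with `table$K == spec$K`.
#' @return Scalar log-likelihood (0 for an empty table).
#' @export
log_likelihood <- function(lambda, spec, table) {
  stopifnot(inherits(table, "lc_agreement_table"))
  if (table$K != spec$K) stopf("table has K=%d but spec has K=%d", table$K, spec$K)
  if (table$N == 0) return(0)
  P <- pattern_probabilities(lambda, spec)
  obs <- table$counts > 0
  sum(table$counts[obs] * log(P[obs]))
}

#' Deviance of a fitted model against a pattern table
#'
#' Likelihood-ratio statistic against the saturated multinomial over the
#' observed agreement patterns:
#' `G^2 = 2 sum_{d: f_d > 0} f_d log(f_d / (N P(Y_d)))`. Zero-count cells
#' contribute nothing; the statistic is 0 when fitted probabilities equal
#' the empirical frequencies.
#'
#' @param fit An `lc_fit` object (or anything with `lambda` and `spec`).
#' @param table An [agreement_table()].
#' @return Scalar deviance.
#' @export
g2_deviance <- function(fit, table) {
  P <- pattern_probabilities(fit$lambda, fit$spec)
  f <- table$counts
  obs <- f > 0
  2 * sum(f[obs] * log(f[obs] / (table$N * P[obs])))
}

#' Bayesian Information Criterion of a fitted model
#'
#' `BIC = -2 loglik + p log N` with `p` the number of free parameters and
#' `N` the number of record pairs (the units of the multinomial sample).
#'
#' @inheritParams g2_deviance
#' @return Scalar BIC.
#' @export
model_bic <- function(fit, table) {
  ll <- log_likelihood(fit$lambda, fit$spec, table)
  -2 * ll + n_free_params(fit$spec) * log(table$N)
}

#' Match score of an agreement pattern
#'
#' Base-2 log likelihood ratio of a pattern under the match versus nonmatch
#' class: `log2 P(Y_d | M = 1) / P(Y_d | M = 0)`. Under conditional
#' independence this equals the familiar sum of per-field Fellegi-Sunter
#' agreement/disagreement weights.
#'
#' @inheritParams expected_cell_means
#' @param pattern A 0/1 vector of length `K`, or a matrix with `K` columns
#'   (one score per row). Omit to score all `2^K` patterns in table order.
#' @return Numeric vector of scores.
#' @export
match_score <- function(lambda, spec, pattern = NULL) {
  cells <- expected_cell_means(lambda, spec)
  lq1 <- log(cells[, "match"]) - log(sum(cells[, "match"]))
  lq0 <- log(cells[, "nonmatch"]) - log(sum(cells[, "nonmatch"]))
  score <- (lq1 - lq0) / log(2)
  if (is.null(pattern)) return(unname(score))
  if (is.null(dim(pattern))) pattern <- matrix(pattern, nrow = 1L)
  if (ncol(pattern) != spec$K) stopf("pattern must have length K=%d", spec$K)
  unname(score[pattern_index(pattern, spec$K)])
}
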