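#' Pairwise interaction term of a loglinear latent class model
#'
#' Describes a within-class dependence between two comparison fields. The
#' four structures differ in which latent class carries a free loglinear
#' interaction coefficient: the match class only, the nonmatch class only,
#' both classes with distinct coefficients, or both classes with a single
#' shared coefficient.
#'
#' @param j,l Field indices with `1 <= j < l <= K`.
#' @param structure One of `"match_only"`, `"nonmatch_only"`,
#'   `"both_distinct"`, `"both_shared"`.
#' @return An object of class `lc_interaction`.
#' @export
interaction_term <- function(j, l,
                             structure = c("match_only", "nonmatch_only",
                                           "both_distinct", "both_shared")) {
  structure <- match.arg(structure)
  j <- as.integer(j); l <- as.integer(l)
  if (length(j) != 1L || length(l) != 1L || is.na(j) || is.na(l) || j < 1L || l <= j)
    stopf("interaction term requires field indices 1 <= j < l (got j=%s, l=%s)", j, l)
  structure(list(j = j, l = l, structure = structure), class = "lc_interaction")
}

#' Specification of a loglinear latent class linkage model
#'
#' A model is determined by the number of binary comparison fields `K` and a
#' (possibly empty) list of pairwise within-class interaction terms. An empty
#' interaction list is the classical Fellegi-Sunter conditional-independence
#' model.
#'
#' @param K Number of comparison fields.
#' @param interactions List of [interaction_term()] objects.
#' @param field_names Optional character vector of `K` field labels.
#' @return An object of class `lc_model_spec`.
#' @export
model_spec <- function(K, interactions = list(), field_names = NULL) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L) stopf("K must be a positive integer")
  if (inherits(interactions, "lc_interaction")) interactions <- list(interactions)
  for (tr in interactions) {
    if (!inherits(tr, "lc_interaction")) stopf("interactions must be interaction_term objects")
    if (tr$l > K) stopf("interaction (%d,%d) exceeds K=%d", tr$j, tr$l, K)
  }
  keys <- vapply(interactions, function(tr) paste(tr$j, tr$l), "")
  if (anyDuplicated(keys)) stopf("duplicate interaction pair in model spec")
  if (is.null(field_names)) field_names <- paste0("field", seq_len(K))
  if (length(field_names) != K || anyDuplicated(field_names))
    stopf("field_names must be %d unique labels", K)
  structure(list(K = K, interactions = interactions,
                 field_names = as.character(field_names)),
            class = "lc_model_spec")
}

#' @export
print.lc_model_spec <- function(x, ...) {
  cat(sprintf("Loglinear latent class model spec: K = %d fields, %d free parameters\n",
              x$K, n_free_params(x)))
  if (length(x$interactions) == 0L) {
    cat("  conditional independence (no interactions)\n")
  } else {
    for (tr in x$interactions)
      cat(sprintf("  interaction %s:%s [%s]\n",
                  x$field_names[tr$j], x$field_names[tr$l], tr$structure))
  }
  invisible(x)
}

# number of free coefficients an interaction structure contributes
n_params_structure <- function(structure) {
  switch(structure,
         match_only = 1L, nonmatch_only = 1L,
         both_shared = 1L, both_distinct = 2L,
         stopf("unknown interaction structure '%s'", structure))
}

#' Number of free parameters of a model specification
#'
#' The conditional-independence model has `2K + 1` free parameters (the match
#' prevalence plus one m- and one u-probability per field). Each interaction
#' adds one coefficient (`match_only`, `nonmatch_only`, `both_shared`) or two
#' (`both_distinct`).
#'
#' @param spec An [model_spec()] object.
#' @return Integer parameter count.
#' @examples
#' n_free_params(model_spec(7)) # 15
#' @export
n_free_params <- function(spec) {
  stopifnot(inherits(spec, "lc_model_spec"))
  2L * spec$K + 1L +
    sum(vapply(spec$interactions, function(tr) n_params_structure(tr$structure), 0L))
}

#' Enumerate all binary agreement patterns for K fields
#'
#' Pattern index `d` (1-based row) encodes the bits of `(y_1, ..., y_K)` with
#' field 1 as the most significant bit, so row 1 is the all-zero pattern and
#' row `2^K` is all-agree. This fixed order makes tables comparable across
#' runs.
#'
#' @param K Number of fields.
#' @return A `2^K` by `K` integer matrix of 0/1 values.
#' @export
pattern_matrix <- function(K) {
  K <- as.integer(K)
  if (K < 1L || K > 24L) stopf("K must be between 1 and 24")
  d <- 0:(2L^K - 1L)
  Y <- matrix(0L, nrow = length(d), ncol = K)
  for (k in seq_len(K)) Y[, k] <- bitwAnd(d, bitwShiftL(1L, K - k)) > 0L
  storage.mode(Y) <- "integer"
  Y
}

# pattern row index (1-based) for a 0/1 matrix of agreement vectors
pattern_index <- function(Y, K) {
  pow <- 2L^((K - 1L):0L)
  as.integer(Y %*% pow) + 1L
}

# sufficient statistics reused across likelihood evaluations:
# Y (D x K main effects) and YY (D x n_terms interaction products)
spec_stats <- function(spec) {
  Y <- pattern_matrix(spec$K)
  nT <- length(spec$interactions)
  YY <- matrix(0, nrow = nrow(Y), ncol = nT)
  for (t in seq_len(nT)) {
    tr <- spec$interactions[[t]]
    YY[, t] <- Y[, tr$j] * Y[, tr$l]
  }
  list(Y = Y, YY = YY, D = nrow(Y))
}

# ---- free ("theta") parameterization --------------------------------------
#
# theta = (logit pi, a0[1..K], a1[1..K], interaction coefficients in spec
# order). a0/a1 are the within-class loglinear main effects of the nonmatch
# and match class; for a field in no interaction a0 = logit u, a1 = logit m.
# This minimal set removes the overall-scale flat direction of the cell-mean
# lambdas, so quasi-Newton optimization is well posed.

theta_length <- function(spec) n_free_params(spec)

theta_names <- function(spec) {
  fn <- spec$field_names
  nm <- c("logit_pi", paste0("a0_", fn), paste0("a1_", fn))
  for (tr in spec$interactions) {
    lab <- paste0(fn[tr$j], ":", fn[tr$l])
    nm <- c(nm, switch(tr$structure,
                       match_only    = paste0("g1_", lab),
                       nonmatch_only = paste0("g0_", lab),
                       both_shared   = paste0("g_", lab),
                       both_distinct = paste0(c("g0_", "g1_"), lab)))
  }
  nm
}

# expand theta's interaction block into per-class coefficient vectors
theta_gammas <- function(theta, spec) {
  nT <- length(spec$interactions)
  g0 <- numeric(nT); g1 <- numeric(nT)
  pos <- 2L * spec$K + 2L
  for (t in seq_len(nT)) {
    st <- spec$interactions[[t]]$structure
    if (st == "match_only") {
      g1[t] <- theta[pos]; pos <- pos + 1L
    } else if (st == "nonmatch_only") {
      g0[t] <- theta[pos]; pos <- pos + 1L
    } else if (st == "both_shared") {
      g0[t] <- g1[t] <- theta[pos]; pos <- pos + 1L
    } else {
      g0[t] <- theta[pos]; g1[t] <- theta[pos + 1L]; pos <- pos + 2L
    }
  }
  list(g0 = g0, g1 = g1)
}

# pack per-class gamma vectors back into theta's interaction block
gammas_to_theta_block <- function(g0, g1, spec) {
  out <- numeric(0)
  for (t in seq_along(spec$interactions)) {
    st <- spec$interactions[[t]]$structure
    out <- c(out, switch(st,
                         match_only    = g1[t],
                         nonmatch_only = g0[t],
                         both_shared   = g0[t],
                         both_distinct = c(g0[t], g1[t])))
  }
  out
}

theta_unpack <- function(theta, spec) {
  K <- spec$K
  if (length(theta) != theta_length(spec))
    stopf("theta has length %d but spec needs %d", length(theta), theta_length(spec))
  g <- theta_gammas(theta, spec)
  list(pi = stats::plogis(theta[1L]),
       a0 = theta[2:(K + 1L)], a1 = theta[(K + 2L):(2L * K + 1L)],
       g0 = g$g0, g1 = g$g1)
}

# normalized within-class pattern distributions q0, q1 and mixture P
theta_distributions <- function(theta, spec, st = spec_stats(spec)) {
  p <- theta_unpack(theta, spec)
  eta0 <- drop(st$Y %*% p$a0)
  eta1 <- drop(st$Y %*% p$a1)
  if (length(p$g0)) {
    eta0 <- eta0 + drop(st$YY %*% p$g0)
    eta1 <- eta1 + drop(st$YY %*% p$g1)
  }
  q0 <- exp(eta0 - logsumexp(eta0))
  q1 <- exp(eta1 - logsumexp(eta1))
  list(pi = p$pi, q0 = q0, q1 = q1, P = p$pi * q1 + (1 - p$pi) * q0)
}

# class-conditional marginal agreement probabilities and prevalence
classical_from_theta <- function(theta, spec, st = spec_stats(spec)) {
  d <- theta_distributions(theta, spec, st)
  list(pi = d$pi,
       m = as.numeric(crossprod(st$Y, d$q1)),
       u = as.numeric(crossprod(st$Y, d$q0)))
}
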