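# EM fitting: an independent estimation route used to cross-check the
# quasi-Newton ML fit. The E-step computes posterior match probabilities per
# pattern; the M-step refits the class prevalence (closed form) and the
# within-class loglinear distributions (closed-form weighted proportions
# under conditional independence, inner Newton iterations when a class
# carries interaction terms).

# per-class design matrices over the class-parameter vector
# beta = (a0[1..K], a1[1..K], interaction block in theta order)
beta_designs <- function(spec, st) {
  K <- spec$K
  D <- st$D
  zero <- matrix(0, D, K)
  X0 <- cbind(st$Y, zero)
  X1 <- cbind(zero, st$Y)
  for (t in seq_along(spec$interactions)) {
    yy <- st$YY[, t]
    z <- numeric(D)
    stt <- spec$interactions[[t]]$structure
    if (stt == "match_only") { X0 <- cbind(X0, z); X1 <- cbind(X1, yy) }
    else if (stt == "nonmatch_only") { X0 <- cbind(X0, yy); X1 <- cbind(X1, z) }
    else if (stt == "both_shared") { X0 <- cbind(X0, yy); X1 <- cbind(X1, yy) }
    else { X0 <- cbind(X0, yy, z); X1 <- cbind(X1, z, yy) }
  }
  list(X0 = X0, X1 = X1)
}

# weighted multinomial loglinear objective for both classes
mstep_objective <- function(beta, dg, c0, c1, n0, n1) {
  eta0 <- drop(dg$X0 %*% beta)
  eta1 <- drop(dg$X1 %*% beta)
  sum(c0 * eta0) - n0 * logsumexp(eta0) + sum(c1 * eta1) - n1 * logsumexp(eta1)
}

# damped Newton ascent of the M-step objective; monotone by step halving
mstep_newton <- function(beta, dg, c0, c1, n0, n1, max_inner = 25L) {
  obj <- mstep_objective(beta, dg, c0, c1, n0, n1)
  for (it in seq_len(max_inner)) {
    q0 <- exp(drop(dg$X0 %*% beta) - logsumexp(drop(dg$X0 %*% beta)))
    q1 <- exp(drop(dg$X1 %*% beta) - logsumexp(drop(dg$X1 %*% beta)))
    g <- drop(crossprod(dg$X0, c0 - n0 * q0)) + drop(crossprod(dg$X1, c1 - n1 * q1))
    if (max(abs(g)) < 1e-9) break
    xq0 <- drop(crossprod(dg$X0, q0)); xq1 <- drop(crossprod(dg$X1, q1))
    H <- n0 * (crossprod(dg$X0, q0 * dg$X0) - tcrossprod(xq0)) +
         n1 * (crossprod(dg$X1, q1 * dg$X1) - tcrossprod(xq1))
    step <- tryCatch(solve(H + 1e-10 * diag(nrow(H)), g), error = function(e) g / max(abs(g)))
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      val <- mstep_objective(cand, dg, c0, c1, n0, n1)
      if (is.finite(val) && val >= obj - 1e-12) { beta <- cand; obj <- val; break }
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    if (alpha < 1e-8) break
  }
  beta
}

em_one_start <- function(theta, spec, st, f, options) {
  K <- spec$K
  N <- sum(f)
  has_int <- length(spec$interactions) > 0L
  dg <- if (has_int) beta_designs(spec, st) else NULL
  ll_old <- loglik_grad(theta, spec, st, f)$ll
  trace <- ll_old
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(options$max_iter)) {
    d <- theta_distributions(theta, spec, st)
    w <- d$pi * d$q1 / d$P                      # E-step posterior per pattern
    c1 <- f * w; c0 <- f - c1
    n1 <- sum(c1); n0 <- N - n1
    pi_new <- clamp(n1 / N, 1e-12, 1 - 1e-12)
    if (has_int) {
      beta <- mstep_newton(theta[-1L], dg, c0, c1, n0, n1)
      theta <- c(stats::qlogis(pi_new), beta)
    } else {
      p0 <- clamp(drop(crossprod(st$Y, c0)) / n0, 1e-12, 1 - 1e-12)
      p1 <- clamp(drop(crossprod(st$Y, c1)) / n1, 1e-12, 1 - 1e-12)
      theta <- c(stats::qlogis(pi_new), stats::qlogis(p0), stats::qlogis(p1))
    }
    ll <- loglik_grad(theta, spec, st, f)$ll
    trace <- c(trace, ll)
    if (ll < ll_old - 1e-7 * (abs(ll_old) + 1))
      warning("EM log-likelihood decreased; numerical M-step issue")
    if (abs(ll - ll_old) < options$tol * (abs(ll_old) + 1e-300)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(theta = theta, ll = ll_old, converged = converged, n_iter = iter, trace = trace)
}

#' Maximum-likelihood fit by the EM algorithm
#'
#' Independent implementation of the same estimator as [fit_ml()], used as a
#' cross-checking oracle. The observed-data log-likelihood is non-decreasing
#' across iterations; the M-step has closed-form weighted-proportion updates
#' under conditional independence and uses inner Newton iterations when a
#' latent class carries interaction terms.
#'
#' @inheritParams fit_ml
#' @return An `lc_fit` object (with `method = "em"` and an `ll_trace`
#'   attribute holding the per-iteration log-likelihood of the best start).
#' @export
fit_em <- function(table, spec = model_spec(table$K, field_names = table$field_names),
                   options = fit_options()) {
  check_fit_inputs(table, spec)
  st <- spec_stats(spec)
  f <- table$counts
  base <- switch(options$init,
                 user = options$init_theta,
                 heuristic_theta(table, spec))
  starts <- with_seed(options$seed, {
    s <- list(base)
    if (options$init == "random") s <- list()
    while (length(s) < options$n_starts)
      s[[length(s) + 1L]] <- base + stats::rnorm(length(base), sd = options$jitter_sd)
    s
  })
  runs <- lapply(starts, function(th)
    tryCatch(em_one_start(th, spec, st, f, options),
             error = function(e) list(ll = -Inf)))
  lls <- vapply(runs, function(r) r$ll, 0)
  if (!any(is.finite(lls))) stopf("all EM starts failed")
  r <- runs[[which.max(lls)]]
  log <- data.frame(start = seq_along(runs), loglik = lls,
                    converged = vapply(runs, function(x) isTRUE(x$converged), TRUE))
  fit <- build_fit(r$theta, spec, table, st, r$ll, r$converged, r$n_iter, log,
                   method = "em", compute_se = options$compute_se)
  attr(fit, "ll_trace") <- r$trace
  fit
}
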