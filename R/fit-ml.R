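#' Fitting options
#'
#' @param max_iter Maximum optimizer (or EM) iterations per start.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param n_starts Number of starts (1 heuristic/user + jittered restarts).
#' @param seed Integer seed controlling the jittered restarts.
#' @param init `"heuristic"` (agreement-margin based), `"user"` (supply
#'   `init_theta`), or `"random"`.
#' @param init_theta Free-parameter vector used when `init = "user"`.
#' @param grad_tol Gradient max-norm required to declare convergence.
#' @param jitter_sd Standard deviation of the Gaussian jitter on restarts.
#' @param compute_se Compute delta-method standard errors after fitting.
#' @return An object of class `lc_fit_options`.
#' @export
fit_options <- function(max_iter = 1000L, tol = 1e-10, n_starts = 5L, seed = 1L,
                        init = c("heuristic", "user", "random"), init_theta = NULL,
                        grad_tol = 1e-6, jitter_sd = 0.5, compute_se = TRUE) {
  init <- match.arg(init)
  if (tol <= 0) stopf("tol must be positive")
  if (n_starts < 1L) stopf("n_starts must be at least 1")
  if (init == "user" && is.null(init_theta)) stopf("init='user' requires init_theta")
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 init = init, init_theta = init_theta, grad_tol = grad_tol,
                 jitter_sd = jitter_sd, compute_se = isTRUE(compute_se)),
            class = "lc_fit_options")
}

# observed-data log-likelihood and analytic gradient in theta
loglik_grad <- function(theta, spec, st, f) {
  d <- theta_distributions(theta, spec, st)
  obs <- f > 0
  ll <- sum(f[obs] * log(d$P[obs]))
  r <- f / d$P
  pi <- d$pi
  grad <- numeric(length(theta))
  grad[1L] <- pi * (1 - pi) * sum(r * (d$q1 - d$q0))
  w0 <- (1 - pi) * r * d$q0
  w1 <- pi * r * d$q1
  K <- spec$K
  mu0 <- as.numeric(crossprod(st$Y, d$q0))
  mu1 <- as.numeric(crossprod(st$Y, d$q1))
  grad[2:(K + 1L)] <- as.numeric(crossprod(st$Y, w0)) - sum(w0) * mu0
  grad[(K + 2L):(2L * K + 1L)] <- as.numeric(crossprod(st$Y, w1)) - sum(w1) * mu1
  nT <- length(spec$interactions)
  if (nT) {
    nu0 <- as.numeric(crossprod(st$YY, d$q0))
    nu1 <- as.numeric(crossprod(st$YY, d$q1))
    c0 <- as.numeric(crossprod(st$YY, w0)) - sum(w0) * nu0
    c1 <- as.numeric(crossprod(st$YY, w1)) - sum(w1) * nu1
    pos <- 2L * K + 2L
    for (t in seq_len(nT)) {
      stt <- spec$interactions[[t]]$structure
      if (stt == "match_only") { grad[pos] <- c1[t]; pos <- pos + 1L }
      else if (stt == "nonmatch_only") { grad[pos] <- c0[t]; pos <- pos + 1L }
      else if (stt == "both_shared") { grad[pos] <- c0[t] + c1[t]; pos <- pos + 1L }
      else { grad[pos] <- c0[t]; grad[pos + 1L] <- c1[t]; pos <- pos + 2L }
    }
  }
  list(ll = ll, grad = grad)
}

# margin-based starting values: u ~ overall agreement proportion,
# m = u + 0.3 (capped), pi = 0.01, interactions at 0
heuristic_theta <- function(table, spec) {
  p <- as.numeric(crossprod(table$patterns, table$counts)) / table$N
  u <- clamp(p, 1e-5, 1 - 1e-5)
  m <- clamp(pmin(0.95, u + 0.3), 1e-5, 1 - 1e-5)
  c(stats::qlogis(0.01), stats::qlogis(u), stats::qlogis(m),
    numeric(theta_length(spec) - 2L * spec$K - 1L))
}

check_fit_inputs <- function(table, spec) {
  stopifnot(inherits(table, "lc_agreement_table"), inherits(spec, "lc_model_spec"))
  if (table$K != spec$K) stopf("table has K=%d but spec has K=%d", table$K, spec$K)
  if (table$N <= 0) stopf("cannot fit an empty pattern table")
  p <- as.numeric(crossprod(table$patterns, table$counts)) / table$N
  bad <- which(p <= 0 | p >= 1)
  if (length(bad))
    stopf("degenerate field(s) with agreement proportion 0 or 1: %s",
          paste(spec$field_names[bad], collapse = ", "))
}

# swap latent class labels of a theta vector; only well defined when every
# interaction structure is class-symmetric
swap_theta <- function(theta, spec) {
  K <- spec$K
  g <- theta_gammas(theta, spec)
  c(-theta[1L], theta[(K + 2L):(2L * K + 1L)], theta[2:(K + 1L)],
    gammas_to_theta_block(g$g1, g$g0, spec))
}

spec_is_symmetric <- function(spec) {
  all(vapply(spec$interactions,
             function(tr) tr$structure %in% c("both_shared", "both_distinct"), TRUE))
}

orient_theta <- function(theta, spec, st) {
  cl <- classical_from_theta(theta, spec, st)
  if (sum(cl$m) >= sum(cl$u)) return(theta)
  if (spec_is_symmetric(spec)) return(swap_theta(theta, spec))
  warning("fit converged to a label-swapped mode that the asymmetric ",
          "interaction structure cannot relabel; reporting as found")
  theta
}

build_fit <- function(theta, spec, table, st, loglik, converged, n_iter,
                      starts, method, compute_se = TRUE) {
  theta <- orient_theta(theta, spec, st)
  lambda <- lambda_from_theta(theta, spec, total = table$N)
  cl <- classical_from_theta(theta, spec, st)
  fit <- structure(list(spec = spec, theta = theta, lambda = lambda,
                        classical = classical_params(clamp(cl$pi, 1e-300, 1 - 1e-16),
                                                     clamp(cl$m, 1e-300, 1 - 1e-16),
                                                     clamp(cl$u, 1e-300, 1 - 1e-16)),
                        se_classical = NULL, loglik = loglik, deviance = NA_real_,
                        bic = NA_real_, converged = converged, n_iter = n_iter,
                        n_free = n_free_params(spec), N = table$N,
                        field_names = table$field_names, method = method,
                        starts = starts),
                   class = "lc_fit")
  fit$deviance <- g2_deviance(fit, table)
  fit$bic <- model_bic(fit, table)
  if (compute_se)
    fit$se_classical <- tryCatch(standard_errors(fit, table),
                                 error = function(e) NULL)
  fit
}

#' Maximum-likelihood fit by quasi-Newton optimization
#'
#' Maximizes the multinomial log-likelihood of the agreement-pattern table
#' under the loglinear latent class model by BFGS on the minimal free
#' parameterization (logit prevalence, within-class main effects, and the
#' free interaction coefficients), with multi-start to guard against local
#' maxima. The reported solution is oriented so that `sum(m) > sum(u)`.
#'
#' @param table An [agreement_table()].
#' @param spec A [model_spec()] with `spec$K == table$K`.
#' @param options A [fit_options()] object.
#' @return An object of class `lc_fit` with elements `spec`, `theta`,
#'   `lambda`, `classical`, `se_classical`, `loglik`, `deviance`, `bic`,
#'   `converged`, `n_iter`, `starts`.
#' @export
fit_ml <- function(table, spec = model_spec(table$K, field_names = table$field_names),
                   options = fit_options()) {
  check_fit_inputs(table, spec)
  st <- spec_stats(spec)
  f <- table$counts
  negll <- function(th) -loglik_grad(th, spec, st, f)$ll
  neggr <- function(th) -loglik_grad(th, spec, st, f)$grad

  base <- switch(options$init,
                 user = {
                   if (length(options$init_theta) != theta_length(spec))
                     stopf("init_theta has length %d, expected %d",
                           length(options$init_theta), theta_length(spec))
                   options$init_theta
                 },
                 heuristic_theta(table, spec))
  starts <- with_seed(options$seed, {
    s <- list(base)
    if (options$init == "random") s <- list()
    while (length(s) < options$n_starts)
      s[[length(s) + 1L]] <- base + stats::rnorm(length(base), sd = options$jitter_sd)
    s
  })
  if (options$init == "user" && options$n_starts > 1L) {
    # keep the heuristic start in the pool alongside the user warm start
    starts[[min(2L, length(starts))]] <- heuristic_theta(table, spec)
  }

  runs <- lapply(seq_along(starts), function(i) {
    res <- tryCatch(
      stats::optim(starts[[i]], fn = negll, gr = neggr, method = "BFGS",
                   control = list(maxit = options$max_iter, reltol = options$tol)),
      error = function(e) NULL)
    if (is.null(res)) return(list(ok = FALSE, ll = -Inf))
    # one restart from the solution polishes the BFGS approximation cheaply
    res2 <- tryCatch(
      stats::optim(res$par, fn = negll, gr = neggr, method = "BFGS",
                   control = list(maxit = options$max_iter, reltol = options$tol)),
      error = function(e) NULL)
    if (!is.null(res2) && res2$value <= res$value) res <- res2
    gmax <- max(abs(neggr(res$par)))
    # gradient criterion is relative: the score is a sum over N pairs, so its
    # raw norm scales with the data size
    gok <- is.finite(gmax) && gmax < options$grad_tol * max(1, abs(res$value))
    list(ok = TRUE, par = res$par, ll = -res$value,
         converged = res$convergence == 0L && gok,
         n_iter = unname(res$counts[1L]))
  })
  ok <- vapply(runs, function(r) r$ok, TRUE)
  if (!any(ok)) stopf("all %d optimization starts failed", length(runs))
  lls <- vapply(runs, function(r) if (r$ok) r$ll else -Inf, 0)
  best <- which.max(lls)
  log <- data.frame(start = seq_along(runs), loglik = lls,
                    converged = vapply(runs, function(r) isTRUE(r$converged), TRUE))
  r <- runs[[best]]
  build_fit(r$par, spec, table, st, r$ll, r$converged, r$n_iter, log,
            method = "ml", compute_se = options$compute_se)
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf("Loglinear latent class fit (%s): K = %d, %d free parameters%s\n",
              toupper(x$method), x$spec$K, x$n_free,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  logLik = %.4f   G2 = %.2f   BIC = %.2f   N = %s\n",
              x$loglik, x$deviance, x$bic, format(x$N, big.mark = ",", scientific = FALSE)))
  est <- data.frame(field = x$field_names,
                    m = round(x$classical$m, 4), u = round(x$classical$u, 4))
  cat(sprintf("  pi = %.4f%s\n", x$classical$pi,
              if (!is.null(x$se_classical))
                sprintf(" (SE %.4g)", x$se_classical$pi) else ""))
  print(est, row.names = FALSE)
  invisible(x)
}

# central-difference Hessian of the negative log-likelihood from the
# analytic gradient
observed_information <- function(theta, spec, st, f) {
  p <- length(theta)
  H <- matrix(0, p, p)
  h <- 1e-5 * (1 + abs(theta))
  for (i in seq_len(p)) {
    up <- theta; up[i] <- up[i] + h[i]
    dn <- theta; dn[i] <- dn[i] - h[i]
    H[, i] <- -(loglik_grad(up, spec, st, f)$grad -
                loglik_grad(dn, spec, st, f)$grad) / (2 * h[i])
  }
  (H + t(H)) / 2
}

#' Standard errors of the classical parameters
#'
#' Inverts the observed information of the free parameterization at the
#' fitted maximum and delta-method-transforms to the `(pi, m, u)` scale.
#'
#' @param fit An `lc_fit` object.
#' @param table The [agreement_table()] the model was fitted to.
#' @return List with numeric `pi`, `m` (length K) and `u` (length K)
#'   standard errors.
#' @export
standard_errors <- function(fit, table) {
  spec <- fit$spec
  st <- spec_stats(spec)
  H <- observed_information(fit$theta, spec, st, table$counts)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(abs(ev))) {
    nm <- theta_names(spec)
    v <- eigen(H, symmetric = TRUE)$vectors[, which.min(ev)]
    stopf("singular information matrix; flat direction dominated by: %s",
          paste(nm[order(-abs(v))[1:2]], collapse = ", "))
  }
  cov_theta <- solve(H)
  # numerical Jacobian of theta -> (pi, m, u)
  cl_vec <- function(th) {
    cl <- classical_from_theta(th, spec, st)
    c(cl$pi, cl$m, cl$u)
  }
  p <- length(fit$theta)
  h <- 1e-6 * (1 + abs(fit$theta))
  J <- matrix(0, nrow = 2L * spec$K + 1L, ncol = p)
  for (i in seq_len(p)) {
    up <- fit$theta; up[i] <- up[i] + h[i]
    dn <- fit$theta; dn[i] <- dn[i] - h[i]
    J[, i] <- (cl_vec(up) - cl_vec(dn)) / (2 * h[i])
  }
  se <- sqrt(pmax(0, diag(J %*% cov_theta %*% t(J))))
  list(pi = se[1L], m = se[2:(spec$K + 1L)], u = se[(spec$K + 2L):(2L * spec$K + 1L)])
}
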