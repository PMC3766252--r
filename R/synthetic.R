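# Synthetic agreement-pattern data from a fully specified two-class latent
# mixture, with optional injected within-class pairwise loglinear
# dependence, for calibration and parameter-recovery studies.

#' Simulation scenario for a latent-class linkage model
#'
#' States the generating world: match prevalence `pi`, per-field m- and
#' u-probabilities, optional injected within-class interactions with
#' class-conditional loglinear coefficients `gamma0` (nonmatch class) and
#' `gamma1` (match class), and the number of record pairs drawn.
#'
#' @param K Number of comparison fields.
#' @param pi Match prevalence in (0, 1).
#' @param m,u Length-`K` agreement probabilities in (0, 1). When a field
#'   takes part in an injected interaction these are its within-class
#'   loglinear main-effect probabilities (logit scale main effects), which
#'   equal its marginal agreement probabilities only in the no-interaction
#'   case.
#' @param interactions List of injected terms, each a list with `j`, `l`,
#'   `gamma0`, `gamma1`.
#' @param N Number of record pairs to draw.
#' @param seed Integer seed; recorded and used by [sample_table()].
#' @param field_names Optional field labels.
#' @return An object of class `lc_scenario`.
#' @export
simulation_scenario <- function(K, pi, m, u, interactions = list(), N,
                                seed = 1L, field_names = NULL) {
  K <- as.integer(K)
  if (length(m) == 1L) m <- rep(m, K)
  if (length(u) == 1L) u <- rep(u, K)
  cl <- classical_params(pi, m, u)     # validates (0,1) ranges
  if (N < 1) stopf("N must be at least 1")
  for (tr in interactions) {
    if (!all(c("j", "l", "gamma0", "gamma1") %in% names(tr)))
      stopf("each injected interaction needs j, l, gamma0, gamma1")
    if (tr$j >= tr$l || tr$j < 1 || tr$l > K) stopf("invalid interaction pair")
  }
  if (is.null(field_names)) field_names <- paste0("field", seq_len(K))
  structure(list(K = K, pi = cl$pi, m = cl$m, u = cl$u,
                 interactions = interactions, N = as.numeric(N),
                 seed = as.integer(seed), field_names = as.character(field_names)),
            class = "lc_scenario")
}

# model spec implied by the injected interaction coefficients
scenario_spec <- function(scenario) {
  terms <- lapply(scenario$interactions, function(tr) {
    structure_name <- if (tr$gamma0 == 0 && tr$gamma1 == 0) "both_shared"
      else if (tr$gamma0 == tr$gamma1) "both_shared"
      else if (tr$gamma0 == 0) "match_only"
      else if (tr$gamma1 == 0) "nonmatch_only"
      else "both_distinct"
    interaction_term(tr$j, tr$l, structure_name)
  })
  model_spec(scenario$K, terms, scenario$field_names)
}

scenario_theta <- function(scenario) {
  spec <- scenario_spec(scenario)
  g0 <- vapply(scenario$interactions, function(tr) tr$gamma0, 0)
  g1 <- vapply(scenario$interactions, function(tr) tr$gamma1, 0)
  c(stats::qlogis(scenario$pi), stats::qlogis(scenario$u), stats::qlogis(scenario$m),
    gammas_to_theta_block(g0, g1, spec))
}

#' Joint pattern-class probabilities of a scenario
#'
#' Within class `c` the log-probability of a pattern is proportional to
#' `sum_k y_k logit(p_ck) + sum gamma_c y_j y_l` (with `p_1k = m_k`,
#' `p_0k = u_k`), normalized per class; classes are mixed with weights
#' `(1 - pi, pi)`. Without injected terms the class distributions factorize
#' exactly into independent Bernoulli fields.
#'
#' @param scenario A [simulation_scenario()].
#' @return A `2^K` by 2 matrix with columns `nonmatch`, `match`, summing
#'   to 1.
#' @export
scenario_probabilities <- function(scenario) {
  stopifnot(inherits(scenario, "lc_scenario"))
  spec <- scenario_spec(scenario)
  d <- theta_distributions(scenario_theta(scenario), spec)
  cells <- cbind(nonmatch = (1 - d$pi) * d$q0, match = d$pi * d$q1)
  rownames(cells) <- apply(pattern_matrix(scenario$K), 1L, paste, collapse = "")
  cells
}

#' Draw an agreement-pattern table from a scenario
#'
#' One multinomial draw of size `N` over the `2 * 2^K` pattern-by-class
#' cells, marginalized over the latent class. Reproducible from
#' `scenario$seed`; the caller's RNG state is left untouched.
#'
#' @param scenario A [simulation_scenario()].
#' @param return_truth Also attach the per-class draw as attribute
#'   `truth` (a `2^K` by 2 matrix) for validation.
#' @return An [agreement_table()].
#' @export
sample_table <- function(scenario, return_truth = FALSE) {
  cells <- scenario_probabilities(scenario)
  draw <- with_seed(scenario$seed,
                    stats::rmultinom(1L, size = scenario$N, prob = as.vector(cells)))
  joint <- matrix(draw, ncol = 2L, dimnames = dimnames(cells))
  tab <- agreement_table(rowSums(joint), scenario$field_names)
  if (return_truth) attr(tab, "truth") <- joint
  tab
}

#' Parameter-recovery experiment
#'
#' Repeatedly draws tables from a scenario and refits a model (the true
#' spec by default), reporting per-parameter mean estimate, bias and RMSE.
#'
#' @param scenario A [simulation_scenario()].
#' @param n_reps Number of replicates.
#' @param seed Master seed; replicate `i` uses `seed + i`.
#' @param fit_spec [model_spec()] to fit (defaults to the scenario's own).
#' @param options [fit_options()] for the fits.
#' @return An object of class `lc_recovery`: data frame with columns
#'   `parameter`, `truth`, `mean_est`, `bias`, `rmse`; attribute `n_fail`
#'   counts failed replicate fits.
#' @export
recovery_experiment <- function(scenario, n_reps, seed = 1L, fit_spec = NULL,
                                options = fit_options()) {
  stopifnot(n_reps >= 1L)
  spec <- fit_spec %||% scenario_spec(scenario)
  truth_gamma <- unlist(lapply(scenario$interactions,
                               function(tr) c(tr$gamma0, tr$gamma1)))
  ests <- vector("list", n_reps)
  n_fail <- 0L
  for (i in seq_len(n_reps)) {
    sc_i <- scenario
    sc_i$seed <- scenario$seed + seed + i
    tab <- sample_table(sc_i)
    opt <- options
    opt$seed <- seed + i
    fit <- tryCatch(fit_ml(tab, spec, opt), error = function(e) NULL)
    if (is.null(fit)) { n_fail <- n_fail + 1L; next }
    g <- theta_gammas(fit$theta, spec)
    ests[[i]] <- c(pi = fit$classical$pi,
                   stats::setNames(fit$classical$m, paste0("m_", seq_len(spec$K))),
                   stats::setNames(fit$classical$u, paste0("u_", seq_len(spec$K))),
                   if (length(g$g0)) stats::setNames(
                     as.vector(rbind(g$g0, g$g1)),
                     as.vector(rbind(paste0("gamma0_", seq_along(g$g0)),
                                     paste0("gamma1_", seq_along(g$g1))))))
  }
  E <- do.call(rbind, ests)
  if (is.null(E)) stopf("all %d replicate fits failed", n_reps)
  same_spec <- is.null(fit_spec)
  truth <- c(scenario$pi,
             # marginal truth: class-conditional marginals of the scenario
             {
               cells <- scenario_probabilities(scenario)
               Y <- pattern_matrix(scenario$K)
               c(as.numeric(crossprod(Y, cells[, "match"])) / sum(cells[, "match"]),
                 as.numeric(crossprod(Y, cells[, "nonmatch"])) / sum(cells[, "nonmatch"]))
             },
             if (same_spec && length(truth_gamma)) truth_gamma)
  truth <- truth[seq_len(ncol(E))]
  out <- data.frame(parameter = colnames(E), truth = truth,
                    mean_est = colMeans(E),
                    bias = colMeans(E) - truth,
                    rmse = sqrt(colMeans(sweep(E, 2L, truth)^2)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("lc_recovery", "data.frame")
  attr(out, "n_fail") <- n_fail
  attr(out, "n_reps") <- n_reps
  out
}
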