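# Stepwise model building: iterate fit -> correlation-residual diagnosis ->
# four-structure comparison by BIC until no candidate field pair remains.

structure_order <- c("match_only", "nonmatch_only", "both_distinct", "both_shared")

#' Compare the four interaction structures for a candidate field pair
#'
#' Extends the base model by an interaction between fields `j` and `l` under
#' each of the four class structures, fits all four by maximum likelihood,
#' and selects the fit with the lowest BIC (the four models are not all
#' nested, so BIC rather than deviance is used). Non-converged candidates
#' are excluded from the comparison; ties are broken toward fewer
#' parameters, then by the fixed structure order `match_only`,
#' `nonmatch_only`, `both_distinct`, `both_shared`.
#'
#' @param table An [agreement_table()].
#' @param base_spec The current [model_spec()] (must not already contain the
#'   pair).
#' @param pair Integer vector `c(j, l)` with `j < l`.
#' @param options [fit_options()] passed to each fit.
#' @param warm_theta Optional parameter vector of the base-model fit; shared
#'   parameters warm-start each candidate.
#' @return List with `winner` (an `lc_fit`), `fits` (all four, named by
#'   structure), and `excluded` (structures dropped for non-convergence).
#' @export
compare_structures <- function(table, base_spec, pair, options = fit_options(),
                               warm_theta = NULL) {
  j <- as.integer(pair[1L]); l <- as.integer(pair[2L])
  for (tr in base_spec$interactions)
    if (tr$j == j && tr$l == l) stopf("pair (%d,%d) already in the model", j, l)
  fits <- list()
  for (stt in structure_order) {
    spec <- model_spec(base_spec$K,
                       c(base_spec$interactions, list(interaction_term(j, l, stt))),
                       base_spec$field_names)
    opt <- options
    if (!is.null(warm_theta)) {
      extra <- theta_length(spec) - length(warm_theta)
      opt <- fit_options(max_iter = options$max_iter, tol = options$tol,
                         n_starts = options$n_starts, seed = options$seed,
                         init = "user", init_theta = c(warm_theta, numeric(extra)),
                         grad_tol = options$grad_tol, jitter_sd = options$jitter_sd,
                         compute_se = options$compute_se)
    }
    fits[[stt]] <- tryCatch(fit_ml(table, spec, opt), error = function(e) NULL)
  }
  usable <- Filter(function(f) !is.null(f) && f$converged, fits)
  excluded <- setdiff(structure_order, names(usable))
  if (length(usable) == 0L)
    stopf("all four interaction-structure fits failed or did not converge for pair (%d,%d)", j, l)
  bics <- vapply(usable, function(f) f$bic, 0)
  nps <- vapply(usable, function(f) f$n_free, 0L)
  ord <- order(bics, nps, match(names(usable), structure_order))
  list(winner = usable[[ord[1L]]], fits = fits, excluded = excluded,
       bic = stats::setNames(vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic,
                                    0), names(fits)),
       pair = c(j = j, l = l))
}

#' Automated stepwise search for conditional dependence
#'
#' Implements the iterative model-building procedure: fit the
#' conditional-independence model, compute correlation residuals, flag the
#' field pair with the largest absolute residual above `threshold`, compare
#' the four interaction structures for that pair by BIC, accept the winner,
#' and repeat. The residual-threshold rule is the primary stopping
#' criterion; a BIC-no-improvement guard and `max_terms` cap the search.
#' Setting `explore_below_threshold = TRUE` keeps extending the model with
#' the largest remaining residual pair even below the threshold, for as long
#' as BIC improves (the optional "explore the next model anyway" behavior).
#'
#' @param table An [agreement_table()].
#' @param options [fit_options()] used for every fit.
#' @param threshold Absolute correlation-residual guideline (default 0.05).
#' @param max_terms Maximum number of interaction terms to add.
#' @param explore_below_threshold Continue past the threshold rule while BIC
#'   improves.
#' @return An object of class `lc_stepwise`: list with `models` (fits for
#'   Model 0, I, II, ...), `residuals` (one [correlation_residuals()] set
#'   per model), `decisions` (per-iteration candidate pair, the four BICs
#'   and the winner), and `stop_reason` (`"no_candidates"`,
#'   `"bic_no_improvement"` or `"max_iterations"`).
#' @export
run_stepwise <- function(table, options = fit_options(), threshold = 0.05,
                         max_terms = 5L, explore_below_threshold = FALSE) {
  fit <- fit_ml(table, model_spec(table$K, field_names = table$field_names), options)
  models <- list(fit)
  residual_sets <- list(correlation_residuals(table, fit))
  decisions <- list()
  stop_reason <- "max_iterations"
  for (iter in seq_len(max_terms)) {
    res <- residual_sets[[length(residual_sets)]]
    in_model <- vapply(fit$spec$interactions, function(tr) paste(tr$j, tr$l), "")
    res_free <- res[!paste(res$j, res$l) %in% in_model & !is.na(res$residual), ,
                    drop = FALSE]
    if (nrow(res_free) == 0L) { stop_reason <- "no_candidates"; break }
    top <- res_free[which.max(abs(res_free$residual)), ]
    if (abs(top$residual) <= threshold && !explore_below_threshold) {
      stop_reason <- "no_candidates"
      break
    }
    cmp <- compare_structures(table, fit$spec, c(top$j, top$l), options,
                              warm_theta = fit$theta)
    decision <- list(iteration = iter, pair = c(top$field_j, top$field_l),
                     residual = top$residual, bic = cmp$bic,
                     winner = cmp$winner$spec$interactions[[length(cmp$winner$spec$interactions)]]$structure,
                     accepted = cmp$winner$bic < fit$bic)
    decisions[[iter]] <- decision
    if (!decision$accepted) { stop_reason <- "bic_no_improvement"; break }
    fit <- cmp$winner
    models[[length(models) + 1L]] <- fit
    residual_sets[[length(residual_sets) + 1L]] <- correlation_residuals(table, fit)
    if (iter == max_terms) stop_reason <- "max_iterations"
  }
  names(models) <- paste0("Model ", c("0", as.character(utils::as.roman(
    seq_len(length(models) - 1L)))))[seq_along(models)]
  names(residual_sets) <- names(models)
  structure(list(models = models, residuals = residual_sets,
                 decisions = decisions, stop_reason = stop_reason,
                 threshold = threshold),
            class = "lc_stepwise")
}

#' @export
print.lc_stepwise <- function(x, ...) {
  cat(sprintf("Stepwise loglinear model search (%d model%s, stop: %s)\n",
              length(x$models), if (length(x$models) == 1L) "" else "s",
              x$stop_reason))
  for (nm in names(x$models)) {
    f <- x$models[[nm]]
    cat(sprintf("  %-9s p=%2d  G2=%10.2f  BIC=%12.2f  pi=%.4f\n",
                nm, f$n_free, f$deviance, f$bic, f$classical$pi))
  }
  for (d in x$decisions) {
    cat(sprintf("  iter %d: pair %s:%s (residual %.3f) -> %s%s\n",
                d$iteration, d$pair[1L], d$pair[2L], d$residual, d$winner,
                if (d$accepted) "" else " [rejected: BIC did not improve]"))
  }
  invisible(x)
}
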