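# JSON round-tripping of model specs, fits, stepwise traces and simulation
# scenarios. JSON is the single serialization format; floats are written at
# full precision so artifacts reproduce byte-identically under a fixed seed.

write_json_file <- function(x, path) {
  write_atomic(path, function(tmp)
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE))
}

#' Write a model specification to JSON
#'
#' Schema: `{"fields": [...], "interactions": [{"pair": [name_j, name_l],
#' "structure": "..."}]}`.
#'
#' @param spec A [model_spec()].
#' @param path Output path.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "lc_model_spec"))
  write_json_file(list(
    fields = spec$field_names,
    interactions = lapply(spec$interactions, function(tr)
      list(pair = list(spec$field_names[tr$j], spec$field_names[tr$l]),
           structure = tr$structure))), path)
}

#' Read a model specification from JSON
#'
#' @param path JSON file written by [write_model_spec()] (or hand-authored
#'   with the same schema; pairs may use field names or 1-based indices).
#' @return A [model_spec()].
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$fields)) stopf("model spec '%s' lacks a 'fields' array", path)
  fields <- unlist(x$fields)
  terms <- lapply(x$interactions %||% list(), function(tr) {
    pr <- unlist(tr$pair)
    idx <- if (suppressWarnings(all(!is.na(as.integer(pr))))) as.integer(pr)
           else match(pr, fields)
    if (any(is.na(idx))) stopf("unknown field in interaction pair: %s",
                               paste(pr, collapse = ", "))
    interaction_term(min(idx), max(idx), tr$structure)
  })
  model_spec(length(fields), terms, fields)
}

fit_to_list <- function(fit) {
  list(spec = list(fields = fit$spec$field_names,
                   interactions = lapply(fit$spec$interactions, function(tr)
                     list(pair = list(fit$spec$field_names[tr$j],
                                      fit$spec$field_names[tr$l]),
                          structure = tr$structure))),
       theta = fit$theta,
       lambda = unclass(fit$lambda),
       classical = unclass(fit$classical),
       se_classical = fit$se_classical,
       loglik = fit$loglik, deviance = fit$deviance, bic = fit$bic,
       n_free_params = fit$n_free, N = fit$N,
       converged = fit$converged, n_iter = fit$n_iter, method = fit$method)
}

#' Write a fit result to JSON
#'
#' @param fit An `lc_fit` object.
#' @param path Output path.
#' @param seed Optional seed to record in the artifact.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  x <- fit_to_list(fit)
  if (!is.null(seed)) x$seed <- seed
  write_json_file(x, path)
}

#' Read a fit result from JSON
#'
#' Reconstructs the `lc_fit` from the stored free parameter vector and the
#' recorded spec; derived quantities are recomputed, so the object is usable
#' by [correlation_residuals()], [classify()] etc.
#'
#' @param path JSON file written by [write_fit_json()].
#' @param table The [agreement_table()] the fit refers to (for deviance and
#'   BIC; `N` must match the stored fit).
#' @return An `lc_fit` object.
#' @export
read_fit_json <- function(path, table) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- x$spec$fields
  terms <- list()
  ints <- x$spec$interactions
  if (!is.null(ints) && length(ints)) {
    if (is.data.frame(ints)) {
      for (r in seq_len(nrow(ints))) {
        idx <- match(unlist(ints$pair[r]), fields)
        terms[[r]] <- interaction_term(min(idx), max(idx), ints$structure[r])
      }
    } else {
      for (r in seq_along(ints)) {
        idx <- match(unlist(ints[[r]]$pair), fields)
        terms[[r]] <- interaction_term(min(idx), max(idx), ints[[r]]$structure)
      }
    }
  }
  spec <- model_spec(length(fields), terms, fields)
  if (!identical(sort(fields), sort(table$field_names)))
    stopf("fit '%s' was computed for fields %s, not the table's fields", path,
          paste(fields, collapse = ", "))
  st <- spec_stats(spec)
  ll <- loglik_grad(x$theta, spec, st, table$counts)$ll
  build_fit(x$theta, spec, table, st, ll, isTRUE(x$converged),
            x$n_iter %||% NA_integer_, NULL, method = x$method %||% "ml",
            compute_se = FALSE)
}

#' Write a stepwise trace to JSON
#'
#' @param trace An `lc_stepwise` object.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @export
write_trace_json <- function(trace, path, seed = NULL) {
  x <- list(models = lapply(trace$models, fit_to_list),
            decisions = trace$decisions,
            stop_reason = trace$stop_reason,
            threshold = trace$threshold)
  if (!is.null(seed)) x$seed <- seed
  write_json_file(x, path)
}

#' Read a simulation scenario from JSON
#'
#' Schema: `{"K":, "pi":, "m": [...], "u": [...], "N":, "seed":,
#' "interactions": [{"j":, "l":, "gamma0":, "gamma1":}], "fields": [...]}`.
#'
#' @param path JSON file path.
#' @return A [simulation_scenario()].
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ints <- list()
  if (!is.null(x$interactions) && length(x$interactions)) {
    df <- x$interactions
    if (is.data.frame(df)) {
      ints <- lapply(seq_len(nrow(df)), function(r)
        list(j = df$j[r], l = df$l[r], gamma0 = df$gamma0[r], gamma1 = df$gamma1[r]))
    } else ints <- df
  }
  simulation_scenario(K = x$K, pi = x$pi, m = x$m, u = x$u, interactions = ints,
                      N = x$N, seed = x$seed %||% 1L,
                      field_names = x$fields %||% NULL)
}

#' Write a simulation scenario to JSON
#'
#' @param scenario A [simulation_scenario()].
#' @param path Output path.
#' @export
write_scenario <- function(scenario, path) {
  write_json_file(list(K = scenario$K, pi = scenario$pi, m = scenario$m,
                       u = scenario$u,
                       interactions = scenario$interactions,
                       N = scenario$N, seed = scenario$seed,
                       fields = scenario$field_names), path)
}
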