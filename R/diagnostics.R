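# Correlation-residual diagnostic for conditional dependence: compare the
# observed pairwise correlation of field agreements with the correlation
# implied by the fitted model; a large residual flags a field pair whose
# dependence the model does not capture.

# pairwise phi correlations of binary fields under a pattern distribution w
pair_correlations <- function(w, Y, field_names) {
  K <- ncol(Y)
  p <- as.numeric(crossprod(Y, w))
  pairs <- which(upper.tri(diag(K)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  if (nrow(pairs) == 0L)
    return(data.frame(j = integer(0), l = integer(0), field_j = character(0),
                      field_l = character(0), correlation = numeric(0),
                      stringsAsFactors = FALSE))
  corr <- apply(pairs, 1L, function(ix) {
    j <- ix[1L]; l <- ix[2L]
    pjl <- sum(w * Y[, j] * Y[, l])
    den <- p[j] * (1 - p[j]) * p[l] * (1 - p[l])
    if (den <= 0) return(NA_real_)
    (pjl - p[j] * p[l]) / sqrt(den)
  })
  data.frame(j = pairs[, 1L], l = pairs[, 2L],
             field_j = field_names[pairs[, 1L]], field_l = field_names[pairs[, 2L]],
             correlation = as.numeric(corr), stringsAsFactors = FALSE)
}

#' Observed pairwise agreement correlations
#'
#' The phi correlation `(p_jl - p_j p_l) / sqrt(p_j(1-p_j) p_l(1-p_l))` for
#' every field pair, with the margins and joint proportions estimated from
#' the observed pattern counts. Pairs with a degenerate margin are reported
#' as `NA` rather than failing.
#'
#' @param table An [agreement_table()] with `N > 0`.
#' @return Data frame with columns `j`, `l`, `field_j`, `field_l`,
#'   `correlation`.
#' @export
observed_correlations <- function(table) {
  stopifnot(inherits(table, "lc_agreement_table"))
  if (table$N <= 0) stopf("pattern table is empty")
  pair_correlations(table$counts / table$N, table$patterns, table$field_names)
}

#' Model-expected pairwise agreement correlations
#'
#' Same statistic as [observed_correlations()] but evaluated at the
#' model-based expected counts `N * P(Y_d)` over all `2^K` patterns
#' (equivalently at the fitted pattern probabilities).
#'
#' @param fit An `lc_fit` object.
#' @return Data frame as in [observed_correlations()].
#' @export
expected_correlations <- function(fit) {
  stopifnot(inherits(fit, "lc_fit"))
  P <- pattern_probabilities(fit$lambda, fit$spec)
  pair_correlations(P, spec_stats(fit$spec)$Y, fit$field_names)
}

#' Correlation residuals of a fitted model
#'
#' Observed minus model-expected pairwise agreement correlation for all
#' `K(K-1)/2` field pairs. Residuals far from zero indicate conditional
#' dependence the fitted model does not account for.
#'
#' @param table An [agreement_table()].
#' @param fit An `lc_fit` for the same fields.
#' @return An object of class `lc_residuals`: data frame with columns `j`,
#'   `l`, `field_j`, `field_l`, `observed`, `expected`, `residual`.
#' @export
correlation_residuals <- function(table, fit) {
  if (table$K != fit$spec$K) stopf("table and fit disagree on K")
  obs <- observed_correlations(table)
  exp_ <- expected_correlations(fit)
  out <- obs
  names(out)[names(out) == "correlation"] <- "observed"
  out$expected <- exp_$correlation
  out$residual <- out$observed - out$expected
  class(out) <- c("lc_residuals", "data.frame")
  out
}

#' @export
print.lc_residuals <- function(x, ...) {
  cat(sprintf("Correlation residuals for %d field pairs (max |residual| = %.4f)\n",
              nrow(x), max(abs(x$residual), na.rm = TRUE)))
  df <- as.data.frame(x)
  df$observed <- round(df$observed, 4)
  df$expected <- round(df$expected, 4)
  df$residual <- round(df$residual, 4)
  print(df[order(-abs(df$residual)), c("field_j", "field_l", "observed",
                                       "expected", "residual")],
        row.names = FALSE)
  invisible(x)
}

#' Field pairs flagged as conditionally dependent
#'
#' Returns the pairs whose absolute correlation residual exceeds the
#' threshold, sorted by descending magnitude. The default threshold 0.05 is
#' an experience-based guideline, not a formal test.
#'
#' @param residuals An [correlation_residuals()] result.
#' @param threshold Absolute-residual cutoff.
#' @return Subset of the residual data frame (possibly empty); `NA`
#'   residuals are never flagged.
#' @export
flag_candidates <- function(residuals, threshold = 0.05) {
  stopifnot(inherits(residuals, "lc_residuals"))
  keep <- !is.na(residuals$residual) & abs(residuals$residual) > threshold
  out <- residuals[keep, , drop = FALSE]
  out[order(-abs(out$residual)), , drop = FALSE]
}

#' Correlation residual plot
#'
#' Scatter of residuals against pair index with pair labels and horizontal
#' guides at plus/minus the threshold. Passing a named list of residual sets
#' draws one panel per model (the multi-model layout used when comparing a
#' stepwise sequence).
#'
#' @param residuals An [correlation_residuals()] result, or a named list of
#'   them.
#' @param path Optional output file (`.png` or `.pdf`); plots to the active
#'   device when `NULL`.
#' @param threshold Guideline drawn as dashed lines.
#' @param main Plot title (panel names are used for lists).
#' @return Invisibly, `path`.
#' @export
plot_residuals <- function(residuals, path = NULL, threshold = 0.05, main = NULL) {
  panels <- if (inherits(residuals, "lc_residuals")) {
    stats::setNames(list(residuals), main %||% "Correlation residuals")
  } else {
    stopifnot(is.list(residuals), length(residuals) > 0L)
    residuals
  }
  draw <- function() {
    op <- graphics::par(mfrow = c(length(panels), 1L), mar = c(6.5, 4, 2.5, 1))
    on.exit(graphics::par(op), add = TRUE)
    for (nm in names(panels)) {
      r <- panels[[nm]]
      n <- nrow(r)
      ylim <- range(c(-threshold, threshold, r$residual), na.rm = TRUE) * 1.15
      graphics::plot(seq_len(n), r$residual, pch = 19, xaxt = "n",
                     xlab = "", ylab = "correlation residual",
                     main = nm, ylim = ylim,
                     xlim = c(0.5, max(n, 1) + 0.5))
      graphics::abline(h = 0, col = "grey50")
      graphics::abline(h = c(-threshold, threshold), lty = 2, col = "red")
      if (n > 0)
        graphics::axis(1, at = seq_len(n), las = 2, cex.axis = 0.7,
                       labels = paste0(r$field_j, ":", r$field_l))
    }
  }
  if (is.null(path)) {
    draw()
  } else {
    ext <- tolower(tools::file_ext(path))
    open_dev <- switch(ext,
                       png = function(p) grDevices::png(p, width = 900,
                                                        height = 320 * length(panels), res = 110),
                       pdf = function(p) grDevices::pdf(p, width = 9,
                                                        height = 3.2 * length(panels)),
                       stopf("unsupported plot format '.%s' (use .png or .pdf)", ext))
    ok <- tryCatch({ open_dev(path); TRUE }, error = function(e) FALSE)
    if (!ok) stopf("cannot open plot device for '%s'", path)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  }
  invisible(path)
}
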