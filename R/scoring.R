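# Classification of record pairs from a fitted model: posterior match
# probabilities, match scores, and pattern-level match/nonmatch labels.

#' Posterior match probabilities per agreement pattern
#'
#' `P(M = 1 | Y_d) = m(Y_d, 1) / (m(Y_d, 1) + m(Y_d, 0))` for every pattern.
#' Averaging over the fitted pattern distribution recovers the match
#' prevalence.
#'
#' @param fit An `lc_fit` object.
#' @return Numeric vector of `2^K` probabilities in pattern-table order.
#' @export
posterior_probabilities <- function(fit) {
  stopifnot(inherits(fit, "lc_fit"))
  cells <- expected_cell_means(fit$lambda, fit$spec)
  unname(cells[, "match"] / rowSums(cells))
}

#' Record-pair classification rule
#'
#' @param mode `"posterior_threshold"` (match iff posterior exceeds
#'   `posterior_cut`), `"score_thresholds"` (three-way match / uncertain /
#'   nonmatch split on the log2 match score), or `"prevalence_rank"`
#'   (declare the highest-scoring patterns matches until the cumulative pair
#'   count first reaches `N * pi_hat`, emulating classification based on the
#'   estimated match prevalence).
#' @param posterior_cut Posterior probability cut, in (0, 1).
#' @param score_lower,score_upper Uncertain-zone bounds on the score scale
#'   (`score_lower <= score_upper`; equal bounds give a two-way split).
#' @param target_prevalence Prevalence for `prevalence_rank`; defaults to
#'   the fitted match prevalence.
#' @return An object of class `lc_rule`.
#' @export
classification_rule <- function(mode = c("posterior_threshold", "score_thresholds",
                                         "prevalence_rank"),
                                posterior_cut = 0.5, score_lower = 0, score_upper = 0,
                                target_prevalence = NULL) {
  mode <- match.arg(mode)
  if (posterior_cut <= 0 || posterior_cut >= 1) stopf("posterior_cut must be in (0,1)")
  if (score_lower > score_upper) stopf("score_lower must not exceed score_upper")
  if (!is.null(target_prevalence) &&
      (target_prevalence < 0 || target_prevalence > 1))
    stopf("target_prevalence must be in [0,1]")
  structure(list(mode = mode, posterior_cut = posterior_cut,
                 score_lower = score_lower, score_upper = score_upper,
                 target_prevalence = target_prevalence),
            class = "lc_rule")
}

#' Classify agreement patterns as matches or non-matches
#'
#' Labels every agreement pattern (classification is a function of the
#' pattern only) and totals the declared matches over the observed pair
#' counts.
#'
#' @param fit An `lc_fit` object.
#' @param table The [agreement_table()] being classified.
#' @param rule A [classification_rule()]; default: posterior threshold 0.5.
#' @return An object of class `lc_classification`: data frame with columns
#'   `pattern`, `count`, `score`, `posterior`, `label`, plus attributes
#'   `n_match` (declared-match pair count), `n_uncertain` and `rule`.
#' @export
classify <- function(fit, table, rule = classification_rule()) {
  stopifnot(inherits(fit, "lc_fit"), inherits(table, "lc_agreement_table"))
  if (!inherits(rule, "lc_rule")) stopf("unknown classification rule configuration")
  if (table$K != fit$spec$K) stopf("table and fit disagree on K")
  score <- match_score(fit$lambda, fit$spec)
  post <- posterior_probabilities(fit)
  D <- length(score)
  label <- rep("nonmatch", D)
  if (rule$mode == "posterior_threshold") {
    label[post > rule$posterior_cut] <- "match"
  } else if (rule$mode == "score_thresholds") {
    label[score > rule$score_upper] <- "match"
    label[score >= rule$score_lower & score <= rule$score_upper &
            rule$score_lower < rule$score_upper] <- "uncertain"
  } else { # prevalence_rank
    target <- (rule$target_prevalence %||% fit$classical$pi) * table$N
    ord <- order(-score, seq_len(D))
    csum <- cumsum(table$counts[ord])
    n_top <- if (target <= 0) 0L else which(csum >= target)[1L]
    if (is.na(n_top)) n_top <- D
    if (n_top > 0L) label[ord[seq_len(n_top)]] <- "match"
  }
  out <- data.frame(pattern = apply(table$patterns, 1L, paste, collapse = ""),
                    count = table$counts, score = score, posterior = post,
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("lc_classification", "data.frame")
  attr(out, "n_match") <- sum(out$count[out$label == "match"])
  attr(out, "n_uncertain") <- sum(out$count[out$label == "uncertain"])
  attr(out, "rule") <- rule
  out
}

#' @export
print.lc_classification <- function(x, ...) {
  cat(sprintf("Pattern classification (%s): %s of %s pairs declared matches, %s uncertain\n",
              attr(x, "rule")$mode,
              format(attr(x, "n_match"), big.mark = ",", scientific = FALSE),
              format(sum(x$count), big.mark = ",", scientific = FALSE),
              format(attr(x, "n_uncertain"), big.mark = ",", scientific = FALSE)))
  df <- as.data.frame(x)[order(-x$score), ]
  df$score <- round(df$score, 3)
  df$posterior <- signif(df$posterior, 4)
  print(utils::head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat(sprintf("  ... %d more patterns\n", nrow(df) - 10L))
  invisible(x)
}
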