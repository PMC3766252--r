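# fixtures built in code: toy tables, random parameter draws, oracles

# classical Fellegi-Sunter mixture probability of every pattern, computed
# directly from (pi, m, u) -- the independent oracle for the loglinear route
fs_mixture_probs <- function(pi, m, u) {
  Y <- pattern_matrix(length(m))
  apply(Y, 1L, function(y)
    pi * prod(m^y * (1 - m)^(1 - y)) + (1 - pi) * prod(u^y * (1 - u)^(1 - y)))
}

random_classical <- function(K, pi_range = c(0.02, 0.3),
                             m_range = c(0.4, 0.9), u_range = c(0.02, 0.25)) {
  classical_params(stats::runif(1, pi_range[1], pi_range[2]),
                   stats::runif(K, m_range[1], m_range[2]),
                   stats::runif(K, u_range[1], u_range[2]))
}

toy_table_k2 <- function(f11 = 30, f10 = 10, f01 = 10, f00 = 50) {
  # pattern order: 00, 01, 10, 11
  agreement_table(c(f00, f01, f10, f11), c("a", "b"))
}

toy_records <- function() {
  data.frame(
    last = c("Smith", "smith ", "Jones", "Smith", "Lee", NA),
    first = c("Ann", "ANN", "Bob", "Ann", "Cy", "Dee"),
    ssn = c("123", "123", "999", "", "555", "777"),
    zip = c("46202", "46202", "46203", "46204", "46205", "46206"),
    sex = c("F", "F", "M", "F", "M", "F"),
    stringsAsFactors = FALSE)
}

quick_opts <- function(seed = 1L, n_starts = 2L, compute_se = FALSE, ...) {
  fit_options(seed = seed, n_starts = n_starts, compute_se = compute_se, ...)
}
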