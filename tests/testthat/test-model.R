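test_that("expected_cell_means evaluates the loglinear predictor", {
  # all coefficients zero -> every cell mean is exp(0) = 1
  spec1 <- model_spec(1)
  lam <- lambda_params(lam_k = 0, lamM_k = 0)
  expect_equal(unname(expected_cell_means(lam, spec1)), matrix(1, 2, 2))

  # a shared interaction log(2) doubles the y1=y2=1 cells in both classes
  spec2 <- model_spec(2, interaction_term(1, 2, "both_shared"))
  lam2 <- lambda_params(lam_k = c(0, 0), lamM_k = c(0, 0),
                        lam_jl = log(2), lamM_jl = 0)
  cells <- expected_cell_means(lam2, spec2)
  expect_equal(unname(cells["11", ]), c(2, 2))
  expect_equal(unname(cells["10", ]), c(1, 1))

  # under CI the class ratio depends on Y only through sum(lamM_k y_k)
  spec3 <- model_spec(3)
  lam3 <- lambda_params(lam0 = 0.3, lamM = -1, lam_k = c(0.2, -0.4, 1),
                        lamM_k = c(1.5, 0.7, -0.2))
  cells3 <- expected_cell_means(lam3, spec3)
  ratio <- log(cells3[, "match"] / cells3[, "nonmatch"])
  pred <- -1 + pattern_matrix(3) %*% c(1.5, 0.7, -0.2)
  expect_equal(unname(ratio), drop(pred))

  expect_error(expected_cell_means(lambda_params(lam_k = c(Inf), lamM_k = 0), spec1),
               "non-finite")
})

test_that("pattern probabilities normalize and ignore intercept shifts", {
  spec <- model_spec(2)
  lam <- lambda_params(lam_k = c(0, 0), lamM_k = c(0, 0))
  expect_equal(pattern_probabilities(lam, spec), rep(0.25, 4))

  set.seed(42)
  for (K in 1:4) {
    spec <- model_spec(K)
    lam <- classical_to_lambda(random_classical(K))
    P <- pattern_probabilities(lam, spec)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    shifted <- lam; shifted$lam0 <- shifted$lam0 + 3.7
    expect_equal(pattern_probabilities(shifted, spec), P, tolerance = 1e-12)
  }
})

test_that("CI loglinear probabilities equal the F-S mixture exhaustively (K <= 5)", {
  set.seed(7)
  for (K in 1:5) {
    for (rep in 1:3) {
      cl <- random_classical(K)
      P <- pattern_probabilities(classical_to_lambda(cl), model_spec(K))
      expect_equal(P, fs_mixture_probs(cl$pi, cl$m, cl$u), tolerance = 1e-12)
    }
  }
})

test_that("lambda_to_classical applies the logistic identities", {
  spec <- model_spec(1)
  lam <- lambda_params(lam_k = 0, lamM_k = 0)
  cl <- lambda_to_classical(lam, spec)
  expect_equal(c(cl$pi, cl$m, cl$u), c(0.5, 0.5, 0.5))

  # one-field fragment at the sex margins: u = 0.661, m = 0.710
  lam2 <- lambda_params(lam_k = qlogis(0.661),
                        lamM_k = qlogis(0.710) - qlogis(0.661))
  cl2 <- lambda_to_classical(lam2, spec)
  expect_equal(cl2$u, 0.661, tolerance = 1e-12)
  expect_equal(cl2$m, 0.710, tolerance = 1e-12)
})

test_that("classical and lambda parameterizations round-trip on CI specs", {
  set.seed(13)
  for (K in c(1, 3, 5)) {
    cl <- random_classical(K)
    back <- lambda_to_classical(classical_to_lambda(cl), model_spec(K))
    expect_equal(back$pi, cl$pi, tolerance = 1e-10)
    expect_equal(back$m, cl$m, tolerance = 1e-10)
    expect_equal(back$u, cl$u, tolerance = 1e-10)
  }
  expect_error(classical_to_lambda(list(pi = 0.5, m = 1, u = 0.2)), "strictly")
})

test_that("log_likelihood matches the hand-summed multinomial form", {
  tab <- toy_table_k2()
  cl <- classical_params(0.2, c(0.8, 0.7), c(0.3, 0.25))
  lam <- classical_to_lambda(cl)
  spec <- model_spec(2)
  P <- fs_mixture_probs(cl$pi, cl$m, cl$u)
  expect_equal(log_likelihood(lam, spec, tab), sum(tab$counts * log(P)))
  # empty table and translation invariance
  empty <- agreement_table(rep(0, 4), c("a", "b"))
  expect_identical(log_likelihood(lam, spec, empty), 0)
  shifted <- lam; shifted$lam0 <- shifted$lam0 - 11
  expect_equal(log_likelihood(shifted, spec, tab), log_likelihood(lam, spec, tab),
               tolerance = 1e-9)
  # single observed pattern: N * log p
  single <- agreement_table(c(0, 0, 0, 25), c("a", "b"))
  expect_equal(log_likelihood(lam, spec, single), 25 * log(P[4]))
})

test_that("n_free_params counts parameters per structure", {
  expect_identical(n_free_params(model_spec(7)), 15L)
  expect_identical(n_free_params(model_spec(1)), 3L)
  expect_identical(n_free_params(model_spec(7, interaction_term(4, 5, "both_distinct"))), 17L)
  expect_identical(n_free_params(model_spec(7, list(
    interaction_term(1, 2, "match_only"), interaction_term(2, 3, "nonmatch_only"),
    interaction_term(3, 4, "both_shared")))), 18L)
  expect_error(model_spec(3, list(interaction_term(1, 2), interaction_term(1, 2))),
               "duplicate")
  expect_error(interaction_term(2, 2), "j < l")
})

test_that("BIC is monotone in loglik and penalizes parameters by log N", {
  sc <- simulation_scenario(3, 0.1, m = c(.8, .7, .6), u = c(.1, .1, .2),
                            N = 5000, seed = 5)
  tab <- sample_table(sc)
  f_ci <- fit_ml(tab, model_spec(3, field_names = tab$field_names), quick_opts())
  spec_big <- model_spec(3, interaction_term(1, 2, "both_distinct"),
                         tab$field_names)
  f_big <- fit_ml(tab, spec_big, quick_opts())
  # nested extension never lowers the maximized log-likelihood
  expect_gte(f_big$loglik, f_ci$loglik - 1e-8)
  expect_equal(f_ci$bic, -2 * f_ci$loglik + 7 * log(tab$N))
  expect_equal(f_big$bic, -2 * f_big$loglik + 9 * log(tab$N))
  # equal loglik would differ by exactly delta_p * log N
  expect_gte(f_big$bic, f_ci$bic - 2 * (f_big$loglik - f_ci$loglik))
})

test_that("match scores reduce to per-field F-S log2 weights under CI", {
  spec <- model_spec(1)
  lam <- classical_to_lambda(classical_params(0.3, 0.8, 0.2))
  expect_equal(match_score(lam, spec, 1), 2)            # log2(0.8/0.2)
  # uninformative fields score 0 everywhere
  flat <- classical_to_lambda(classical_params(0.4, c(.3, .6), c(.3, .6)))
  expect_equal(match_score(flat, model_spec(2)), rep(0, 4), tolerance = 1e-12)
  # random CI fits against the closed-form weight sum
  set.seed(23)
  for (K in 1:3) {
    cl <- random_classical(K)
    lam <- classical_to_lambda(cl)
    Y <- pattern_matrix(K)
    oracle <- apply(Y, 1, function(y)
      sum(y * log2(cl$m / cl$u) + (1 - y) * log2((1 - cl$m) / (1 - cl$u))))
    expect_equal(match_score(lam, model_spec(K)), oracle, tolerance = 1e-10)
  }
})

test_that("deviance is zero at a saturated fit and matches its formula", {
  tab <- toy_table_k2()
  # both_distinct on the only pair saturates the 3 free multinomial cells
  spec <- model_spec(2, interaction_term(1, 2, "both_distinct"), tab$field_names)
  fit <- fit_ml(tab, spec, quick_opts())
  expect_equal(fit$deviance, 0, tolerance = 1e-6)
  P <- pattern_probabilities(fit$lambda, fit$spec)
  expect_equal(P, tab$counts / tab$N, tolerance = 1e-6)
  # explicit formula on a non-saturated fit
  ci <- fit_ml(tab, model_spec(2, field_names = tab$field_names), quick_opts())
  Pci <- pattern_probabilities(ci$lambda, ci$spec)
  expect_equal(ci$deviance,
               2 * sum(tab$counts * log(tab$counts / (tab$N * Pci))))
})
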