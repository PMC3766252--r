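test_that("observed correlations match hand arithmetic", {
  # f(11)=30, f(10)=10, f(01)=10, f(00)=50
  tab <- toy_table_k2()
  r <- observed_correlations(tab)
  expect_equal(r$correlation,
               (0.3 - 0.4 * 0.4) / sqrt(0.4 * 0.6 * 0.4 * 0.6))
  # balanced table -> independence -> 0
  expect_equal(observed_correlations(toy_table_k2(10, 10, 10, 10))$correlation, 0)
  # perfectly coupled fields -> 1
  expect_equal(observed_correlations(toy_table_k2(40, 0, 0, 60))$correlation, 1)
})

test_that("degenerate margins give NA, not an error", {
  tab <- agreement_table(c(5, 0, 7, 0), c("a", "b"))  # b never agrees
  r <- observed_correlations(tab)
  expect_true(is.na(r$correlation))
})

test_that("correlations are symmetric and bounded", {
  set.seed(4)
  sc <- simulation_scenario(4, 0.1, m = c(.8, .7, .6, .9), u = c(.1, .2, .05, .15),
                            interactions = list(list(j = 1, l = 4, gamma0 = 1, gamma1 = 1)),
                            N = 1e4, seed = 12)
  tab <- sample_table(sc)
  r <- observed_correlations(tab)
  expect_true(all(abs(r$correlation) <= 1 + 1e-12))
  expect_equal(nrow(r), choose(4, 2))
  expect_true(all(r$j < r$l))
})

test_that("expected correlations vanish in the single-class limit and are
           positive for informative two-class CI models", {
  # pi -> 0: essentially one CI class, within which fields are independent
  lam <- classical_to_lambda(classical_params(1e-8, c(.8, .7), c(.3, .2)))
  fitlike <- structure(list(lambda = lam, spec = model_spec(2),
                            field_names = c("a", "b")), class = "lc_fit")
  expect_equal(expected_correlations(fitlike)$correlation, 0, tolerance = 1e-5)

  # brute-force oracle over all 4 patterns for a genuine mixture
  cl <- classical_params(0.3, c(.8, .7), c(.2, .1))
  lam2 <- classical_to_lambda(cl)
  fitlike2 <- structure(list(lambda = lam2, spec = model_spec(2),
                             field_names = c("a", "b")), class = "lc_fit")
  P <- fs_mixture_probs(cl$pi, cl$m, cl$u)
  Y <- pattern_matrix(2)
  p1 <- sum(P * Y[, 1]); p2 <- sum(P * Y[, 2]); p12 <- sum(P * Y[, 1] * Y[, 2])
  oracle <- (p12 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  got <- expected_correlations(fitlike2)$correlation
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_gt(got, 0)
})

test_that("residuals are observed minus expected and shrink like 1/sqrt(N)", {
  sc <- function(N, seed) simulation_scenario(4, 0.08, m = c(.8, .7, .6, .75),
                                              u = c(.1, .05, .2, .15), N = N, seed = seed)
  worst <- sapply(c(1e4, 1e6), function(N) {
    tab <- sample_table(sc(N, 101))
    fit <- fit_ml(tab, options = quick_opts())
    res <- correlation_residuals(tab, fit)
    expect_equal(res$residual, res$observed - res$expected)
    max(abs(res$residual))
  })
  expect_lt(worst[2], worst[1])   # calibration improves with N
  expect_lt(worst[2], 0.01)
})

test_that("a fitted interaction absorbs the corresponding residual", {
  sc <- simulation_scenario(5, 0.04, m = c(.7, .6, .5, .75, .65),
                            u = c(.05, .1, .12, .02, .08),
                            interactions = list(list(j = 2, l = 3, gamma0 = 1.2, gamma1 = 0.8)),
                            N = 5e5, seed = 31)
  tab <- sample_table(sc)
  ci <- fit_ml(tab, model_spec(5, field_names = tab$field_names), quick_opts())
  res_ci <- correlation_residuals(tab, ci)
  dep <- fit_ml(tab, model_spec(5, interaction_term(2, 3, "both_distinct"),
                                tab$field_names), quick_opts())
  res_dep <- correlation_residuals(tab, dep)
  at <- res_ci$j == 2 & res_ci$l == 3
  expect_gt(abs(res_ci$residual[at]), 0.05)
  expect_lt(abs(res_dep$residual[at]), 0.01)   # expected ~ observed once modeled
})

test_that("flag_candidates sorts above-threshold pairs and honors threshold 0", {
  res <- structure(data.frame(j = c(1, 1, 2), l = c(2, 3, 3),
                              field_j = c("a", "a", "b"), field_l = c("b", "c", "c"),
                              observed = c(.2, .01, -.1), expected = c(.01, .005, .02),
                              residual = c(.19, .005, -.12)),
                   class = c("lc_residuals", "data.frame"))
  got <- flag_candidates(res, 0.05)
  expect_equal(got$residual, c(.19, -.12))
  expect_equal(nrow(flag_candidates(res, 0.5)), 0L)
  expect_equal(nrow(flag_candidates(res, 0)), 3L)
  res$residual[2] <- NA
  expect_equal(nrow(flag_candidates(res, 0)), 2L)
})

test_that("plot_residuals writes single and multi-panel files", {
  sc <- simulation_scenario(3, 0.1, m = c(.8, .7, .6), u = c(.1, .2, .05),
                            N = 1e4, seed = 6)
  tab <- sample_table(sc)
  fit <- fit_ml(tab, options = quick_opts())
  res <- correlation_residuals(tab, fit)
  png1 <- withr::local_tempfile(fileext = ".png")
  plot_residuals(res, png1)
  expect_true(file.exists(png1) && file.size(png1) > 0)
  multi <- withr::local_tempfile(fileext = ".pdf")
  plot_residuals(list(`Model 0` = res, `Model I` = res), multi)
  expect_true(file.exists(multi) && file.size(multi) > 0)
  expect_error(plot_residuals(res, file.path(tempdir(), "x.svg")), "unsupported")
  # K = 1 has no pairs: axes-only plot, no error
  t1 <- agreement_table(c(70, 30), "f")
  f1 <- fit_ml(t1, options = quick_opts())
  empty <- correlation_residuals(t1, f1)
  expect_equal(nrow(empty), 0L)
  png0 <- withr::local_tempfile(fileext = ".png")
  plot_residuals(empty, png0)
  expect_true(file.exists(png0) && file.size(png0) > 0)
})
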