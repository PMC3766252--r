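test_that("fit_ml recovers the parameters of a well-separated CI scenario", {
  sc <- simulation_scenario(5, 0.05, m = c(.8, .7, .6, .75, .9),
                            u = c(.05, .1, .15, .02, .2), N = 2e5, seed = 42)
  tab <- sample_table(sc)
  fit <- fit_ml(tab, options = fit_options(seed = 1))
  expect_true(fit$converged)
  expect_equal(fit$classical$pi, 0.05, tolerance = 0.1)
  expect_equal(fit$classical$m, sc$m, tolerance = 0.05)
  expect_equal(fit$classical$u, sc$u, tolerance = 0.05)
  expect_true(sum(fit$classical$m) > sum(fit$classical$u))
})

test_that("fit is deterministic given table, spec and seed", {
  sc <- simulation_scenario(4, 0.08, m = c(.7, .8, .6, .75), u = c(.1, .05, .2, .1),
                            N = 5e4, seed = 9)
  tab <- sample_table(sc)
  f1 <- fit_ml(tab, options = quick_opts(seed = 31))
  f2 <- fit_ml(tab, options = quick_opts(seed = 31))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("degenerate fields are rejected before fitting", {
  tab <- agreement_table(c(10, 0, 5, 0), c("a", "b"))  # field b never agrees
  expect_error(fit_ml(tab), "degenerate field")
  expect_error(fit_ml(agreement_table(rep(0, 4), c("a", "b"))), "empty")
})

test_that("one-field fit saturates the observed agreement margin", {
  tab <- agreement_table(c(700, 300), "f")
  fit <- fit_ml(tab, options = quick_opts())
  P <- pattern_probabilities(fit$lambda, fit$spec)
  expect_equal(P[2], 0.3, tolerance = 1e-6)
})

test_that("EM log-likelihood trace is monotone and matches ML (CI and interactions)", {
  set.seed(77)
  scenarios <- list(
    simulation_scenario(3, 0.1, m = c(.8, .65, .7), u = c(.1, .2, .05), N = 2e4, seed = 1),
    simulation_scenario(4, 0.05, m = c(.7, .8, .6, .9), u = c(.05, .1, .2, .02),
                        interactions = list(list(j = 1, l = 3, gamma0 = 0.8, gamma1 = 1.1)),
                        N = 5e4, seed = 2),
    simulation_scenario(3, 0.15, m = c(.75, .7, .8), u = c(.1, .15, .1),
                        interactions = list(list(j = 2, l = 3, gamma0 = 0, gamma1 = 1.2)),
                        N = 3e4, seed = 3))
  for (sc in scenarios) {
    tab <- sample_table(sc)
    spec <- lclink:::scenario_spec(sc)
    fml <- fit_ml(tab, spec, quick_opts(seed = 5))
    fem <- fit_em(tab, spec, quick_opts(seed = 5, max_iter = 3000, tol = 1e-12))
    trace <- attr(fem, "ll_trace")
    expect_true(all(diff(trace) > -1e-7 * (abs(trace[-length(trace)]) + 1)))
    expect_equal(fem$loglik, fml$loglik,
                 tolerance = 1e-6 * abs(fml$loglik))
  }
})

test_that("label orientation is invariant to a swapped start", {
  sc <- simulation_scenario(3, 0.1, m = c(.8, .7, .75), u = c(.1, .15, .05),
                            N = 5e4, seed = 21)
  tab <- sample_table(sc)
  ref <- fit_ml(tab, options = quick_opts(seed = 1))
  # start the optimizer at the label-swapped mode: same likelihood, and the
  # reported orientation still satisfies sum(m) > sum(u)
  swapped <- lclink:::swap_theta(ref$theta, ref$spec)
  fit <- fit_ml(tab, options = fit_options(init = "user", init_theta = swapped,
                                           n_starts = 1, compute_se = FALSE))
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-8 * abs(ref$loglik))
  expect_true(sum(fit$classical$m) > sum(fit$classical$u))
  expect_equal(fit$classical$pi, ref$classical$pi, tolerance = 1e-4)
})

test_that("standard errors scale as 1/sqrt(N) and match Fisher expectations", {
  sc <- simulation_scenario(4, 0.1, m = c(.8, .7, .6, .75), u = c(.1, .05, .2, .15),
                            N = 1e5, seed = 3)
  tab1 <- sample_table(sc)
  fit1 <- fit_ml(tab1, options = fit_options(seed = 1))
  expect_true(all(unlist(fit1$se_classical) > 0))
  # identical pattern proportions at 4N -> SEs halve
  tab4 <- agreement_table(tab1$counts * 4, tab1$field_names)
  fit4 <- fit_ml(tab4, options = fit_options(seed = 1))
  ratio <- unlist(fit4$se_classical) / unlist(fit1$se_classical)
  expect_true(all(abs(ratio - 0.5) < 0.025))
})

test_that("standard errors agree with a bootstrap oracle", {
  sc <- simulation_scenario(3, 0.15, m = c(.8, .7, .75), u = c(.1, .2, .05),
                            N = 3e4, seed = 8)
  tab <- sample_table(sc)
  fit <- fit_ml(tab, options = fit_options(seed = 1))
  P <- tab$counts / tab$N
  set.seed(99)
  reps <- replicate(200, {
    counts <- as.vector(rmultinom(1, tab$N, P))
    bt <- agreement_table(counts, tab$field_names)
    f <- fit_ml(bt, options = quick_opts(n_starts = 1))
    c(f$classical$pi, f$classical$m, f$classical$u)
  })
  boot_se <- apply(reps, 1, sd)
  est_se <- c(fit$se_classical$pi, fit$se_classical$m, fit$se_classical$u)
  expect_true(all(abs(est_se / boot_se - 1) < 0.15))
})

test_that("singular information is reported with the offending parameters", {
  # K=2 CI model is over-parameterized for a 4-cell table -> flat direction
  tab <- toy_table_k2()
  fit <- fit_ml(tab, model_spec(2, field_names = tab$field_names), quick_opts())
  expect_error(standard_errors(fit, tab), "singular information")
})

test_that("adding an interaction never decreases the maximized log-likelihood", {
  sc <- simulation_scenario(4, 0.07, m = c(.7, .8, .6, .75), u = c(.1, .05, .15, .2),
                            N = 1e5, seed = 17)
  tab <- sample_table(sc)
  base <- fit_ml(tab, options = quick_opts(seed = 2))
  for (stt in c("match_only", "nonmatch_only", "both_distinct", "both_shared")) {
    spec <- model_spec(4, interaction_term(2, 4, stt), tab$field_names)
    ext <- fit_ml(tab, spec, quick_opts(seed = 2))
    expect_gte(ext$loglik, base$loglik - 1e-8 * abs(base$loglik))
  }
})
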