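test_that("noiseless three-exponential data is recovered essentially exactly", {
  acf <- gen_multiexp_acf(table1_model(), mixed_lag_grid(), noise_sd = 0)
  fit <- fit_multiexp(acf, 3)
  expect_true(fit$converged)
  expect_equal(fit$model$tau_ps, c(7, 419, 3400), tolerance = 1e-3 / 100)
  expect_equal(fit$model$a, c(0.37, 0.36, 0.27), tolerance = 1e-3)
  expect_equal(fit$dof, length(acf$lags_ps) - 5L)
})

test_that("a nested fit of single-exponential truth pushes the extra term to zero", {
  acf <- gen_multiexp_acf(rigid_model(5000), seq(0, 20000, 20), noise_sd = 0)
  fit <- fit_multiexp(acf, 2)
  k <- which.max(fit$model$a)
  expect_equal(fit$model$a[k], 1, tolerance = 1e-4)
  expect_equal(fit$model$tau_ps[k], 5000, tolerance = 5)
})

test_that("non-decaying input is flagged with tau at the upper bound", {
  acf <- acf_series(seq(0, 1000, 10), rep(1, 101))
  fit <- fit_multiexp(acf, 2)
  expect_false(fit$converged)
  expect_true("tau_at_upper_bound" %in% fit$flags)
})

test_that("F-ratio formula and edge cases match hand evaluation", {
  fake_fit <- function(ss, dof, n, n_points = 100L) {
    structure(list(model = rigid_model(1000), ss = ss, dof = dof,
                   n_points = n_points, n_requested = n, converged = TRUE,
                   collapsed = FALSE, flags = character(),
                   param_se = numeric()),
              class = "multiexp_fit")
  }
  cmp <- compare_models(fake_fit(10, 97, 2), fake_fit(8, 95, 3))
  expect_equal(cmp$f_ratio, (2 / 2) / (8 / 95), tolerance = 1e-12)
  expect_equal(cmp$f_ratio, 11.875, tolerance = 1e-12)
  expect_equal(cmp$p_value,
               pf(11.875, 2, 95, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(cmp$dof_numerator, 2L)

  # no improvement: F = 0
  cmp0 <- compare_models(fake_fit(10, 97, 2), fake_fit(10, 95, 3))
  expect_equal(cmp0$f_ratio, 0)
  expect_equal(cmp0$preferred_n, 2L)

  # larger model fitting worse is flagged, not an error
  expect_warning(cmpw <- compare_models(fake_fit(8, 97, 2), fake_fit(10, 95, 3)),
                 "worse")
  expect_equal(cmpw$f_ratio, 0)
  expect_true("larger_model_worse" %in% cmpw$flags)

  expect_error(compare_models(fake_fit(8, 95, 3), fake_fit(10, 97, 2)),
               "more free parameters")
  expect_error(compare_models(fake_fit(10, 97, 2),
                              fake_fit(8, 95, 3, n_points = 90L)),
               "same fitted points")
})

test_that("refitting noiseless two-exponential truth with n = 3 gives F ~ 0", {
  m2 <- build_multiexp_model(c(0.4, 0.6), c(50, 3000))
  acf <- gen_multiexp_acf(m2, mixed_lag_grid(), noise_sd = 0)
  sel <- select_model(acf, candidates = c(2, 3))
  expect_equal(sel$n_requested, 2L)
  expect_equal(sel$model$tau_ps, c(50, 3000), tolerance = 1e-3)
})

test_that("model selection prefers the generating model and honors alpha", {
  acf <- gen_multiexp_acf(table1_model(), mixed_lag_grid(), noise_sd = 0.005,
                          seed = 101)
  sel <- select_model(acf)
  expect_equal(sel$n_requested, 3L)
  trail <- attr(sel, "comparison_trail")
  expect_length(trail, 2L)
  expect_true(trail[[1]]$accepted)

  # alpha = 0 degenerates to the smallest candidate
  sel0 <- select_model(acf, alpha = 0)
  expect_equal(sel0$n_requested, 2L)
  expect_error(select_model(acf, alpha = 1), "alpha")
})

test_that("sum of squares is non-increasing in n under nested initialization", {
  acf <- gen_multiexp_acf(table1_model(), mixed_lag_grid(), noise_sd = 0.005,
                          seed = 55)
  sel <- select_model(acf)
  fits <- attr(sel, "all_fits")
  expect_lte(fits[["3"]]$ss, fits[["2"]]$ss + 1e-12)
  expect_lte(fits[["4"]]$ss, fits[["3"]]$ss + 1e-12)
})

test_that("noisy fits recover parameters within 10% for most seeded replicates", {
  # generating truth has taus separated by >= 10x; Gaussian noise sd 0.005
  ok <- 0L
  n_rep <- 40L
  for (s in seq_len(n_rep)) {
    acf <- gen_multiexp_acf(table1_model(), mixed_lag_grid(),
                            noise_sd = 0.005, seed = 1000L + s)
    fit <- fit_multiexp(acf, 3)
    if (fit$model$n == 3L &&
        all(abs(fit$model$tau_ps / c(7, 419, 3400) - 1) < 0.10) &&
        all(abs(fit$model$a - c(0.37, 0.36, 0.27)) < 0.10 * c(0.37, 0.36, 0.27)))
      ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("fit reports serialize with the comparison trail", {
  acf <- gen_multiexp_acf(table1_model(), mixed_lag_grid(), noise_sd = 0.005,
                          seed = 7)
  sel <- select_model(acf)
  p <- tempfile(fileext = ".json")
  write_fit_report(sel, p)
  rep <- jsonlite::read_json(p)
  expect_equal(rep$n, sel$model$n)
  expect_length(rep$a, sel$model$n)
  expect_equal(length(rep$f_trail), length(attr(sel, "comparison_trail")))
  unlink(p)
})
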