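test_that("synthetic ACFs are exact at zero noise and seed-reproducible", {
  m <- table1_model()
  grid <- seq(0, 10000, 50)
  a0 <- gen_multiexp_acf(m, grid, noise_sd = 0)
  expect_equal(a0$values, evaluate_acf_model(m, grid))
  a1 <- gen_multiexp_acf(m, grid, noise_sd = 0.01, seed = 5)
  a2 <- gen_multiexp_acf(m, grid, noise_sd = 0.01, seed = 5)
  expect_identical(a1$values, a2$values)
  expect_false(identical(a1$values,
                         gen_multiexp_acf(m, grid, 0.01, seed = 6)$values))
  # no noise is ever added at lag zero
  expect_equal(a1$values[1], 1)
})

test_that("rotational-diffusion generator honors its limits and guards", {
  tr0 <- gen_rotdiff_trajectory(0, 10, 100)
  expect_equal(compute_p2_acf(tr0, 500)$values, rep(1, 51))
  expect_identical(gen_rotdiff_trajectory(0.1, 10, 500, seed = 2)$vectors,
                   gen_rotdiff_trajectory(0.1, 10, 500, seed = 2)$vectors)
  # frames stay unit vectors
  tr <- gen_rotdiff_trajectory(0.05, 10, 500, seed = 2)
  expect_equal(sqrt(rowSums(tr$vectors^2)), rep(1, 500), tolerance = 1e-9)
  expect_warning(gen_rotdiff_trajectory(2, 10, 10), "coarse")
  expect_error(gen_rotdiff_trajectory(10, 10, 10), "too coarse")
})

test_that("empirical <P2> at lag 1/(6 D) sits near 1/e across seeds", {
  vals <- vapply(1:20, function(s) {
    tr <- gen_rotdiff_trajectory(1 / (6 * 0.5), 5, 4000, seed = s)
    a <- compute_p2_acf(tr, 600)
    a$values[a$lags_ps == 500]
  }, numeric(1))
  expect_lt(abs(mean(vals) - exp(-1)), 3 * sd(vals) / sqrt(20))
})

test_that("the cone generator collapses to free diffusion for a narrow cone", {
  # theta0 -> 0: internal motion frozen; decay is global tumbling alone.
  # average the ACF over 4 seeds (a single 80-tau record is noisy) and
  # compare the amplitude-weighted correlation time of the fit
  vals <- 0
  lags <- NULL
  for (s in 1:4) {
    tr <- gen_cone_tumbling_trajectory(0.5, 10, 1, 10, 8000, seed = s)
    a <- compute_p2_acf(tr, 3000)
    vals <- vals + a$values / 4
    lags <- a$lags_ps
  }
  am <- acf_series(lags, vals, traj_span_ps = 79990)
  f <- fit_multiexp(am, 2, options = list(window_ps = 3000))
  expect_equal(sum(f$model$a * f$model$tau_ps), 1000, tolerance = 0.2)
  expect_error(gen_cone_tumbling_trajectory(95, 10, 1, 10, 100), "90")
  expect_error(gen_cone_tumbling_trajectory(30, 2000, 1, 10, 100),
               "shorter")
})

test_that("the cone plateau tracks the closed-form order parameter", {
  s2_for <- function(theta_deg) {
    c0 <- cos(theta_deg * pi / 180)
    (c0 * (1 + c0) / 2)^2
  }
  # fast internal decay to a plateau, then slow tumbling: the slow-term
  # amplitude of a two-exponential fit estimates S^2
  slow_amp <- function(theta_deg, seed) {
    tr <- gen_cone_tumbling_trajectory(theta_deg, 50, 5, 10, 20000,
                                       seed = seed)
    f <- fit_multiexp(compute_p2_acf(tr, 20000), 2)
    f$model$a[f$model$n]
  }
  a30 <- slow_amp(30, 8)
  expect_equal(a30, s2_for(30), tolerance = 0.15)
  # wider cone, smaller order parameter
  a60 <- slow_amp(60, 8)
  expect_lt(a60, a30)
  expect_equal(a60, s2_for(60), tolerance = 0.4)
})

test_that("intensity decay tables use the standard schedules and round-trip", {
  t1 <- gen_intensity_decays(c(a = 2), kind = "R1")
  expect_equal(range(t1$delay_s), c(0.010, 0.640))
  t1r <- gen_intensity_decays(c(a = 8), kind = "R1rho")
  expect_equal(range(t1r$delay_s), c(0.010, 0.150))
  # zero noise: exact exponentials
  expect_equal(t1$intensity, 100 * exp(-2 * t1$delay_s))
  # round trip at 2% noise recovers rates within 2% on average
  rates <- seq(1, 4, length.out = 50)
  names(rates) <- as.character(1:50)
  tab <- gen_intensity_decays(rates, noise_frac = 0.02, kind = "R1",
                              seed = 23)
  rec <- vapply(split(tab, tab$residue), function(d)
    fit_decay(decay_curve(d$residue[1], d$delay_s, d$intensity),
              n_mc = 10)$R, numeric(1))
  expect_equal(mean(rec[names(rates)] / rates), 1, tolerance = 0.02)
})

test_that("residue ensembles honor their spec and keep ground truth", {
  # zero SDs: every residue is the mean model
  spec0 <- ensemble_spec(n_residues = 5, a_sd = c(0, 0, 0),
                         tau_sd_ps = c(0, 0, 0), rate_noise_frac = 0)
  ens0 <- gen_residue_ensemble(spec0)
  expect_length(ens0$models, 5L)
  for (m in ens0$models) expect_equal(m, table1_model())
  expect_equal(ens0$observed$R2, ens0$truth$R2)

  ens1 <- gen_residue_ensemble(ensemble_spec(n_residues = 20, seed = 12))
  ens2 <- gen_residue_ensemble(ensemble_spec(n_residues = 20, seed = 12))
  expect_identical(ens1$observed, ens2$observed)
  for (m in ens1$models) {
    expect_true(all(diff(m$tau_ps) > 0))
    expect_true(all(m$a > 0))
    expect_equal(sum(m$a), 1, tolerance = 1e-12)
  }
  # an infeasible spec (huge SDs force constant rejection) errors out
  expect_error(
    gen_residue_ensemble(ensemble_spec(n_residues = 5,
                                       a_sd = c(3, 3, 3),
                                       tau_sd_ps = c(5, 5, 5) * 1e4,
                                       seed = 1)),
    "infeasible")
})
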