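test_that("noiseless exponential decays are recovered exactly", {
  delays <- c(10, 20, 40, 80, 160, 320, 480, 640) / 1000
  cur <- decay_curve("12", delays, 100 * exp(-2 * delays))
  fit <- fit_decay(cur, n_mc = 50)
  expect_equal(fit$R, 2, tolerance = 1e-8)
  expect_equal(fit$I0, 100, tolerance = 1e-6)
  expect_true(fit$decaying)
})

test_that("flat intensities are flagged non-decaying", {
  cur <- decay_curve("1", c(0.01, 0.05, 0.2, 0.5), rep(50, 4))
  fit <- fit_decay(cur, n_mc = 10)
  expect_false(fit$decaying)
  expect_lt(abs(fit$R), 1e-4)
})

test_that("decay curves validate their inputs", {
  expect_error(decay_curve("1", c(0.01, 0.02), c(1, 2)), "3 distinct")
  expect_error(decay_curve("1", c(-0.01, 0.02, 0.05), c(1, 2, 3)),
               "non-negative")
  expect_error(decay_curve("1", c(0.01, 0.02, 0.05), c(1, 2)), "equal length")
})

test_that("decay fitting is scale-equivariant and seed-reproducible", {
  delays <- c(10, 30, 50, 70, 90, 110, 130, 150) / 1000
  set.seed(81)
  y <- 80 * exp(-6 * delays) * (1 + rnorm(8, 0, 0.02))
  f1 <- fit_decay(decay_curve("5", delays, y), seed = 42)
  fk <- fit_decay(decay_curve("5", delays, 3.5 * y), seed = 42)
  expect_equal(fk$R, f1$R, tolerance = 1e-9)
  expect_equal(fk$I0, 3.5 * f1$I0, tolerance = 1e-8)
  # Monte-Carlo uncertainties reproduce bit-for-bit under the same seed
  f2 <- fit_decay(decay_curve("5", delays, y), seed = 42)
  expect_identical(f1$R_se, f2$R_se)
  expect_identical(f1$I0_se, f2$I0_se)
  f3 <- fit_decay(decay_curve("5", delays, y), seed = 43)
  expect_false(identical(f1$R_se, f3$R_se))
})

test_that("Monte-Carlo sigma tracks the empirical spread of noisy refits", {
  delays <- c(10, 20, 40, 80, 160, 320, 480, 640) / 1000
  rs <- numeric(200)
  sigmas <- numeric(200)
  for (s in 1:200) {
    tab <- gen_intensity_decays(c(r1 = 3), i0s = 100, noise_frac = 0.02,
                                kind = "R1", seed = 9000 + s)
    f <- fit_decay(decay_curve("r1", tab$delay_s, tab$intensity),
                   n_mc = 100, seed = 1)
    rs[s] <- f$R
    sigmas[s] <- f$R_se
  }
  expect_equal(mean(rs), 3, tolerance = 0.01)
  emp <- sd(rs)
  expect_gt(mean(sigmas), emp / 1.5)
  expect_lt(mean(sigmas), emp * 1.5)
})

test_that("NOE ratios and their noise propagation match hand values", {
  expect_equal(noe_from_intensities(100, 100)$NOE, 1)
  expect_equal(noe_from_intensities(100, 100)$NOE_se, 0)
  expect_equal(noe_from_intensities(-50, 100)$NOE, -0.5)
  out <- noe_from_intensities(80, 100, 5, 5)
  expect_equal(out$NOE, 0.8)
  expect_equal(out$NOE_se, 0.8 * sqrt(0.0625^2 + 0.05^2), tolerance = 1e-12)
  expect_equal(out$NOE_se, 0.064, tolerance = 1e-3)
  expect_error(noe_from_intensities(80, 0), "zero")
})

test_that("residue tables join, convert R1rho and propagate errors", {
  mk_fit <- function(res, r, se, kind) {
    structure(list(residue = res, I0 = 100, R = r, I0_se = 1, R_se = se,
                   decaying = TRUE, kind = kind), class = "decay_fit")
  }
  r1 <- list(mk_fit("1", 1.2, 0.05, "R1"), mk_fit("2", 1.4, 0.04, "R1"))
  r1r <- list(mk_fit("1", 3.0, 0.10, "R1rho"), mk_fit("2", 3.5, 0.12, "R1rho"))
  noes <- data.frame(residue = "1", NOE = -0.2, NOE_se = 0.03)
  offs <- data.frame(residue = c("1", "2"), offset_hz = c(0, 1500))
  tab <- assemble_residue_table(r1, r1r, noes, offs, b_sl_hz = 1500)

  # on resonance: R2 = R1rho, sigma passes through
  expect_equal(tab$R2[tab$residue == "1"], 3.0)
  expect_equal(tab$R2_se[tab$residue == "1"], 0.10)
  # 45-degree tilt: R2 = (R1rho - R1/2) / (1/2)
  expect_equal(tab$R2[tab$residue == "2"], (3.5 - 1.4 * 0.5) / 0.5)
  # off-resonance error amplification: sigma_R2 >= sigma_R1rho / sin^2(theta)
  expect_gte(tab$R2_se[tab$residue == "2"], 0.12 / 0.5 - 1e-12)
  # outer join: missing NOE stays NA, everything else populated
  expect_true(is.na(tab$NOE[tab$residue == "2"]))
  expect_false(is.na(tab$R2[tab$residue == "2"]))

  expect_error(assemble_residue_table(c(r1, r1[1]), r1r, noes, offs),
               "duplicate")
})

test_that("a synthetic residue set round-trips through the primary pipeline", {
  set.seed(91)
  n_res <- 40
  true_r1 <- runif(n_res, 1.0, 2.2)
  true_r1rho <- runif(n_res, 2.0, 5.0)
  offsets <- data.frame(residue = as.character(1:n_res),
                        offset_hz = runif(n_res, -2000, 2000))
  b_sl <- 1500
  names(true_r1) <- names(true_r1rho) <- as.character(1:n_res)
  t1 <- gen_intensity_decays(true_r1, i0s = 100, noise_frac = 0.02,
                             kind = "R1", seed = 17)
  t1r <- gen_intensity_decays(true_r1rho, i0s = 100, noise_frac = 0.02,
                              kind = "R1rho", seed = 18)
  fits1 <- lapply(split(t1, t1$residue), function(d)
    fit_decay(decay_curve(d$residue[1], d$delay_s, d$intensity),
              n_mc = 100, seed = 2))
  fits1r <- lapply(split(t1r, t1r$residue), function(d)
    fit_decay(decay_curve(d$residue[1], d$delay_s, d$intensity,
                          kind = "R1rho"), n_mc = 100, seed = 2))
  tab <- assemble_residue_table(fits1, fits1r, NULL, offsets, b_sl)
  # ground-truth R2 through the same tilted-frame geometry
  th <- ifelse(offsets$offset_hz == 0, pi / 2,
               atan(abs(b_sl / offsets$offset_hz)))
  true_r2 <- (true_r1rho[offsets$residue] -
                true_r1[offsets$residue] * cos(th)^2) / sin(th)^2
  m <- match(tab$residue, offsets$residue)
  within3 <- abs(tab$R2 - true_r2[m]) <= 3 * tab$R2_se
  expect_gte(mean(within3), 0.9)
  expect_equal(unname(cor(tab$R2, true_r2[m])), 1, tolerance = 0.05)
})
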