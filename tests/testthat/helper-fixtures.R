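# shared fixtures: the ensemble-average three-exponential model of
# disordered-protein backbone dynamics, and the 600 MHz spin system
table1_model <- function() {
  build_multiexp_model(c(0.37, 0.36, 0.27), c(7, 419, 3400))
}

spin600 <- function(...) spin_system(600, ...)

# lag grid dense at short lags (resolves the 7 ps component), coarser out
# to 20 ns; used by the fitting and selection tests
mixed_lag_grid <- function() {
  c(0:20, seq(25, 100, 5), seq(110, 1000, 10), seq(1050, 20000, 50))
}

# independent oracle for J(omega): trapezoid cosine transform of the model
# ACF, lag cutoff 50 * tau_max, on a piecewise grid fine enough for the
# fastest still-alive exponential and for the cosine oscillation
numeric_spectral_density <- function(model, omega) {
  taus <- model$tau_ps * 1e-12
  t_max <- 50 * max(taus)
  bounds <- sort(unique(c(0, pmin(40 * taus, t_max), t_max)))
  vapply(omega, function(w) {
    total <- 0
    for (k in seq_len(length(bounds) - 1L)) {
      alive <- taus[40 * taus > bounds[k] * (1 + 1e-12)]
      dt <- (if (length(alive)) min(alive) else min(taus)) / 100
      if (w > 0) dt <- min(dt, 0.005 / w)
      tt <- seq(bounds[k], bounds[k + 1L], by = dt)
      if (tt[length(tt)] < bounds[k + 1L]) tt <- c(tt, bounds[k + 1L])
      y <- evaluate_acf_model(model, tt * 1e12) * cos(w * tt)
      total <- total + sum(diff(tt) * (y[-1] + y[-length(y)]) / 2)
    }
    (2 / 5) * total
  }, numeric(1))
}

# rate formulas applied to an arbitrary J function (oracle route)
rates_from_j_fn <- function(j_fn, constants) {
  wh <- constants$omega_h
  wn <- abs(constants$omega_n)
  j <- c(zero = j_fn(0), wn = j_fn(wn), wh_minus_wn = j_fn(wh - wn),
         wh = j_fn(wh), wh_plus_wn = j_fn(wh + wn))
  d2 <- constants$d^2
  c2 <- constants$c^2
  r1 <- (d2 / 4) * (j[["wh_minus_wn"]] + 3 * j[["wn"]] +
                      6 * j[["wh_plus_wn"]]) + c2 * j[["wn"]]
  r2 <- (d2 / 8) * (4 * j[["zero"]] + j[["wh_minus_wn"]] + 3 * j[["wn"]] +
                      6 * j[["wh"]] + 6 * j[["wh_plus_wn"]]) +
    (c2 / 6) * (4 * j[["zero"]] + 3 * j[["wn"]])
  noe <- 1 + (constants$gamma_h / constants$gamma_n) * (d2 / 4) *
    (6 * j[["wh_plus_wn"]] - j[["wh_minus_wn"]]) / r1
  list(R1 = r1, R2 = r2, NOE = noe)
}

# random valid model on well-separated timescales, for property loops
random_model <- function(n = 3) {
  a <- stats::runif(n, 0.05, 1)
  a <- a / sum(a)
  tau <- sort(exp(stats::runif(n, log(1), log(2e4))))
  build_multiexp_model(a, tau)
}
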