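#' Spin-system constants for 15N relaxation
#'
#' Collects the field and spin parameters that turn a spectral density into
#' 15N relaxation rates: gyromagnetic ratios, N-H bond length, 15N chemical
#' shift anisotropy (CSA) and the proton Larmor frequency. The defaults are
#' the values conventionally used in amide 15N model-free analysis
#' (gamma_H = 2.6752218744e8, gamma_N = -2.71261804e7 rad s^-1 T^-1,
#' r_NH = 1.02 A, CSA = -172 ppm) at a 600 MHz proton frequency.
#'
#' Derived quantities: angular frequencies `omega_h` and `omega_n = omega_h *
#' gamma_n / gamma_h` (signed; rate formulas use magnitudes, J is even), the
#' dipolar constant \eqn{d = (\mu_0/4\pi)\,\hbar\,\gamma_H |\gamma_N| /
#' r_{NH}^3} and the CSA constant \eqn{c = |\omega_N| |\Delta\sigma| /
#' \sqrt{3}}, both in rad/s (they enter the rates squared).
#'
#' @param field_mhz proton Larmor frequency in MHz.
#' @param r_nh_angstrom N-H bond length in Angstrom.
#' @param csa_ppm 15N chemical shift anisotropy in ppm.
#' @param gamma_h,gamma_n gyromagnetic ratios in rad s^-1 T^-1.
#' @return An object of class `spin_system`.
#' @examples
#' ss <- spin_system(600)
#' ss$omega_n / ss$omega_h  # = gamma_n / gamma_h
#' @export
spin_system <- function(field_mhz = 600, r_nh_angstrom = 1.02,
                        csa_ppm = -172, gamma_h = 2.6752218744e8,
                        gamma_n = -2.71261804e7) {
  stopifnot(field_mhz > 0, r_nh_angstrom > 0)
  mu0_over_4pi <- 1e-7      # T m / A
  hbar <- 1.054571817e-34   # J s
  omega_h <- 2 * pi * field_mhz * 1e6
  omega_n <- omega_h * gamma_n / gamma_h
  r <- r_nh_angstrom * 1e-10
  d <- mu0_over_4pi * hbar * gamma_h * abs(gamma_n) / r^3
  cc <- abs(omega_n) * abs(csa_ppm) * 1e-6 / sqrt(3)
  structure(list(field_mhz = field_mhz, gamma_h = gamma_h, gamma_n = gamma_n,
                 r_nh_angstrom = r_nh_angstrom, csa_ppm = csa_ppm,
                 omega_h = omega_h, omega_n = omega_n, d = d, c = cc),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("15N spin system at %.6g MHz (r_NH = %.3g A, CSA = %.4g ppm)\n",
              x$field_mhz, x$r_nh_angstrom, x$csa_ppm))
  invisible(x)
}

# frequencies (rad/s, magnitudes) at which J is sampled for amide 15N rates
rate_frequencies <- function(constants) {
  wh <- constants$omega_h
  wn <- abs(constants$omega_n)
  c(zero = 0, wn = wn, wh_minus_wn = wh - wn, wh = wh, wh_plus_wn = wh + wn)
}

relaxation_from_j <- function(j, constants) {
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

#' Back-calculate 15N R1, R2 and NOE from a dynamic model
#'
#' Evaluates the standard dipolar + CSA expressions for amide 15N relaxation
#' from the analytic spectral density of a multi-exponential model:
#' \deqn{R_1 = (d^2/4)[J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H+\omega_N)] + c^2 J(\omega_N)}
#' \deqn{R_2 = (d^2/8)[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H) + 6J(\omega_H+\omega_N)] + (c^2/6)[4J(0) + 3J(\omega_N)]}
#' \deqn{NOE = 1 + (\gamma_H/\gamma_N)(d^2/4)[6J(\omega_H+\omega_N) -
#'   J(\omega_H-\omega_N)]/R_1.}
#' No chemical-exchange (Rex) contribution is included.
#'
#' @param model a `multiexp_model`.
#' @param constants a [spin_system()].
#' @return An object of class `relaxation_triple`: list with `R1`, `R2`
#'   (s^-1) and `NOE` (dimensionless).
#' @examples
#' m <- build_multiexp_model(c(0.37, 0.63), c(7, 3400))
#' relaxation_rates(m, spin_system(600))
#' @export
relaxation_rates <- function(model, constants = spin_system()) {
  stopifnot(inherits(model, "multiexp_model"), inherits(constants, "spin_system"))
  j <- spectral_density(model, rate_frequencies(constants))
  names(j) <- names(rate_frequencies(constants))
  if (any(!is.finite(j))) stop("non-finite spectral density")
  out <- relaxation_from_j(j, constants)
  structure(out, class = "relaxation_triple")
}

#' @export
print.relaxation_triple <- function(x, ...) {
  cat(sprintf("R1 = %.4g s^-1, R2 = %.4g s^-1, NOE = %.4g\n",
              x$R1, x$R2, x$NOE))
  invisible(x)
}

#' Rotating-frame experiment geometry
#'
#' Spin-lock field and resonance offset defining the effective-field tilt
#' angle theta with tan(theta) = B_SL / offset; on resonance (zero offset)
#' theta = pi/2.
#'
#' @param b_sl_hz spin-lock field strength in Hz (positive).
#' @param offset_hz resonance offset from the carrier in Hz (sign ignored
#'   for the tilt angle).
#' @return An object of class `rotating_frame` with `b_sl_hz`, `offset_hz`
#'   and `theta` (radians, in (0, pi/2]).
#' @export
rotating_frame <- function(b_sl_hz, offset_hz) {
  if (b_sl_hz <= 0) stop("'b_sl_hz' must be positive")
  theta <- if (offset_hz == 0) pi / 2 else atan(abs(b_sl_hz / offset_hz))
  structure(list(b_sl_hz = b_sl_hz, offset_hz = offset_hz, theta = theta),
            class = "rotating_frame")
}

#' Convert a rotating-frame rate to R2
#'
#' Inverts the tilted-frame mixing relation \eqn{R_{1\rho} = R_1\cos^2\theta
#' + R_2\sin^2\theta} to recover the transverse rate:
#' \deqn{R_2 = (R_{1\rho} - R_1\cos^2\theta)/\sin^2\theta,}
#' with the tilt angle from the spin-lock field and the per-residue
#' resonance offset. On resonance this is the identity R2 = R1rho. A
#' negative result is unphysical (noise or mis-set offset) and is returned
#' with a warning.
#'
#' @param r1rho rotating-frame rate in s^-1 (positive).
#' @param r1 longitudinal rate in s^-1 (positive).
#' @param settings a [rotating_frame()].
#' @return R2 in s^-1.
#' @export
r2_from_r1rho <- function(r1rho, r1, settings) {
  stopifnot(inherits(settings, "rotating_frame"))
  if (any(r1rho <= 0) || any(r1 <= 0)) stop("rates must be positive")
  s2 <- sin(settings$theta)^2
  if (s2 <= 0) stop("tilt angle of 0 (infinite offset): R2 undefined")
  r2 <- (r1rho - r1 * cos(settings$theta)^2) / s2
  if (any(r2 < 0)) warning("negative R2 after off-resonance correction (unphysical)")
  r2
}

#' Estimate the rigid-rotor tumbling time from R2/R1
#'
#' Solves for the isotropic tumbling time tau_m at which a rigid rotor
#' (single-exponential correlation function, order parameter 1) reproduces
#' the observed R2/R1 ratio at the stated field. Outside extreme narrowing
#' the ratio is strictly increasing in tau_m, so the root on the bracket
#' [0.05, 200] ns is unique. Ratios at or below the extreme-narrowing floor
#' carry no tumbling information and raise an error reporting the floor.
#'
#' @param r1,r2 observed rates in s^-1.
#' @param constants a [spin_system()].
#' @return An object of class `tumbling_estimate`: list with `tau_m_ns`, the
#'   solver `bracket_ns` and the `residual` of the ratio match.
#' @examples
#' rr <- relaxation_rates(rigid_model(4300), spin_system(600))
#' estimate_tauc(rr$R1, rr$R2)$tau_m_ns  # recovers 4.3 ns
#' @export
estimate_tauc <- function(r1, r2, constants = spin_system()) {
  stopifnot(r1 > 0, r2 > 0)
  bracket <- c(0.05, 200)
  ratio_obs <- r2 / r1
  f <- function(tau_ns) {
    rr <- relaxation_rates(rigid_model(tau_ns * 1000), constants)
    rr$R2 / rr$R1 - ratio_obs
  }
  f_lo <- f(bracket[1])
  if (f_lo >= 0)
    stop(sprintf(paste0("R2/R1 = %.4g is at or below the extreme-narrowing ",
                        "floor %.4g at %.6g MHz; no tumbling-time solution"),
                 ratio_obs, ratio_obs + f_lo, constants$field_mhz))
  if (f(bracket[2]) <= 0)
    stop("R2/R1 exceeds the rigid-rotor ratio at the 200 ns bracket edge")
  root <- stats::uniroot(f, interval = bracket, tol = 1e-10)
  structure(list(tau_m_ns = root$root, bracket_ns = bracket,
                 residual = abs(root$f.root)),
            class = "tumbling_estimate")
}

#' @export
print.tumbling_estimate <- function(x, ...) {
  cat(sprintf("Rigid-rotor tumbling time: %.4g ns\n", x$tau_m_ns))
  invisible(x)
}
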