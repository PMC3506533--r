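#' Multi-exponential autocorrelation model
#'
#' Construct a normalized multi-exponential model of a rank-2 bond-vector
#' autocorrelation function,
#' \deqn{C(t) = \sum_{i=1}^{n} a_i \exp(-t/\tau_i),}
#' the "LS-n" decomposition of backbone amide dynamics into motions on n
#' timescales (for n = 3: fast librational, intermediate segmental, and slow
#' tumbling-like components).
#'
#' Amplitudes must be non-negative and sum to 1 (within `1e-6`; they are then
#' rescaled to sum to 1 exactly), because the normalized rank-2
#' autocorrelation satisfies C(0) = 1. Terms are stored sorted by ascending
#' correlation time; terms whose correlation times agree within `1e-6`
#' relative are merged (their amplitudes summed), which leaves C(t)
#' unchanged.
#'
#' @param amps numeric vector of 2-4 amplitudes \eqn{a_i} (dimensionless).
#' @param taus numeric vector of correlation times \eqn{\tau_i} in ps, same
#'   length as `amps`, all positive.
#' @return An object of class `multiexp_model`: a list with elements `a`
#'   (amplitudes), `tau_ps` (correlation times, ascending) and `n` (number of
#'   terms).
#' @examples
#' m <- build_multiexp_model(c(0.37, 0.36, 0.27), c(7, 419, 3400))
#' evaluate_acf_model(m, c(0, 419))
#' @seealso [rigid_model()] for the single-exponential (rigid rotor) case,
#'   [evaluate_acf_model()], [spectral_density()], [fit_multiexp()].
#' @export
build_multiexp_model <- function(amps, taus) {
  if (length(amps) != length(taus))
    stop("'amps' and 'taus' must have equal length")
  if (length(amps) < 2L || length(amps) > 4L)
    stop("a multi-exponential model has 2-4 terms; ",
         "use rigid_model() for a single-exponential model")
  new_multiexp_model(amps, taus)
}

#' Rigid-rotor (single-exponential) model
#'
#' A one-term model C(t) = exp(-t/tau_m) describing isotropic rigid-body
#' tumbling with correlation time tau_m. Single-term models are deliberately
#' excluded from [build_multiexp_model()] (they cannot be fitted by
#' [fit_multiexp()]); this constructor is the explicit opt-in used for
#' rigid-rotor rate calculations and tumbling-time estimation.
#'
#' @param tau_ps tumbling correlation time in ps (scalar, positive).
#' @return A `multiexp_model` with a single term of amplitude 1.
#' @examples
#' rigid_model(4300)  # 4.3 ns tumbling
#' @export
rigid_model <- function(tau_ps) {
  if (length(tau_ps) != 1L || !is.finite(tau_ps) || tau_ps <= 0)
    stop("'tau_ps' must be a single positive number")
  new_multiexp_model(1, tau_ps)
}

# internal constructor: validates, normalizes, sorts, merges duplicate taus
new_multiexp_model <- function(amps, taus) {
  amps <- as.numeric(amps)
  taus <- as.numeric(taus)
  if (anyNA(amps) || anyNA(taus) || any(!is.finite(c(amps, taus))))
    stop("amplitudes and correlation times must be finite")
  if (any(amps < 0)) stop("amplitudes must be non-negative")
  if (any(taus <= 0)) stop("correlation times must be positive")
  s <- sum(amps)
  if (abs(s - 1) > 1e-6)
    stop(sprintf("amplitudes must sum to 1 (got %.8g); C(0) = 1 for a %s",
                 s, "normalized rank-2 autocorrelation"))
  amps <- amps / s
  ord <- order(taus)
  amps <- amps[ord]
  taus <- taus[ord]
  # merge terms with (near-)identical correlation times: C(t) is unchanged
  if (length(taus) > 1L) {
    keep_a <- amps[1]
    keep_t <- taus[1]
    for (k in 2:length(taus)) {
      last <- length(keep_t)
      if (taus[k] / keep_t[last] - 1 < 1e-6) {
        keep_a[last] <- keep_a[last] + amps[k]
      } else {
        keep_a <- c(keep_a, amps[k])
        keep_t <- c(keep_t, taus[k])
      }
    }
    amps <- keep_a
    taus <- keep_t
  }
  structure(list(a = amps, tau_ps = taus, n = length(amps)),
            class = "multiexp_model")
}

#' @export
print.multiexp_model <- function(x, ...) {
  cat(sprintf("Multi-exponential ACF model (n = %d)\n", x$n))
  for (i in seq_len(x$n))
    cat(sprintf("  a%-2d = %-8.4f tau%-2d = %.6g ps\n", i, x$a[i], i,
                x$tau_ps[i]))
  invisible(x)
}

#' Evaluate a multi-exponential autocorrelation model
#'
#' Computes \eqn{C(t) = \sum_i a_i \exp(-t/\tau_i)} at the requested lag
#' times. By construction `C(0) = 1`.
#'
#' @param model a `multiexp_model`.
#' @param lags_ps numeric vector of lag times in ps, all non-negative.
#' @return numeric vector of correlation values, same length as `lags_ps`.
#' @export
evaluate_acf_model <- function(model, lags_ps) {
  stopifnot(inherits(model, "multiexp_model"))
  lags_ps <- as.numeric(lags_ps)
  if (any(lags_ps < 0)) stop("lag times must be non-negative")
  drop(exp(-outer(lags_ps, 1 / model$tau_ps)) %*% model$a)
}

#' Analytic spectral density of a multi-exponential model
#'
#' The cosine transform of C(t) for a sum of exponentials is a sum of
#' Lorentzians. With the conventional 2/5 normalization for rank-2
#' reorientation,
#' \deqn{J(\omega) = \frac{2}{5} \sum_i \frac{a_i \tau_i}
#'   {1 + (\omega \tau_i)^2},}
#' with \eqn{\tau_i} in seconds, so that the rigid-rotor limit gives
#' \eqn{J(0) = (2/5)\tau_m}. Model correlation times are stored in ps and
#' converted internally.
#'
#' @param model a `multiexp_model`.
#' @param omega angular frequency (or vector of frequencies) in rad/s,
#'   non-negative.
#' @return J(omega) in seconds (s/rad), same length as `omega`.
#' @examples
#' m <- build_multiexp_model(c(0.37, 0.36, 0.27), c(7, 419, 3400))
#' spectral_density(m, 0)  # (2/5) * sum(a * tau) = 4.286e-10 s
#' @export
spectral_density <- function(model, omega) {
  stopifnot(inherits(model, "multiexp_model"))
  omega <- as.numeric(omega)
  if (any(omega < 0)) stop("angular frequencies must be non-negative")
  tau_s <- model$tau_ps * 1e-12
  drop((2 / 5) * (outer(omega^2, tau_s^2, function(w2, t2) 1 / (1 + w2 * t2)) %*%
                    (model$a * tau_s)))
}
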