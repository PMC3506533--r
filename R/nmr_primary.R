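#' Peak-intensity decay curve
#'
#' Per-residue peak intensities versus relaxation delay for a longitudinal
#' (R1) or rotating-frame (R1rho) experiment. Replicate measurements at a
#' delay are kept as independent points.
#'
#' @param residue residue label (opaque string).
#' @param delays_s relaxation delays in seconds, non-negative; at least 3
#'   distinct values.
#' @param intensities peak intensities (arbitrary units), same length.
#' @param kind `"R1"` or `"R1rho"`.
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(residue, delays_s, intensities,
                        kind = c("R1", "R1rho")) {
  kind <- match.arg(kind)
  delays_s <- as.numeric(delays_s)
  intensities <- as.numeric(intensities)
  if (length(delays_s) != length(intensities))
    stop("'delays_s' and 'intensities' must have equal length")
  if (any(delays_s < 0)) stop("delays must be non-negative")
  if (length(unique(delays_s)) < 3L)
    stop("need at least 3 distinct delays")
  structure(list(residue = as.character(residue), delays_s = delays_s,
                 intensities = intensities, kind = kind),
            class = "decay_curve")
}

#' Two-parameter exponential fit of an intensity decay
#'
#' Least-squares fit of \eqn{I(t) = I_0 \exp(-R t)} to the peak intensities
#' of one residue. Parameter uncertainties are estimated by seeded Monte
#' Carlo: the residual standard deviation of the fit is used to perturb the
#' fitted curve `n_mc` times and the spread of the refitted parameters is
#' reported (covariance-matrix standard errors are available with
#' `method = "covariance"`).
#'
#' A non-decaying curve (fitted R <= 0) is flagged, not silently returned.
#'
#' @param curve a [decay_curve()].
#' @param n_mc number of Monte-Carlo resamples (default 500).
#' @param seed RNG seed for the resampling (default 1).
#' @param method `"montecarlo"` (default) or `"covariance"`.
#' @return An object of class `decay_fit`: list with `residue`, `I0`, `R`
#'   (s^-1), `I0_se`, `R_se`, `decaying` (flag), `kind`.
#' @export
fit_decay <- function(curve, n_mc = 500L, seed = 1L,
                      method = c("montecarlo", "covariance")) {
  stopifnot(inherits(curve, "decay_curve"))
  method <- match.arg(method)
  t <- curve$delays_s
  y <- curve$intensities
  est <- exp_fit_core(t, y)
  res <- y - est$I0 * exp(-est$R * t)
  dof <- max(length(y) - 2L, 1L)
  sigma <- sqrt(sum(res^2) / dof)
  if (method == "covariance") {
    se <- exp_fit_cov_se(t, est, sigma)
    i0_se <- se[1]
    r_se <- se[2]
  } else {
    yhat <- est$I0 * exp(-est$R * t)
    draws <- with_seed_local(seed, {
      vapply(seq_len(n_mc), function(b) {
        eb <- exp_fit_core(t, yhat + stats::rnorm(length(t), 0, sigma))
        c(eb$I0, eb$R)
      }, numeric(2))
    })
    i0_se <- stats::sd(draws[1, ])
    r_se <- stats::sd(draws[2, ])
  }
  structure(list(residue = curve$residue, I0 = est$I0, R = est$R,
                 I0_se = i0_se, R_se = r_se,
                 decaying = est$R > 0, kind = curve$kind),
            class = "decay_fit")
}

# Gauss-Newton on (I0, R) with a log-linear start; robust to R ~ 0
exp_fit_core <- function(t, y) {
  pos <- y > 0
  if (sum(pos) >= 2L) {
    co <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
    start <- c(exp(co[1]), max(-co[2], 1e-6))
  } else {
    start <- c(max(abs(y)), 1)
  }
  fit <- minpack.lm::nls.lm(
    par = c(I0 = unname(start[1]), R = unname(start[2])),
    fn = function(p) y - p[1] * exp(-p[2] * t),
    jac = function(p) cbind(-exp(-p[2] * t), p[1] * t * exp(-p[2] * t)),
    control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-13,
                                         ftol = 1e-13))
  list(I0 = fit$par[[1]], R = fit$par[[2]])
}

exp_fit_cov_se <- function(t, est, sigma) {
  J <- cbind(exp(-est$R * t), -est$I0 * t * exp(-est$R * t))
  V <- tryCatch(solve(crossprod(J)) * sigma^2, error = function(e) NULL)
  if (is.null(V)) return(c(NA_real_, NA_real_))
  sqrt(pmax(diag(V), 0))
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Steady-state NOE from saturated/reference intensities
#'
#' NOE = I_sat / I_ref, with the uncertainty propagated from the
#' background-noise levels of the two spectra:
#' \deqn{\sigma_{NOE} = |NOE| \sqrt{(\sigma_{sat}/I_{sat})^2 +
#'   (\sigma_{ref}/I_{ref})^2}.}
#' Negative NOEs are passed through (they are expected for flexible IDP
#' residues).
#'
#' @param i_sat,i_ref peak intensities with and without proton saturation.
#' @param noise_sat,noise_ref background noise levels of the two spectra.
#' @return list with `NOE` and `NOE_se`.
#' @export
noe_from_intensities <- function(i_sat, i_ref, noise_sat = 0, noise_ref = 0) {
  if (any(i_ref == 0)) stop("reference intensity is zero")
  noe <- i_sat / i_ref
  se <- abs(noe) * sqrt((noise_sat / i_sat)^2 + (noise_ref / i_ref)^2)
  list(NOE = noe, NOE_se = se)
}

#' Assemble a per-residue relaxation table
#'
#' Joins R1 fits, R1rho fits, NOE values and per-residue resonance offsets
#' into one record per residue, converting R1rho to R2 through the
#' tilted-frame relation with that residue's offset and propagating the R2
#' uncertainty to first order:
#' \deqn{\sigma_{R_2}^2 = (\sigma_{R_{1\rho}}/\sin^2\theta)^2 +
#'   (\sigma_{R_1}\cos^2\theta/\sin^2\theta)^2.}
#' The join is outer: residues missing from one input get `NA` in the
#' corresponding fields. Duplicate residue keys within one input are an
#' error.
#'
#' @param r1_fits list of `decay_fit` objects from R1 experiments.
#' @param r1rho_fits list of `decay_fit` objects from R1rho experiments.
#' @param noes data.frame with columns `residue`, `NOE`, `NOE_se` (may be
#'   `NULL`).
#' @param offsets_hz data.frame with columns `residue`, `offset_hz`.
#' @param b_sl_hz spin-lock field in Hz (default 1500).
#' @return data.frame with columns `residue`, `R1`, `R1_se`, `R1rho`,
#'   `R1rho_se`, `R2`, `R2_se`, `NOE`, `NOE_se`, `offset_hz`, `b_sl_hz`.
#' @export
assemble_residue_table <- function(r1_fits, r1rho_fits, noes = NULL,
                                   offsets_hz = NULL, b_sl_hz = 1500) {
  fit_df <- function(fits, prefix) {
    if (!length(fits)) return(NULL)
    keys <- vapply(fits, function(f) f$residue, character(1))
    if (anyDuplicated(keys))
      stop(sprintf("duplicate residue keys in %s fits", prefix))
    d <- data.frame(residue = keys,
                    R = vapply(fits, function(f) f$R, numeric(1)),
                    R_se = vapply(fits, function(f) f$R_se, numeric(1)))
    names(d)[2:3] <- c(prefix, paste0(prefix, "_se"))
    d
  }
  d1 <- fit_df(r1_fits, "R1")
  d1r <- fit_df(r1rho_fits, "R1rho")
  if (is.null(d1) && is.null(d1r)) stop("no decay fits supplied")
  if (is.null(d1))
    d1 <- data.frame(residue = character(), R1 = numeric(),
                     R1_se = numeric())
  if (is.null(d1r))
    d1r <- data.frame(residue = character(), R1rho = numeric(),
                      R1rho_se = numeric())
  out <- merge(d1, d1r, by = "residue", all = TRUE)
  if (!is.null(noes)) {
    if (anyDuplicated(noes$residue)) stop("duplicate residue keys in NOE table")
    out <- merge(out, noes[, c("residue", "NOE", "NOE_se")],
                 by = "residue", all = TRUE)
  } else {
    out$NOE <- NA_real_
    out$NOE_se <- NA_real_
  }
  if (!is.null(offsets_hz)) {
    if (anyDuplicated(offsets_hz$residue))
      stop("duplicate residue keys in offset table")
    out <- merge(out, offsets_hz[, c("residue", "offset_hz")],
                 by = "residue", all = TRUE)
  } else {
    out$offset_hz <- 0
  }
  out$b_sl_hz <- b_sl_hz
  out$R2 <- NA_real_
  out$R2_se <- NA_real_
  ok <- !is.na(out$R1) & !is.na(out$R1rho) & !is.na(out$offset_hz)
  for (i in which(ok)) {
    rf <- rotating_frame(b_sl_hz, out$offset_hz[i])
    s2 <- sin(rf$theta)^2
    c2 <- cos(rf$theta)^2
    out$R2[i] <- r2_from_r1rho(out$R1rho[i], out$R1[i], rf)
    out$R2_se[i] <- sqrt((out$R1rho_se[i] / s2)^2 +
                           (out$R1_se[i] * c2 / s2)^2)
  }
  out[order(suppressWarnings(as.numeric(out$residue)), out$residue), ,
      drop = FALSE]
}
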