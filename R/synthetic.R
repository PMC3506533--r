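#' Synthetic multi-exponential autocorrelation series
#'
#' Evaluates a model on a lag grid and adds i.i.d. Gaussian noise (none at
#' lag 0, which is pinned to 1 for a normalized autocorrelation).
#' Bit-reproducible under a fixed seed.
#'
#' @param model a `multiexp_model`.
#' @param lag_grid_ps lag grid in ps, strictly increasing from 0.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed RNG seed.
#' @return An [acf_series()].
#' @export
gen_multiexp_acf <- function(model, lag_grid_ps, noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  vals <- evaluate_acf_model(model, lag_grid_ps)
  if (noise_sd > 0) {
    eps <- with_seed_local(seed, stats::rnorm(length(vals), 0, noise_sd))
    eps[lag_grid_ps == 0] <- 0
    vals <- vals + eps
  }
  acf_series(lag_grid_ps, vals, noise_tol = 0.05 + 10 * noise_sd)
}

#' Simulated isotropic rotational-diffusion trajectory
#'
#' Small-step Brownian rotational diffusion of a unit vector: at each step
#' the vector is rotated about a uniformly random axis in its perpendicular
#' plane by a Gaussian angle of variance \eqn{4 D_r \Delta t} (the mean
#' square angular displacement of a direction diffusing on the sphere). In
#' the small-step limit the rank-2 autocorrelation is exactly
#' \eqn{C_2(t) = \exp(-6 D_r t)}, i.e. a single-exponential decay with
#' correlation time \eqn{1/(6 D_r)}.
#'
#' Step-size guard: a warning above \eqn{6 D_r \Delta t > 0.1}, an error
#' above 0.5, where the discretization is no longer faithful.
#'
#' @param d_r_ns rotational diffusion coefficient in ns^-1.
#' @param timestep_ps frame spacing in ps.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return A [vector_trajectory()].
#' @export
gen_rotdiff_trajectory <- function(d_r_ns, timestep_ps, n_frames, seed = 1L) {
  if (d_r_ns < 0) stop("'d_r_ns' must be non-negative")
  step <- 6 * (d_r_ns / 1000) * timestep_ps
  if (step > 0.5) stop("timestep too coarse: 6*D_r*dt > 0.5")
  if (step > 0.1) warning("coarse timestep: 6*D_r*dt > 0.1")
  v0 <- c(0, 0, 1)
  if (d_r_ns == 0)
    return(vector_trajectory(matrix(v0, n_frames, 3, byrow = TRUE),
                             timestep_ps))
  sd_ang <- sqrt(4 * (d_r_ns / 1000) * timestep_ps)
  V <- with_seed_local(seed, {
    out <- matrix(0, n_frames, 3)
    v <- v0
    out[1, ] <- v
    for (i in 2:n_frames) {
      v <- rotate_about_random_perp(v, stats::rnorm(1, 0, sd_ang),
                                    stats::runif(1, 0, 2 * pi))
      out[i, ] <- v
    }
    out
  })
  vector_trajectory(V, timestep_ps)
}

# rotate unit vector v by 'angle' about a unit axis in its perpendicular
# plane at azimuth 'phi' (Rodrigues; axis _|_ v so v.axis = 0)
rotate_about_random_perp <- function(v, angle, phi) {
  # orthonormal basis of the plane perpendicular to v
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  k <- cos(phi) * e1 + sin(phi) * e2
  kxv <- c(k[2] * v[3] - k[3] * v[2],
           k[3] * v[1] - k[1] * v[3],
           k[1] * v[2] - k[2] * v[1])
  w <- v * cos(angle) + kxv * sin(angle)
  w / sqrt(sum(w^2))
}

#' Simulated wobble-in-cone plus tumbling trajectory
#'
#' Two-timescale fixture: a bond vector diffuses inside a cone of half-angle
#' `cone_half_angle_deg` (reflecting boundary) fixed in a molecular frame
#' that itself tumbles isotropically with correlation time `tau_global_ns`.
#' The lab-frame rank-2 autocorrelation decays first by the restricted
#' internal motion to a plateau near the squared cone order parameter
#' \deqn{S = \cos\theta_0 (1 + \cos\theta_0)/2,}
#' then to zero with the global tumbling time.
#'
#' @param cone_half_angle_deg cone half-angle in degrees, in (0, 90].
#' @param tau_internal_ps internal diffusion correlation time
#'   (\eqn{1/(6 D_{int})}) in ps; must be shorter than the global time.
#' @param tau_global_ns global tumbling time in ns.
#' @param timestep_ps frame spacing in ps.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return A [vector_trajectory()].
#' @export
gen_cone_tumbling_trajectory <- function(cone_half_angle_deg, tau_internal_ps,
                                         tau_global_ns, timestep_ps, n_frames,
                                         seed = 1L) {
  if (cone_half_angle_deg <= 0 || cone_half_angle_deg > 90)
    stop("'cone_half_angle_deg' must be in (0, 90]")
  if (tau_internal_ps >= tau_global_ns * 1000)
    stop("'tau_internal_ps' must be shorter than the global tumbling time")
  theta0 <- cone_half_angle_deg * pi / 180
  d_int <- 1 / (6 * tau_internal_ps)        # ps^-1
  d_glob <- 1 / (6 * tau_global_ns * 1000)  # ps^-1
  sd_int <- sqrt(4 * d_int * timestep_ps)
  sd_frame <- sqrt(2 * d_glob * timestep_ps)
  V <- with_seed_local(seed, {
    out <- matrix(0, n_frames, 3)
    b <- c(0, 0, 1)     # body-frame vector, cone axis = body z
    R <- diag(3)        # body -> lab rotation
    out[1, ] <- R %*% b
    for (i in 2:n_frames) {
      # internal: tangent step inside the cone, reflect at the boundary
      b <- rotate_about_random_perp(b, stats::rnorm(1, 0, sd_int),
                                    stats::runif(1, 0, 2 * pi))
      th <- acos(min(max(b[3], -1), 1))
      if (th > theta0) {
        b <- tilt_toward_axis(b, 2 * (th - theta0))
        th2 <- acos(min(max(b[3], -1), 1))
        if (th2 > theta0) b <- tilt_toward_axis(b, th2 - theta0)
      }
      # global: small random rigid-body rotation of the frame
      R <- R %*% rotation_from_vector(stats::rnorm(3, 0, sd_frame))
      out[i, ] <- R %*% b
    }
    out
  })
  vector_trajectory(V, timestep_ps)
}

# reduce the polar angle of b (w.r.t. +z) by 'delta', keeping its azimuth
tilt_toward_axis <- function(b, delta) {
  th <- acos(min(max(b[3], -1), 1))
  th_new <- max(th - delta, 0)
  s <- sqrt(b[1]^2 + b[2]^2)
  if (s < 1e-12) return(c(0, 0, 1))
  c(sin(th_new) * b[1] / s, sin(th_new) * b[2] / s, cos(th_new))
}

# rotation matrix for a small rotation vector w (Rodrigues)
rotation_from_vector <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Synthetic peak-intensity decay tables
#'
#' Exponential decays \eqn{I = I_0 \exp(-R t)(1 + \epsilon)} with relative
#' Gaussian noise, on the delay schedules used for amide 15N experiments:
#' by default 10-640 ms for R1 and 10-150 ms for R1rho.
#'
#' @param rates named numeric vector of per-residue decay rates in s^-1.
#' @param i0s intensities at zero delay (recycled).
#' @param delays_s delay schedule in seconds; defaults to the experiment's
#'   standard schedule.
#' @param noise_frac relative noise level (default 0).
#' @param kind `"R1"` or `"R1rho"` (selects the default schedule).
#' @param n_replicates replicate measurements per delay (default 1).
#' @param seed RNG seed.
#' @return data.frame with columns `residue`, `delay_s`, `intensity`,
#'   `replicate`.
#' @export
gen_intensity_decays <- function(rates, i0s = 100, delays_s = NULL,
                                 noise_frac = 0, kind = c("R1", "R1rho"),
                                 n_replicates = 1L, seed = 1L) {
  kind <- match.arg(kind)
  if (noise_frac < 0) stop("'noise_frac' must be non-negative")
  if (is.null(delays_s))
    delays_s <- if (kind == "R1")
      c(10, 20, 40, 80, 160, 320, 480, 640) / 1000
    else c(10, 30, 50, 70, 90, 110, 130, 150) / 1000
  labs <- names(rates) %||% as.character(seq_along(rates))
  i0s <- rep_len(i0s, length(rates))
  grid <- expand.grid(replicate = seq_len(n_replicates), delay_s = delays_s,
                      res_i = seq_along(rates), KEEP.OUT.ATTRS = FALSE)
  ideal <- i0s[grid$res_i] * exp(-rates[grid$res_i] * grid$delay_s)
  eps <- if (noise_frac > 0)
    with_seed_local(seed, stats::rnorm(nrow(grid), 0, noise_frac))
  else rep(0, nrow(grid))
  data.frame(residue = labs[grid$res_i], delay_s = grid$delay_s,
             intensity = as.numeric(ideal * (1 + eps)),
             replicate = grid$replicate)
}

#' Ensemble specification for synthetic per-residue dynamics
#'
#' Population parameters for drawing per-residue three-exponential models:
#' mean and SD for each amplitude and correlation time. The defaults are
#' the ensemble statistics of the three-exponential fits to disordered
#' ProTalpha backbone amide autocorrelation functions (tau = 7+/-9,
#' 419+/-454, 3400+/-5700 ps; a = 0.37+/-0.09, 0.36+/-0.12, 0.27+/-0.17).
#'
#' @param n_residues number of residues (default 110, the approximate
#'   ProTalpha chain length).
#' @param a_mean,a_sd length-3 amplitude means and SDs.
#' @param tau_mean_ps,tau_sd_ps length-3 correlation-time means and SDs in
#'   ps.
#' @param rate_noise_frac relative noise applied to back-calculated rates
#'   (default 0.02).
#' @param seed RNG seed.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_residues = 110L,
                          a_mean = c(0.37, 0.36, 0.27),
                          a_sd = c(0.09, 0.12, 0.17),
                          tau_mean_ps = c(7, 419, 3400),
                          tau_sd_ps = c(9, 454, 5700),
                          rate_noise_frac = 0.02,
                          seed = 1L) {
  stopifnot(length(a_mean) == 3L, length(a_sd) == 3L,
            length(tau_mean_ps) == 3L, length(tau_sd_ps) == 3L,
            all(a_mean > 0), all(tau_mean_ps > 0),
            all(a_sd >= 0), all(tau_sd_ps >= 0),
            n_residues >= 1L, rate_noise_frac >= 0)
  structure(list(n_residues = as.integer(n_residues), a_mean = a_mean,
                 a_sd = a_sd, tau_mean_ps = tau_mean_ps,
                 tau_sd_ps = tau_sd_ps, rate_noise_frac = rate_noise_frac,
                 seed = seed),
            class = "ensemble_spec")
}

# lognormal draws matching a stated mean and SD (sd = 0 gives the mean)
rlnorm_match <- function(n, mean, sd) {
  sig2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, log(mean) - sig2 / 2, sqrt(sig2))
}

#' Draw a synthetic per-residue ensemble with ground truth
#'
#' Per residue, amplitudes are drawn from truncated normals (truncated at
#' >= 0.01, then renormalized to sum to 1) and correlation times from
#' lognormals whose mean and SD match the stated population values.
#' Reported correlation-time statistics of multi-exponential fits across a
#' disordered chain have SDs comparable to or larger than their means
#' (e.g. 7 +/- 9 ps), which a normal distribution over a positive variable
#' cannot represent; the moment-matched lognormal reproduces both the
#' stated mean and SD together with the heavy right skew such populations
#' imply (most residues below the mean, a few far above). The whole draw
#' is resampled until the correlation times are ordered tau1 < tau2 < tau3
#' (resampling, not sorting, so each marginal keeps its own distribution).
#' Ground-truth models are returned alongside noisy back-calculated
#' relaxation rates for recovery testing.
#'
#' @param spec an [ensemble_spec()].
#' @param constants a [spin_system()] for the back-calculated observables.
#' @return list with `models` (named list of `multiexp_model`), `truth`
#'   (data.frame of noise-free R1, R2, NOE) and `observed` (same with
#'   relative Gaussian noise `spec$rate_noise_frac`).
#' @export
gen_residue_ensemble <- function(spec, constants = spin_system()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  max_tries <- 50L
  draws <- with_seed_local(spec$seed, {
    models <- vector("list", spec$n_residues)
    rejected <- 0L
    total <- 0L
    for (r in seq_len(spec$n_residues)) {
      for (k in seq_len(max_tries)) {
        total <- total + 1L
        a <- stats::rnorm(3, spec$a_mean, spec$a_sd)
        tau <- rlnorm_match(3, spec$tau_mean_ps, spec$tau_sd_ps)
        ok <- all(a >= 0.01) && all(tau > 0.1) && tau[1] < tau[2] &&
          tau[2] < tau[3]
        if (ok) break
        rejected <- rejected + 1L
      }
      if (!ok)
        stop("ensemble spec infeasible: a residue draw failed ", max_tries,
             " times; tighten the SDs or truncation bounds")
      models[[r]] <- new_multiexp_model(a / sum(a), tau)
    }
    if (rejected > 0.9 * total)
      stop(sprintf(paste0("ensemble spec infeasible: %d of %d draws rejected ",
                          "(> 90%%); tighten the SDs or truncation bounds"),
                   rejected, total))
    noise <- stats::rnorm(3L * spec$n_residues, 0, 1)
    list(models = models, noise = noise)
  })
  models <- draws$models
  names(models) <- as.character(seq_len(spec$n_residues))
  truth <- do.call(rbind, lapply(seq_along(models), function(i) {
    rr <- relaxation_rates(models[[i]], constants)
    data.frame(residue = names(models)[i], R1 = rr$R1, R2 = rr$R2,
               NOE = rr$NOE)
  }))
  eps <- matrix(draws$noise, ncol = 3) * spec$rate_noise_frac
  observed <- truth
  observed$R1 <- truth$R1 * (1 + eps[, 1])
  observed$R2 <- truth$R2 * (1 + eps[, 2])
  observed$NOE <- truth$NOE * (1 + eps[, 3])
  list(models = models, truth = truth, observed = observed)
}
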