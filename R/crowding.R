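#' Viscosity-scaling transform for crowded conditions
#'
#' Rule for predicting a dynamic model under macromolecular crowding:
#' correlation times of the slow motions are multiplied by a common factor
#' `scale` (the ratio by which a rigid reference protein's tumbling time
#' grows in the crowded solution, e.g. 8.0/4.3 = 1.86 for 160 g/L Ficoll
#' 70), while the fastest (librational) component is left untouched.
#' Optionally the fast-motion amplitude is overridden (e.g. a1 = 0.20 for a
#' highly crowded environment), with the remaining amplitudes rescaled
#' proportionally so they still sum to 1.
#'
#' @param scale positive factor applied to the scaled correlation times.
#' @param scaled_terms indices of the terms to scale; default `NULL` means
#'   all but the fastest.
#' @param a1_override optional replacement amplitude for the fastest term,
#'   in `[0, 1)`.
#' @return An object of class `crowding_transform`.
#' @export
crowding_transform <- function(scale, scaled_terms = NULL, a1_override = NULL) {
  if (scale <= 0) stop("'scale' must be positive")
  if (!is.null(a1_override) &&
      (a1_override < 0 || a1_override >= 1))
    stop("'a1_override' must be in [0, 1)")
  structure(list(scale = scale, scaled_terms = scaled_terms,
                 a1_override = a1_override),
            class = "crowding_transform")
}

#' Apply a crowding transform to a dynamic model
#'
#' Multiplies the slow correlation times by the transform's scale factor
#' (the fastest term is untouched by default) and, if requested, replaces
#' the fast amplitude, renormalizing the remaining amplitudes
#' proportionally.
#'
#' @param model a `multiexp_model`.
#' @param transform a [crowding_transform()].
#' @return A new, valid `multiexp_model`.
#' @examples
#' m <- build_multiexp_model(c(0.37, 0.36, 0.27), c(7, 419, 3400))
#' apply_crowding(m, crowding_transform(1.86))  # tau -> 7, 779.3, 6324 ps
#' @export
apply_crowding <- function(model, transform) {
  stopifnot(inherits(model, "multiexp_model"),
            inherits(transform, "crowding_transform"))
  idx <- transform$scaled_terms %||%
    (if (model$n > 1L) 2:model$n else integer())
  if (length(idx) && (min(idx) < 1L || max(idx) > model$n))
    stop("'scaled_terms' out of range for this model")
  tau <- model$tau_ps
  tau[idx] <- tau[idx] * transform$scale
  a <- model$a
  if (!is.null(transform$a1_override)) {
    rest <- sum(a[-1])
    if (rest <= 0)
      stop("cannot override the fast amplitude: no weight in slower terms")
    a <- c(transform$a1_override,
           a[-1] * (1 - transform$a1_override) / rest)
    if (any(a < 0)) stop("amplitude override makes an amplitude negative")
  }
  new_multiexp_model(a, tau)
}

#' Relaxation-parameter surface over (a2, tau2)
#'
#' Forward simulation of how 15N R1, R2 and NOE respond to the amplitude
#' and timescale of the intermediate (segmental) motion: with the fast
#' component (a1, tau1) and the slow correlation time tau3 fixed, the
#' three-term model with a3 = 1 - a1 - a2 is evaluated at every grid point
#' and the rates back-calculated.
#'
#' @param a1 fast-motion amplitude.
#' @param tau1_ps fast correlation time in ps.
#' @param tau3_ps slow correlation time in ps.
#' @param a2_grid vector of intermediate amplitudes, each in `[0, 1 - a1]`.
#' @param tau2_grid vector of intermediate correlation times in ps.
#' @param constants a [spin_system()].
#' @return An object of class `relaxation_surface`: list with the grids and
#'   matrices `R1`, `R2`, `NOE` of dimension
#'   `length(a2_grid) x length(tau2_grid)`.
#' @export
relaxation_surface <- function(a1, tau1_ps, tau3_ps,
                               a2_grid = seq(0, 1 - a1, length.out = 32),
                               tau2_grid = exp(seq(log(50), log(2000),
                                                   length.out = 32)),
                               constants = spin_system()) {
  if (any(a2_grid < 0) || any(a2_grid > 1 - a1 + 1e-12))
    stop("every a2 must lie in [0, 1 - a1]")
  dims <- c(length(a2_grid), length(tau2_grid))
  R1 <- R2 <- NOE <- matrix(NA_real_, dims[1], dims[2])
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      a2 <- a2_grid[i]
      m <- new_multiexp_model(c(a1, a2, 1 - a1 - a2),
                              c(tau1_ps, tau2_grid[j], tau3_ps))
      rr <- relaxation_rates(m, constants)
      R1[i, j] <- rr$R1
      R2[i, j] <- rr$R2
      NOE[i, j] <- rr$NOE
    }
  }
  structure(list(a1 = a1, tau1_ps = tau1_ps, tau3_ps = tau3_ps,
                 a2_grid = a2_grid, tau2_grid = tau2_grid,
                 R1 = R1, R2 = R2, NOE = NOE),
            class = "relaxation_surface")
}

#' Surface as a long-format data frame
#'
#' @param surface a [relaxation_surface()].
#' @return data.frame with columns `a2`, `tau2_ps`, `R1`, `R2`, `NOE`.
#' @export
surface_as_table <- function(surface) {
  stopifnot(inherits(surface, "relaxation_surface"))
  g <- expand.grid(a2 = surface$a2_grid, tau2_ps = surface$tau2_grid,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(g, R1 = as.vector(surface$R1), R2 = as.vector(surface$R2),
             NOE = as.vector(surface$NOE))
}

#' Predict crowded-condition relaxation for a residue ensemble
#'
#' Applies a crowding transform to every per-residue model and
#' back-calculates R1, R2 and NOE before and after, returning a paired
#' table (starred columns = crowded prediction) suitable for scatter
#' comparison.
#'
#' @param models list of `multiexp_model` objects, optionally named by
#'   residue.
#' @param transform a [crowding_transform()].
#' @param constants a [spin_system()].
#' @return data.frame with columns `residue`, `R1`, `R2`, `NOE`,
#'   `R1_star`, `R2_star`, `NOE_star`.
#' @export
predict_crowded_ensemble <- function(models, transform,
                                     constants = spin_system()) {
  if (!length(models)) stop("need at least one model")
  labs <- names(models) %||% as.character(seq_along(models))
  rows <- lapply(seq_along(models), function(i) {
    before <- relaxation_rates(models[[i]], constants)
    after <- relaxation_rates(apply_crowding(models[[i]], transform),
                              constants)
    data.frame(residue = labs[i], R1 = before$R1, R2 = before$R2,
               NOE = before$NOE, R1_star = after$R1, R2_star = after$R2,
               NOE_star = after$NOE)
  })
  do.call(rbind, rows)
}

#' Ensemble summary of fitted model parameters
#'
#' Mean and sample (n - 1) standard deviation of every amplitude and
#' correlation time across a set of fits sharing the same number of terms,
#' in the layout conventionally used to report multi-exponential fit
#' statistics over residues.
#'
#' @param fits list of `multiexp_fit` objects (or bare `multiexp_model`s),
#'   all with the same number of terms.
#' @return data.frame with one row per term and columns `term`, `a_mean`,
#'   `a_sd`, `tau_mean_ps`, `tau_sd_ps`.
#' @export
summarize_ensemble <- function(fits) {
  if (!length(fits)) stop("need at least one fit")
  models <- lapply(fits, function(f) {
    if (inherits(f, "multiexp_fit")) f$model
    else if (inherits(f, "multiexp_model")) f
    else stop("elements must be multiexp_fit or multiexp_model objects")
  })
  ns <- vapply(models, function(m) m$n, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all fits must share the same number of terms")
  n <- ns[1]
  A <- t(vapply(models, function(m) m$a, numeric(n)))
  Tau <- t(vapply(models, function(m) m$tau_ps, numeric(n)))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  data.frame(term = seq_len(n),
             a_mean = colMeans(A),
             a_sd = apply(A, 2, sd0),
             tau_mean_ps = colMeans(Tau),
             tau_sd_ps = apply(Tau, 2, sd0))
}
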