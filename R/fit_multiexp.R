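#' Fit a multi-exponential model to an autocorrelation series
#'
#' Weighted least-squares fit of \eqn{C(t) = \sum_{i=1}^{n} a_i
#' \exp(-t/\tau_i)} under the simplex constraint \eqn{\sum a_i = 1},
#' \eqn{a_i \ge 0} (n - 1 free amplitudes; the last is \eqn{1 - \sum}), with
#' correlation times bounded in \eqn{[0.01\,\mathrm{ps}, 1\,\mu s]}.
#' Levenberg-Marquardt minimization with analytic Jacobian and multi-start
#' initialization: correlation times log-spaced over the fit window with
#' equal amplitudes, jittered across `restarts` starts; the best sum of
#' squares wins, ties broken by the lexicographically smaller
#' correlation-time vector. When a previous, smaller fit is supplied
#' (`prev_fit`), its solution extended by a near-zero extra term is added as
#' a start, which makes the fitted sum of squares non-increasing in n.
#'
#' The default fit window runs from 0 to 1/5 of the originating trajectory
#' span (when the series carries one; long-lag ACF estimates are averages
#' over few origins and noise-dominated), otherwise to the last lag.
#'
#' Post-processing: if two fitted correlation times agree within 5% the two
#' terms are merged (amplitude-weighted geometric-mean tau) and the fit is
#' reflagged as the smaller model (`collapsed = TRUE`); if any correlation
#' time is pinned at the upper bound the data did not decay within the
#' window and the fit is flagged not converged.
#'
#' @param acf an [acf_series()].
#' @param n number of exponential terms, 2, 3 or 4.
#' @param options list of fit options: `window_ps` (fit window upper edge),
#'   `restarts` (number of multi-start initializations, default 8),
#'   `tau_bounds_ps` (default `c(0.01, 1e6)`), `prev_fit` (a `multiexp_fit`
#'   with fewer terms, used for nested initialization), `seed` (restart
#'   jitter seed, default 1).
#' @return An object of class `multiexp_fit`: list with `model`
#'   (a `multiexp_model`, possibly collapsed), `ss`, `dof`
#'   (`n_points - (2n - 1)`), `n_points`, `n_requested`, `converged`,
#'   `collapsed`, `flags` (character), and `param_se` (named standard errors
#'   for a_i and tau_i from the local curvature).
#' @export
fit_multiexp <- function(acf, n, options = list()) {
  stopifnot(inherits(acf, "acf_series"))
  n <- as.integer(n)
  if (!n %in% 2:4) stop("'n' must be 2, 3 or 4")
  restarts <- options$restarts %||% 8L
  bounds <- options$tau_bounds_ps %||% c(0.01, 1e6)
  seed <- options$seed %||% 1L
  window <- options$window_ps %||%
    (if (!is.null(acf$traj_span_ps)) min(max(acf$lags_ps), acf$traj_span_ps / 5)
     else max(acf$lags_ps))

  in_win <- acf$lags_ps <= window
  lags <- acf$lags_ps[in_win]
  vals <- acf$values[in_win]
  wts <- if (is.null(acf$weights)) rep(1, length(lags)) else acf$weights[in_win]
  n_pts <- length(lags)
  if (n_pts < 4L * n)
    stop(sprintf("need >= %d points in the fit window for n = %d (have %d)",
                 4L * n, n, n_pts))
  sw <- sqrt(wts)
  n_free <- 2L * n - 1L
  dof <- n_pts - n_free
  lo <- c(rep(0, n - 1L), rep(log(bounds[1]), n))
  hi <- c(rep(1, n - 1L), rep(log(bounds[2]), n))

  # residuals and analytic Jacobian in p = (a_1..a_{n-1}, log tau_1..log tau_n),
  # with a_n = 1 - sum(a_free) kept feasible by a one-sided penalty residual
  pen <- 1e4
  resid_fn <- function(p) {
    a <- c(p[seq_len(n - 1L)], 1 - sum(p[seq_len(n - 1L)]))
    tau <- exp(p[n:(2L * n - 1L)])
    r <- (drop(exp(-outer(lags, 1 / tau)) %*% a) - vals) * sw
    c(r, pen * max(0, -a[n]))
  }
  jac_fn <- function(p) {
    a_free <- p[seq_len(n - 1L)]
    a_n <- 1 - sum(a_free)
    tau <- exp(p[n:(2L * n - 1L)])
    E <- exp(-outer(lags, 1 / tau))
    a <- c(a_free, a_n)
    J <- matrix(0, length(lags) + 1L, n_free)
    for (i in seq_len(n - 1L)) J[seq_along(lags), i] <- (E[, i] - E[, n]) * sw
    for (k in seq_len(n))
      J[seq_along(lags), n - 1L + k] <- a[k] * E[, k] * (lags / tau[k]) * sw
    if (a_n < 0) J[length(lags) + 1L, seq_len(n - 1L)] <- pen
    J
  }

  starts <- fit_starts(n, lags, bounds, restarts, seed, options$prev_fit)
  best <- NULL
  any_conv <- FALSE
  for (p0 in starts) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = pmin(pmax(p0, lo), hi), lower = lo,
                           upper = hi, fn = resid_fn, jac = jac_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ptol = 1e-12, ftol = 1e-12))),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_conv <- any_conv || fit$info %in% 1:4
    ss <- sum(resid_fn(fit$par)[seq_len(n_pts)]^2)
    if (is.null(best) || ss < best$ss - 1e-14 ||
        (abs(ss - best$ss) <= 1e-14 &&
         lex_less(sort(exp(fit$par[n:(2L * n - 1L)])),
                  sort(exp(best$par[n:(2L * n - 1L)]))))) {
      best <- list(par = fit$par, ss = ss, fit = fit)
    }
  }
  if (is.null(best)) stop("all fit starts failed")

  a <- c(best$par[seq_len(n - 1L)], 1 - sum(best$par[seq_len(n - 1L)]))
  a[a < 0 & a > -1e-9] <- 0
  a <- a / sum(a)
  tau <- exp(best$par[n:(2L * n - 1L)])
  flags <- character()
  converged <- any_conv

  # standard errors from the local curvature at the optimum
  se <- param_se_from_jac(jac_fn(best$par)[seq_len(n_pts), , drop = FALSE],
                          best$ss, dof, a, tau, n)

  at_upper <- tau >= bounds[2] * 0.99
  if (any(at_upper & a > 1e-3)) {
    flags <- c(flags, "tau_at_upper_bound")
    converged <- FALSE
  }

  ord <- order(tau)
  model <- new_multiexp_model(pmax(a[ord], 0), tau[ord])
  collapsed <- FALSE
  # near-degenerate correlation times: merge within 5% and reflag smaller
  if (model$n > 1L && any(diff(model$tau_ps) / model$tau_ps[-model$n] < 0.05)) {
    model <- collapse_close_taus(model, rel_tol = 0.05)
  }
  if (model$n < n) {
    collapsed <- TRUE
    flags <- c(flags, "collapsed_degenerate_tau")
    ss_m <- sum(((evaluate_acf_model(model, lags) - vals) * sw)^2)
    best$ss <- ss_m
  }

  structure(list(model = model, ss = best$ss, dof = dof, n_points = n_pts,
                 n_requested = n, converged = converged, collapsed = collapsed,
                 flags = flags, param_se = se,
                 window_ps = window),
            class = "multiexp_fit")
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat(sprintf("Multi-exponential fit: n = %d (requested %d), ss = %.4g, dof = %d%s\n",
              x$model$n, x$n_requested, x$ss, x$dof,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$model)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lex_less <- function(x, y) {
  for (i in seq_along(x)) {
    if (x[i] < y[i] - 1e-12) return(TRUE)
    if (x[i] > y[i] + 1e-12) return(FALSE)
  }
  FALSE
}

fit_starts <- function(n, lags, bounds, restarts, seed, prev_fit) {
  pos <- lags[lags > 0]
  t_lo <- max(bounds[1], min(pos) / 2)
  t_hi <- min(bounds[2], max(pos))
  starts <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (r in seq_len(restarts)) {
    ltau <- seq(log(t_lo), log(t_hi), length.out = n)
    if (r > 1) ltau <- ltau + stats::rnorm(n, 0, 0.4)
    ltau <- pmin(pmax(ltau, log(bounds[1])), log(bounds[2]))
    starts[[r]] <- c(rep(1 / n, n - 1L), sort(ltau))
  }
  if (!is.null(prev_fit) && inherits(prev_fit, "multiexp_fit") &&
      prev_fit$model$n == n - 1L) {
    m <- prev_fit$model
    eps <- 1e-6
    a0 <- c(m$a * (1 - eps), eps)
    t0 <- c(m$tau_ps, exp(mean(log(m$tau_ps))) * 1.5)
    ord <- order(t0)
    starts[[length(starts) + 1L]] <-
      c(a0[ord][seq_len(n - 1L)], log(t0[ord]))
  }
  starts
}

param_se_from_jac <- function(J, ss, dof, a, tau, n) {
  se <- rep(NA_real_, 2L * n)
  names(se) <- c(paste0("a", seq_len(n)), paste0("tau", seq_len(n)))
  V <- tryCatch(solve(crossprod(J)) * ss / max(dof, 1L), error = function(e) NULL)
  if (is.null(V)) return(se)
  dv <- diag(V)
  dv[dv < 0] <- NA_real_
  se[seq_len(n - 1L)] <- sqrt(dv[seq_len(n - 1L)])
  # a_n = 1 - sum(a_free): var is 1' V_aa 1
  v_an <- sum(V[seq_len(n - 1L), seq_len(n - 1L)])
  se[n] <- if (v_an >= 0) sqrt(v_an) else NA_real_
  # tau fitted in log space: delta method
  se[(n + 1L):(2L * n)] <- tau * sqrt(dv[n:(2L * n - 1L)])
  se
}

collapse_close_taus <- function(model, rel_tol = 0.05) {
  a <- model$a
  tau <- model$tau_ps
  repeat {
    if (length(tau) == 1L) break
    rel <- diff(tau) / tau[-length(tau)]
    k <- which(rel < rel_tol)
    if (!length(k)) break
    k <- k[1]
    w <- a[k] + a[k + 1]
    t_new <- if (w > 0) exp((a[k] * log(tau[k]) + a[k + 1] * log(tau[k + 1])) / w)
             else sqrt(tau[k] * tau[k + 1])
    a <- c(a[seq_len(k - 1)], w, a[-seq_len(k + 1)])
    tau <- c(tau[seq_len(k - 1)], t_new, tau[-seq_len(k + 1)])
  }
  new_multiexp_model(a, tau)
}

#' Nested F-test between two multi-exponential fits
#'
#' Tests whether the model with more free parameters (fit `fit_j`)
#' statistically outperforms the nested smaller model (`fit_i`) on the same
#' data, using
#' \deqn{F = \frac{(SS_i - SS_j)/(D_i - D_j)}{SS_j / D_j},}
#' where SS and D are the residual sum of squares and degrees of freedom of
#' each fit, with the p-value from the F distribution on
#' \eqn{(D_i - D_j,\, D_j)} degrees of freedom. If the larger model fits
#' worse (SS_j > SS_i, improper nesting or a poor fit), F is reported as 0
#' with a warning flag.
#'
#' @param fit_i the smaller model's `multiexp_fit`.
#' @param fit_j the larger model's `multiexp_fit` (more free parameters,
#'   same number of fitted points).
#' @param alpha significance level used to set `preferred_n` (default 0.05).
#' @return An object of class `fit_comparison`: list with `f_ratio`,
#'   `p_value`, `dof_numerator`, `dof_denominator`, `preferred_n`,
#'   `n_small`, `n_large`, `accepted`, `flags`.
#' @examples
#' # SS_i = 10, D_i = 97 vs SS_j = 8, D_j = 95 gives F = (2/2)/(8/95) = 11.875
#' @export
compare_models <- function(fit_i, fit_j, alpha = 0.05) {
  stopifnot(inherits(fit_i, "multiexp_fit"), inherits(fit_j, "multiexp_fit"))
  if (fit_j$n_points != fit_i$n_points)
    stop("fits must share the same fitted points")
  d_i <- fit_i$dof
  d_j <- fit_j$dof
  if (d_i <= d_j)
    stop("'fit_j' must have more free parameters (smaller dof) than 'fit_i'")
  flags <- character()
  if (fit_j$ss > fit_i$ss) {
    warning("larger model fits worse than the smaller one; F reported as 0")
    flags <- c(flags, "larger_model_worse")
    f <- 0
  } else {
    f <- ((fit_i$ss - fit_j$ss) / (d_i - d_j)) / (fit_j$ss / d_j)
  }
  p <- stats::pf(f, d_i - d_j, d_j, lower.tail = FALSE)
  accepted <- alpha > 0 && p <= alpha
  structure(list(f_ratio = f, p_value = p,
                 dof_numerator = d_i - d_j, dof_denominator = d_j,
                 preferred_n = if (accepted) fit_j$n_requested else fit_i$n_requested,
                 n_small = fit_i$n_requested, n_large = fit_j$n_requested,
                 accepted = accepted, flags = flags),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat(sprintf("F-test n=%d vs n=%d: F = %.4g on (%d, %d) df, p = %.3g -> prefer n = %d\n",
              x$n_small, x$n_large, x$f_ratio, x$dof_numerator,
              x$dof_denominator, x$p_value, x$preferred_n))
  invisible(x)
}

#' Select the number of exponential terms by nested F-tests
#'
#' Fits the candidate models in ascending order of n (nested multi-start
#' initialization) and accepts each larger model only when the nested F-test
#' against the current best model is significant at level `alpha`. A larger
#' fit that collapses to the current model size (near-degenerate correlation
#' times) is never accepted. With `alpha = 0` the smallest candidate is
#' always returned.
#'
#' @param acf an [acf_series()].
#' @param candidates integer vector of candidate term counts (subset of
#'   2:4, default `c(2, 3, 4)`).
#' @param alpha significance level in `[0, 1)` (default 0.05).
#' @param options passed to [fit_multiexp()].
#' @return The selected `multiexp_fit`, with the full comparison trail in
#'   `attr(, "comparison_trail")` and all candidate fits in
#'   `attr(, "all_fits")`.
#' @export
select_model <- function(acf, candidates = c(2L, 3L, 4L), alpha = 0.05,
                         options = list()) {
  candidates <- sort(unique(as.integer(candidates)))
  if (!all(candidates %in% 2:4)) stop("candidates must be within 2:4")
  if (alpha < 0 || alpha >= 1) stop("'alpha' must be in [0, 1)")
  fits <- list()
  trail <- list()
  current <- fit_multiexp(acf, candidates[1], options)
  fits[[as.character(candidates[1])]] <- current
  for (n in candidates[-1]) {
    opt <- options
    opt$prev_fit <- current
    cand <- fit_multiexp(acf, n, opt)
    fits[[as.character(n)]] <- cand
    if (cand$collapsed && cand$model$n <= current$model$n) {
      trail[[length(trail) + 1L]] <-
        structure(list(f_ratio = NA_real_, p_value = NA_real_,
                       dof_numerator = current$dof - cand$dof,
                       dof_denominator = cand$dof,
                       preferred_n = current$n_requested,
                       n_small = current$n_requested, n_large = n,
                       accepted = FALSE,
                       flags = "collapsed_to_smaller_model"),
                  class = "fit_comparison")
      next
    }
    cmp <- withCallingHandlers(
      compare_models(current, cand, alpha = alpha),
      warning = function(w) invokeRestart("muffleWarning"))
    trail[[length(trail) + 1L]] <- cmp
    if (cmp$accepted) current <- cand
  }
  attr(current, "comparison_trail") <- trail
  attr(current, "all_fits") <- fits
  current
}
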