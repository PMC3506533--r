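#' Sampled autocorrelation series
#'
#' Container for a rank-2 bond-vector autocorrelation function sampled on a
#' lag grid, as produced by trajectory ACF tools or by
#' [compute_p2_acf()] / [gen_multiexp_acf()]. Lags must be strictly
#' increasing and start at 0; the value at lag 0 must be 1 (within `1e-6`
#' plus the declared noise tolerance).
#'
#' @param lags_ps numeric vector of lag times in ps, strictly increasing,
#'   first element 0.
#' @param values numeric vector of correlation values, same length.
#' @param weights optional non-negative per-point fit weights.
#' @param noise_tol tolerance added to the `|C| <= 1` and `C(0) = 1` checks
#'   for noisy estimates (default 0.05).
#' @param traj_span_ps optional total time span of the trajectory the ACF was
#'   estimated from; used by [fit_multiexp()] to pick its default fit window.
#' @return An object of class `acf_series`.
#' @export
acf_series <- function(lags_ps, values, weights = NULL, noise_tol = 0.05,
                       traj_span_ps = NULL) {
  lags_ps <- as.numeric(lags_ps)
  values <- as.numeric(values)
  if (length(lags_ps) != length(values))
    stop("'lags_ps' and 'values' must have equal length")
  if (length(lags_ps) < 2L) stop("need at least 2 lag points")
  if (lags_ps[1] != 0) stop("lag grid must start at 0")
  if (any(diff(lags_ps) <= 0)) stop("lag times must be strictly increasing")
  if (abs(values[1] - 1) > 1e-6 + noise_tol)
    stop(sprintf("C(0) = %.6g; a normalized autocorrelation has C(0) = 1",
                 values[1]))
  if (any(abs(values) > 1 + noise_tol))
    stop("|C(t)| exceeds 1 beyond the noise tolerance")
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(values) || any(weights < 0))
      stop("'weights' must be non-negative and match the series length")
  }
  structure(list(lags_ps = lags_ps, values = values, weights = weights,
                 traj_span_ps = traj_span_ps),
            class = "acf_series")
}

#' @export
print.acf_series <- function(x, ...) {
  cat(sprintf("Autocorrelation series: %d lags, 0 - %.4g ps\n",
              length(x$lags_ps), max(x$lags_ps)))
  invisible(x)
}

#' Read an autocorrelation table
#'
#' Reads a two-column (lag in ps, correlation) table. Two dialects are
#' supported: whitespace-delimited text with `#` / `@` comment or directive
#' lines (the xvg dialect written by trajectory analysis tools), and CSV with
#' header `lag_ps,acf`.
#'
#' @param path file path.
#' @param ... passed to [acf_series()] (e.g. `noise_tol`).
#' @return An `acf_series`.
#' @export
read_acf_table <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && grepl("^\\s*lag_ps\\s*,", lines[1])) {
    d <- utils::read.csv(path)
    return(acf_series(d$lag_ps, d$acf, ...))
  }
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  d <- utils::read.table(text = lines[keep])
  if (ncol(d) < 2L) stop("expected two columns: lag_ps, acf")
  acf_series(d[[1]], d[[2]], ...)
}

#' Write an autocorrelation table
#'
#' @param acf an `acf_series`.
#' @param path output file path.
#' @param format `"xvg"` (whitespace-delimited with `@` headers) or `"csv"`
#'   (header `lag_ps,acf`).
#' @return `path`, invisibly.
#' @export
write_acf_table <- function(acf, path, format = c("xvg", "csv")) {
  stopifnot(inherits(acf, "acf_series"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(data.frame(lag_ps = acf$lags_ps, acf = acf$values),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("@    title \"Rotational autocorrelation\"",
                 "@    xaxis  label \"Time (ps)\"",
                 "@    yaxis  label \"C(t)\""), con)
    writeLines(sprintf("%.6g %.10g", acf$lags_ps, acf$values), con)
  }
  invisible(path)
}

#' Serialize a fit result as JSON
#'
#' Writes `{n, a, tau_ps, ss, dof, f_trail}` for a [fit_multiexp()] /
#' [select_model()] result. The `f_trail` element holds the model-comparison
#' trail (one record per nested F-test) when the fit came from
#' [select_model()], otherwise an empty list.
#'
#' @param fit a `multiexp_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "multiexp_fit"))
  trail <- attr(fit, "comparison_trail")
  rep <- list(n = fit$model$n, a = fit$model$a, tau_ps = fit$model$tau_ps,
              ss = fit$ss, dof = fit$dof,
              f_trail = if (is.null(trail)) list() else lapply(trail, function(cmp)
                list(n_small = cmp$n_small, n_large = cmp$n_large,
                     f_ratio = cmp$f_ratio, p_value = cmp$p_value,
                     accepted = cmp$accepted)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
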