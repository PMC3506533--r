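#' Unit bond-vector trajectory
#'
#' Per-frame unit vectors (e.g. backbone H-N bond orientations) on a uniform
#' time grid, in the lab frame. Vectors are normalized on construction; a
#' zero-norm vector is an error.
#'
#' @param vectors numeric matrix with 3 columns (x, y, z), one row per
#'   frame, at least 2 rows.
#' @param timestep_ps frame spacing in ps (positive).
#' @param residue optional residue label.
#' @return An object of class `vector_trajectory`.
#' @export
vector_trajectory <- function(vectors, timestep_ps, residue = NULL) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3L) stop("'vectors' must have 3 columns")
  if (nrow(vectors) < 2L) stop("need at least 2 frames")
  if (timestep_ps <= 0) stop("'timestep_ps' must be positive")
  nrm <- sqrt(rowSums(vectors^2))
  bad <- which(nrm < 1e-12)
  if (length(bad))
    stop(sprintf("zero-norm vector at frame %d", bad[1]))
  vectors <- vectors / nrm
  dimnames(vectors) <- NULL
  structure(list(vectors = vectors, timestep_ps = timestep_ps,
                 residue = residue),
            class = "vector_trajectory")
}

#' @export
print.vector_trajectory <- function(x, ...) {
  cat(sprintf("Vector trajectory: %d frames, dt = %.4g ps%s\n",
              nrow(x$vectors), x$timestep_ps,
              if (!is.null(x$residue)) paste0(" (residue ", x$residue, ")") else ""))
  invisible(x)
}

#' Read a bond-vector trajectory from text
#'
#' Parses whitespace-delimited rows `time_ps x y z` (single residue) or
#' `time_ps resid x y z` (multiple residues). Comment/directive lines
#' starting with `#` or `@` are skipped. Vectors are normalized on load; the
#' timestep must be uniform within 1e-6 relative.
#'
#' @param path file path.
#' @return A `vector_trajectory` (single residue) or a named list of them
#'   (one per residue, in order of first appearance).
#' @export
read_vector_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  d <- utils::read.table(text = lines[keep])
  if (!ncol(d) %in% c(4L, 5L))
    stop("expected columns 'time_ps x y z' or 'time_ps resid x y z'")
  line_no <- which(keep)
  parse_one <- function(dd, rows, residue = NULL) {
    tt <- dd[[1]]
    dt <- diff(tt)
    if (length(dt) < 1L) stop("need at least 2 frames")
    if (any(abs(dt / dt[1] - 1) > 1e-6))
      stop("non-uniform timestep in trajectory file")
    v <- as.matrix(dd[, (ncol(dd) - 2L):ncol(dd)])
    nrm <- sqrt(rowSums(v^2))
    bad <- which(nrm < 1e-12)
    if (length(bad))
      stop(sprintf("zero-norm vector at line %d of '%s'",
                   rows[bad[1]], path))
    vector_trajectory(v, dt[1], residue = residue)
  }
  if (ncol(d) == 4L) return(parse_one(d, line_no))
  resid <- as.character(d[[2]])
  out <- lapply(unique(resid), function(r) {
    sel <- resid == r
    parse_one(d[sel, c(1, 3, 4, 5)], line_no[sel], residue = r)
  })
  names(out) <- unique(resid)
  out
}

#' Rank-2 (P2) orientational autocorrelation of a vector trajectory
#'
#' The reorientational correlation function governing dipolar NMR
#' relaxation:
#' \deqn{C(k\Delta t) = \langle P_2(\mu(t)\cdot\mu(t+k\Delta t))\rangle_t,
#'   \quad P_2(x) = (3x^2 - 1)/2,}
#' averaged over all valid time origins (direct sliding-window estimator).
#' Vectors are used in the lab frame: no superposition or removal of overall
#' tumbling is performed, so the decay contains both internal motion and
#' global reorientation. C(0) = 1 exactly.
#'
#' @param traj a [vector_trajectory()].
#' @param max_lag_ps largest lag to evaluate, at most the trajectory span.
#' @return An [acf_series()] carrying the trajectory span (used by
#'   [fit_multiexp()] to pick its default fit window).
#' @export
compute_p2_acf <- function(traj, max_lag_ps) {
  stopifnot(inherits(traj, "vector_trajectory"))
  v <- traj$vectors
  n <- nrow(v)
  dt <- traj$timestep_ps
  span <- (n - 1) * dt
  if (max_lag_ps > span + 1e-9)
    stop(sprintf("max lag %.6g ps exceeds trajectory span %.6g ps",
                 max_lag_ps, span))
  k_max <- floor(max_lag_ps / dt + 1e-9)
  vals <- vapply(0:k_max, function(k) {
    if (k == 0) return(1)
    dots <- rowSums(v[1:(n - k), , drop = FALSE] * v[(k + 1):n, , drop = FALSE])
    mean((3 * dots^2 - 1) / 2)
  }, numeric(1))
  acf_series((0:k_max) * dt, vals, noise_tol = 0.5, traj_span_ps = span)
}
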