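series_data <- function(series) {
  if (inherits(series, "session_series")) series$data else as.matrix(series)
}

#' Pearson correlation matrix of a session
#'
#' Functional connectivity between every pair of regions: Pearson's r
#' between their time courses.
#'
#' @param series A [session_series()] or a plain region x time matrix with
#'   at least 4 time points.
#' @return Symmetric region x region correlation matrix, unit diagonal.
#' @export
pearson_matrix <- function(series) {
  x <- series_data(series)
  if (ncol(x) < 4) abort("need at least 4 time points")
  v <- apply(x, 1, stats::var)
  if (any(v <= 0 | !is.finite(v))) {
    bad <- which(v <= 0 | !is.finite(v))[1] - 1L
    abort(sprintf("region %d has zero variance", bad))
  }
  r <- stats::cor(t(x))
  (r + t(r)) / 2
}

#' Lag-1 autocorrelation per region
#'
#' Sample autocorrelation at lag 1 of each region's series, the quantity
#' entering the effective-sample-size correction for correlation
#' significance between autocorrelated signals.
#'
#' @param series A [session_series()] or a plain region x time matrix with
#'   at least 4 time points.
#' @return Named numeric vector, one coefficient per region, in `[-1, 1]`.
#' @export
lag1_autocorr <- function(series) {
  x <- series_data(series)
  if (ncol(x) < 4) abort("need at least 4 time points")
  autocorr_at_lags(x, 1L)[, 1]
}

# Sample autocorrelations (acf convention: denominator = lag-0 sum over
# the full series) at lags 1..max_lag for each row of x.
autocorr_at_lags <- function(x, max_lag) {
  tt <- ncol(x)
  xc <- x - rowMeans(x)
  denom <- rowSums(xc^2)
  if (any(denom <= 0)) {
    abort(sprintf("region %d has zero variance", which(denom <= 0)[1] - 1L))
  }
  out <- matrix(NA_real_, nrow(x), max_lag)
  for (k in seq_len(max_lag)) {
    out[, k] <- rowSums(xc[, 1:(tt - k), drop = FALSE] *
                          xc[, (1 + k):tt, drop = FALSE]) / denom
  }
  rownames(out) <- rownames(x)
  out
}

#' Effective sample size of a correlation between autocorrelated series
#'
#' Two AR-correlated series carry fewer independent observations than time
#' points. The default lag-1 correction is
#' `N_eff = n * (1 - rho_i * rho_j) / (1 + rho_i * rho_j)`, floored at 4 so
#' the downstream t statistic keeps at least 2 degrees of freedom. Values
#' above `n` (opposite-signed autocorrelations) are reported as computed.
#'
#' @param n_timepoints Number of time points, at least 4.
#' @param rho_i,rho_j Lag-1 autocorrelation of each series (vectorized;
#'   recycled against each other).
#' @return Effective sample size(s), same shape as `rho_i * rho_j`.
#' @export
#' @examples
#' effective_n(100, 0.5, 0.5) # 100 * 0.75 / 1.25 = 60
effective_n <- function(n_timepoints, rho_i, rho_j) {
  stopifnot(n_timepoints >= 4)
  prod <- rho_i * rho_j
  if (any(prod <= -1)) abort("rho_i * rho_j = -1 is degenerate")
  pmax(n_timepoints * (1 - prod) / (1 + prod), 4)
}

# Full-lag-sum variant: N_eff = n / (1 + 2 * sum_k rho_i(k) rho_j(k)),
# with the lag window capped at n/3. Returns an n_regions^2 matrix.
effective_n_full <- function(x, n_timepoints) {
  max_lag <- max(1L, min(n_timepoints %/% 3, 50L))
  ac <- autocorr_at_lags(x, max_lag)
  denom <- 1 + 2 * tcrossprod(ac)
  pmax(n_timepoints / pmax(denom, 0.1), 4)
}

#' Convert a correlation to a Z score through the t distribution
#'
#' `t = r * sqrt((n_eff - 2) / (1 - r^2))`, then `Z` is the standard-normal
#' quantile matching the t statistic's tail probability, computed on the log
#' scale so large `|t|` does not overflow to infinity. The sign of `Z`
#' equals the sign of `r`, and `|Z| > 1.96` corresponds to two-sided
#' `p < 0.05` exactly as for the normal reference.
#'
#' @param r Correlation(s), `|r| < 1`; `|r| = 1` returns `z_cap` with a
#'   warning.
#' @param n_eff Effective sample size(s), at least 4.
#' @param z_cap Cap returned for degenerate `|r| = 1`, default 40.
#' @return Z score(s), same shape as `r`.
#' @export
r_to_z <- function(r, n_eff, z_cap = 40) {
  stopifnot(all(n_eff >= 4))
  z <- numeric(length(r))
  degen <- abs(r) >= 1
  if (any(degen)) {
    warn("|r| = 1 encountered; capping Z")
    z[degen] <- sign(r[degen]) * z_cap
  }
  ok <- !degen
  if (any(ok)) {
    t_stat <- r[ok] * sqrt((n_eff[ok] - 2) / (1 - r[ok]^2))
    df <- n_eff[ok] - 2
    log_upper <- stats::pt(abs(t_stat), df = df, lower.tail = FALSE,
                           log.p = TRUE)
    z_abs <- stats::qnorm(log_upper, lower.tail = FALSE, log.p = TRUE)
    z[ok] <- sign(t_stat) * pmin(z_abs, z_cap)
  }
  dim(z) <- dim(r)
  z
}

#' Session-level Z matrix
#'
#' The full per-session significance map: Pearson r for every region pair,
#' effective sample size from the two regions' autocorrelations, r -> t -> Z.
#' Diagonal is stored as 0.
#'
#' @param series A (filtered) [session_series()].
#' @param ess_mode `"lag1"` for the lag-1 effective-sample-size correction,
#'   `"full"` for the full-lag-sum variant.
#' @return Symmetric region x region Z matrix with zero diagonal.
#' @export
session_z_matrix <- function(series, ess_mode = c("lag1", "full")) {
  ess_mode <- match.arg(ess_mode)
  x <- series_data(series)
  r <- pearson_matrix(x)
  tt <- ncol(x)
  n_eff <- if (ess_mode == "lag1") {
    rho <- lag1_autocorr(x)
    effective_n(tt, outer(rho, rho, function(a, b) a),
                outer(rho, rho, function(a, b) b))
  } else {
    effective_n_full(x, tt)
  }
  diag(r) <- 0 # self-correlation is not an edge candidate
  z <- r_to_z(r, n_eff)
  diag(z) <- 0
  (z + t(z)) / 2
}

#' Average Z matrices over sessions
#'
#' Element-wise mean over the sessions that passed quality control.
#'
#' @param z_list Non-empty list of identically sized Z matrices.
#' @return List with `z` (the mean matrix) and `n_sessions_used`.
#' @export
average_z <- function(z_list) {
  if (length(z_list) == 0) abort("no usable sessions to average")
  dims <- vapply(z_list, dim, integer(2))
  if (any(dims != dims[, 1])) abort("Z matrices differ in shape")
  z <- Reduce(`+`, z_list) / length(z_list)
  list(z = (z + t(z)) / 2, n_sessions_used = length(z_list))
}

#' Binarize a Z matrix into an adjacency matrix
#'
#' An edge joins two regions when their averaged `Z` strictly exceeds the
#' threshold (default 1.96, the two-sided 5% normal quantile). The diagonal
#' is never an edge.
#'
#' @param z Symmetric Z matrix.
#' @param threshold Strict lower bound for an edge, default 1.96.
#' @return List of class `adjacency`: binary symmetric matrix `a` with zero
#'   diagonal and the unordered edge count `n_edges`.
#' @export
binarize <- function(z, threshold = 1.96) {
  z <- as.matrix(z)
  if (!isTRUE(all.equal(z, t(z), tolerance = 1e-8))) {
    abort("Z matrix must be symmetric")
  }
  a <- (z > threshold) * 1
  diag(a) <- 0
  a <- pmax(a, t(a)) # symmetric by construction; guard against fp asymmetry
  storage.mode(a) <- "double"
  structure(list(a = a, n_edges = sum(a) / 2), class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("<adjacency> %d regions, %d edges\n", nrow(x$a), x$n_edges))
  invisible(x)
}

#' Subject-level connectivity from raw sessions
#'
#' Runs the per-subject connectivity chain: motion QC on every session,
#' band-pass filtering of the passing ones, per-session Z matrices, and the
#' across-session average. Subjects with no usable session return `NULL`
#' with the exclusion reason attached.
#'
#' @param sessions List of [session_series()].
#' @param motion List of motion traces matching `sessions` (or `NULL` to
#'   skip QC).
#' @param low_hz,high_hz Band-pass limits passed to [bandpass()].
#' @param ess_mode Effective-sample-size variant, see [session_z_matrix()].
#' @param trans_limit_mm,rot_limit_rad QC limits, see [qc_session()].
#' @return List with `z`, `n_sessions_used`, and `qc` (per-session tibble),
#'   or `NULL` with attribute `reason` when every session failed QC.
#' @export
subject_z_matrix <- function(sessions, motion = NULL,
                             low_hz = 0.01, high_hz = 0.1,
                             ess_mode = "lag1",
                             trans_limit_mm = 2, rot_limit_rad = 0.02) {
  qc <- if (is.null(motion)) {
    tibble(session = seq_along(sessions), pass = TRUE, reason = NA_character_)
  } else {
    dplyr::bind_rows(lapply(seq_along(motion), function(i) {
      dplyr::mutate(
        qc_session(motion[[i]], trans_limit_mm, rot_limit_rad),
        session = i, .before = 1
      )
    }))
  }
  keep <- which(qc$pass)
  if (length(keep) == 0) {
    return(structure(
      list(z = NULL, n_sessions_used = 0L, qc = qc,
           reason = "all sessions failed motion QC"),
      class = "subject_connectivity"
    ))
  }
  z_list <- lapply(sessions[keep], function(s) {
    session_z_matrix(bandpass(s, low_hz, high_hz), ess_mode = ess_mode)
  })
  avg <- average_z(z_list)
  structure(list(z = avg$z, n_sessions_used = avg$n_sessions_used, qc = qc),
            class = "subject_connectivity")
}
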