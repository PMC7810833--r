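#' A single session of region-averaged BOLD signal
#'
#' Thin container for one run's region x time matrix plus sampling metadata.
#' Rows are regions (in canonical atlas order), columns are volumes.
#'
#' @param data Numeric region x time matrix; no missing values, at least
#'   2 regions and 8 time points.
#' @param tr_seconds Sampling interval (repetition time), seconds.
#' @param subject_id,session_id Identifiers carried through the pipeline.
#' @return A `session_series` object.
#' @export
session_series <- function(data, tr_seconds, subject_id = NA_character_,
                           session_id = NA_character_) {
  data <- as.matrix(data)
  if (anyNA(data)) abort("session data contains missing values")
  if (nrow(data) < 2) abort("session needs at least 2 regions")
  if (ncol(data) < 8) abort("session needs at least 8 time points")
  stopifnot(is.numeric(tr_seconds), tr_seconds > 0)
  structure(
    list(data = data, tr_seconds = as.numeric(tr_seconds),
         subject_id = subject_id, session_id = session_id),
    class = "session_series"
  )
}

#' @export
print.session_series <- function(x, ...) {
  cat(sprintf("<session_series> %s/%s: %d regions x %d volumes, TR = %gs\n",
              x$subject_id, x$session_id, nrow(x$data), ncol(x$data),
              x$tr_seconds))
  invisible(x)
}

#' Motion-based session quality control
#'
#' A session fails when any volume moved at least `trans_limit_mm` on any
#' translation axis or at least `rot_limit_rad` on any rotation axis,
#' relative to the session's first (reference) volume — the realignment
#' parameter convention. Both limits are inclusive.
#'
#' @param motion T x 6 numeric matrix or data frame: three translations in
#'   mm then three rotations in radians, one row per volume.
#' @param trans_limit_mm Translation exclusion limit, default 2 mm.
#' @param rot_limit_rad Rotation exclusion limit, default 0.02 rad.
#' @return One-row tibble: `pass`, `reason` (`NA` when passing),
#'   `max_translation_mm`, `max_rotation_rad`.
#' @export
#' @examples
#' qc_session(matrix(0, 10, 6))
qc_session <- function(motion, trans_limit_mm = 2, rot_limit_rad = 0.02) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 1 || ncol(motion) != 6) {
    abort("motion trace must have 6 columns (3 translations, 3 rotations)")
  }
  if (anyNA(motion)) abort("motion trace contains missing values")
  disp <- sweep(motion, 2, motion[1, ])
  max_t <- max(abs(disp[, 1:3]))
  max_r <- max(abs(disp[, 4:6]))
  fail_t <- max_t >= trans_limit_mm
  fail_r <- max_r >= rot_limit_rad
  reason <- if (fail_t && fail_r) {
    sprintf("translation %.3f mm >= %g mm; rotation %.4f rad >= %g rad",
            max_t, trans_limit_mm, max_r, rot_limit_rad)
  } else if (fail_t) {
    sprintf("translation %.3f mm >= %g mm", max_t, trans_limit_mm)
  } else if (fail_r) {
    sprintf("rotation %.4f rad >= %g rad", max_r, rot_limit_rad)
  } else {
    NA_character_
  }
  tibble(pass = !(fail_t || fail_r), reason = reason,
         max_translation_mm = max_t, max_rotation_rad = max_r)
}

#' Band-pass filter a session
#'
#' Removes the constant offset, the linear trend, and all Fourier components
#' outside `[low_hz, high_hz]` in one step, by projecting each region's
#' series onto the orthogonal complement of the span of the intercept, the
#' linear ramp, and the out-of-band discrete Fourier modes. Because the
#' operation is an orthogonal projection it is exactly idempotent, unlike
#' detrend-then-FFT-mask pipelines; retained in-band components pass through
#' unchanged up to their overlap with the trend regressors.
#'
#' @param series A [session_series()].
#' @param low_hz,high_hz Pass band, Hz. `high_hz` must not exceed the
#'   Nyquist frequency `1 / (2 * tr_seconds)`.
#' @return A filtered [session_series()]; per-region means are 0.
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(series, "session_series"))
  nyquist <- 1 / (2 * series$tr_seconds)
  if (low_hz < 0 || low_hz >= high_hz) {
    abort("need 0 <= low_hz < high_hz")
  }
  if (high_hz > nyquist + 1e-12) {
    abort(sprintf("high_hz = %g exceeds the Nyquist frequency %g Hz for TR = %g s",
                  high_hz, nyquist, series$tr_seconds))
  }
  tt <- ncol(series$data)
  q <- stop_band_basis(tt, series$tr_seconds, low_hz, high_hz)
  qr_q <- qr(q)
  filtered <- t(qr.resid(qr_q, t(series$data)))
  dimnames(filtered) <- dimnames(series$data)
  out <- series
  out$data <- filtered
  out
}

# Regressor matrix spanning what the filter removes: intercept, linear
# trend, and every DFT mode with frequency outside [low, high].
stop_band_basis <- function(tt, tr, low_hz, high_hz) {
  t_idx <- seq_len(tt)
  cols <- list(rep(1, tt), t_idx - mean(t_idx))
  freqs <- seq_len(floor(tt / 2)) / (tt * tr)
  for (k in seq_along(freqs)) {
    if (freqs[k] >= low_hz && freqs[k] <= high_hz) next
    ang <- 2 * pi * k * t_idx / tt
    cols <- c(cols, list(cos(ang)))
    # the sine mode vanishes identically at the Nyquist index of even T
    if (!(tt %% 2 == 0 && k == tt / 2)) cols <- c(cols, list(sin(ang)))
  }
  do.call(cbind, cols)
}

#' Drop initial volumes from a session
#'
#' Removes the first `k` volumes (T1-equilibration scans) from a session.
#'
#' @param series A [session_series()].
#' @param k Number of leading volumes to discard; must be < the session length.
#' @return The shortened [session_series()].
#' @export
discard_initial_volumes <- function(series, k = 3) {
  stopifnot(inherits(series, "session_series"), k >= 0)
  if (k >= ncol(series$data)) {
    abort(sprintf("cannot discard %d of %d volumes", k, ncol(series$data)))
  }
  if (k == 0) return(series)
  out <- series
  out$data <- series$data[, -seq_len(k), drop = FALSE]
  out
}
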