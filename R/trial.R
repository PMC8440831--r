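#' Construct a motion trial of 3D marker trajectories
#'
#' @param data numeric array `frames x markers x 3` (mm, ground frame).
#' @param marker_names character vector matching `dim(data)[2]`.
#' @param rate sampling rate in Hz (the study protocol records at 100 Hz).
#' @param time optional time vector (s); defaults to `(0:(n-1))/rate`.
#' @param mask logical `frames x markers` matrix, `TRUE` where the sample is
#'   missing; defaults to the `NA` pattern of `data`.
#' @return an object of class `motion_trial`.
#' @export
motion_trial <- function(data, marker_names, rate = 100,
                         time = NULL, mask = NULL) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == 3L)
  if (rate <= 0) stop("sampling rate must be > 0")
  if (dim(data)[1] < 2L) stop("a motion trial needs at least 2 frames")
  if (length(marker_names) != dim(data)[2])
    stop("marker_names length does not match data")
  if (is.null(time)) time <- (seq_len(dim(data)[1]) - 1L) / rate
  if (is.null(mask)) mask <- apply(is.na(data), c(1, 2), any)
  dimnames(data) <- list(NULL, marker_names, c("x", "y", "z"))
  structure(list(data = data, marker_names = marker_names, rate = rate,
                 time = time, mask = mask),
            class = "motion_trial")
}

#' @export
print.motion_trial <- function(x, ...) {
  cat(sprintf("<motion_trial> %d frames x %d markers @ %g Hz (%.2f s), %d missing samples\n",
              dim(x$data)[1], dim(x$data)[2], x$rate,
              dim(x$data)[1] / x$rate, sum(x$mask)))
  invisible(x)
}

#' Zero-phase Butterworth low-pass filter of marker trajectories
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' (zero phase lag) to every marker coordinate, the conventional treatment
#' of optical marker data before inverse kinematics. Reflective padding is
#' used at both ends to suppress edge transients; trajectory length is
#' preserved.
#'
#' @param trial a `motion_trial`.
#' @param cutoff_hz cutoff frequency (default 6 Hz); must be below Nyquist.
#' @param order filter order before the bidirectional pass (default 4).
#' @return a filtered `motion_trial`.
#' @export
lowpass_filter <- function(trial, cutoff_hz = 6, order = 4) {
  nyq <- trial$rate / 2
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, nyq))
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  n <- dim(trial$data)[1]
  x <- matrix(trial$data, n)  # frames x (markers*3)
  y <- filtfilt_ss(bf$b, bf$a, x)
  out <- trial
  out$data <- array(y, dim(trial$data), dimnames = dimnames(trial$data))
  out
}

## steady-state initial conditions of a direct-form-II-transposed IIR filter
## (the step-response trick used by the canonical filtfilt implementations),
## so that constant signals pass exactly and edge transients vanish
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  a <- c(a, numeric(nf - length(a)))
  b <- c(b, numeric(nf - length(b)))
  b <- b / a[1]; a <- a / a[1]
  A_t <- rbind(-a[-1], cbind(diag(nf - 2), 0))
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(diag(nf - 1) - t(A_t), B))
}

## forward-backward (zero-phase) filtering of each column of x, with odd
## reflective padding and steady-state initial conditions; vectorized across
## columns (the time recursion is the only loop)
filtfilt_ss <- function(b, a, x) {
  n <- nrow(x)
  nfact <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= nfact + 1L)
    stop("trial too short for zero-phase filtering (need > ", nfact + 1L,
         " frames)")
  zi <- lfilter_zi(b, a)
  pad_head <- 2 * matrix(x[1, ], nfact, ncol(x), byrow = TRUE) -
    x[(nfact + 1L):2L, , drop = FALSE]
  pad_tail <- 2 * matrix(x[n, ], nfact, ncol(x), byrow = TRUE) -
    x[(n - 1L):(n - nfact), , drop = FALSE]
  xp <- rbind(pad_head, x, pad_tail)
  y <- iir_df2t(b, a, xp, zi)
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- iir_df2t(b, a, y, zi)
  y <- y[nrow(y):1L, , drop = FALSE]
  y[(nfact + 1L):(nfact + n), , drop = FALSE]
}

## direct-form-II-transposed recursion, all columns at once; zi is scaled by
## each column's first sample
iir_df2t <- function(b, a, x, zi) {
  nf <- max(length(a), length(b))
  a <- c(a, numeric(nf - length(a)))
  b <- c(b, numeric(nf - length(b)))
  b <- b / a[1]; a <- a / a[1]
  n <- nrow(x); m <- ncol(x)
  z <- outer(zi, x[1, ])           # (nf-1) x m state
  y <- matrix(0, n, m)
  for (i in seq_len(n)) {
    xi <- x[i, ]
    yi <- b[1] * xi + z[1, ]
    if (nf > 2L) {
      z[1:(nf - 2L), ] <- z[2:(nf - 1L), , drop = FALSE] +
        outer(b[2:(nf - 1L)], xi) - outer(a[2:(nf - 1L)], yi)
    }
    z[nf - 1L, ] <- b[nf] * xi - a[nf] * yi
    y[i, ] <- yi
  }
  y
}

#' Linearly interpolate a time series onto a normalized time base
#'
#' Resamples each channel onto `n_frames` equally spaced points between the
#' start and the end of the motion (t_% in 0..100). Endpoints are preserved
#' exactly, so ranges of motion are invariant to normalization.
#'
#' @param series numeric matrix `frames x channels` (a vector is treated as
#'   one channel).
#' @param n_frames number of output frames (default 100).
#' @return matrix `n_frames x channels`.
#' @export
time_normalize <- function(series, n_frames = 100) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1L)
  n <- nrow(series)
  if (n < 2L) stop("time normalization needs at least 2 input frames")
  xin <- seq(0, 1, length.out = n)
  xout <- seq(0, 1, length.out = n_frames)
  apply(series, 2, function(y) stats::approx(xin, y, xout)$y)
}

#' Centered moving-average smoother
#'
#' Noise reduction applied to time-normalized joint-angle curves; a centered
#' window of odd width (default three frames). Windows shrink at the series
#' edges instead of padding, so the endpoints are averaged over fewer samples
#' and no artificial values bias the range of motion.
#'
#' @param series numeric matrix `frames x channels` or vector.
#' @param width odd window width (default 3).
#' @return smoothed series, same shape as the input.
#' @export
moving_average <- function(series, width = 3) {
  if (width %% 2 == 0 || width < 1) stop("width must be odd and >= 1")
  vec <- is.null(dim(series))
  if (vec) series <- matrix(series, ncol = 1L)
  h <- (width - 1L) / 2L
  n <- nrow(series)
  out <- series
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i, ] <- colMeans(series[lo:hi, , drop = FALSE])
  }
  if (vec) out[, 1] else out
}

#' Range of motion of a channel
#'
#' The absolute value of the difference between the value at the end and at
#' the start of the motion.
#'
#' @param series numeric vector or `frames x channels` matrix.
#' @return scalar, or a named vector for a matrix input.
#' @export
rom <- function(series) {
  if (is.null(dim(series))) {
    if (length(series) < 2L) stop("rom() needs at least 2 frames")
    return(abs(series[length(series)] - series[1L]))
  }
  if (nrow(series) < 2L) stop("rom() needs at least 2 frames")
  abs(series[nrow(series), ] - series[1L, ])
}
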