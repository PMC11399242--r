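#' Frequency band specification
#'
#' @param low_hz lower band edge in Hz (>= 0).
#' @param high_hz upper band edge in Hz (> `low_hz`).
#' @return object of class `band_spec`.
#' @export
band_spec <- function(low_hz, high_hz) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      length(low_hz) != 1L || length(high_hz) != 1L ||
      is.na(low_hz) || is.na(high_hz) || low_hz < 0 || high_hz <= low_hz) {
    stop("band_spec requires 0 <= low_hz < high_hz")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("band_spec: %g-%g Hz\n", x$low_hz, x$high_hz))
  invisible(x)
}

#' Average ROI time courses over a parcellation
#'
#' Unweighted mean over all vertices carrying each ROI label, each timepoint
#' independently.
#'
#' @param series [vertex_series()].
#' @param parc [parcellation()] with as many labels as the series has
#'   vertices.
#' @return object of class `parcel_series` (fields `data` n_rois x
#'   n_timepoints, `dt`, `roi_ids`).
#' @export
roi_average <- function(series, parc) {
  stopifnot(inherits(series, "vertex_series"), inherits(parc, "parcellation"))
  if (length(parc$labels) != series$n_vertices) {
    stop("parcellation length does not match vertex count")
  }
  sums <- rowsum(series$data, group = parc$labels)
  counts <- tabulate(parc$labels, nbins = parc$n_rois)
  data <- sums / counts
  parcel_series(data, series$dt, roi_ids = parc$roi_ids)
}

#' Vertex parcellation into ROIs
#'
#' @param labels integer vector (one per vertex) of ROI labels in
#'   `1..n_rois`; every ROI must be non-empty.
#' @param n_rois number of ROIs (default `max(labels)`).
#' @param roi_ids optional character labels in ROI order.
#' @return object of class `parcellation`.
#' @export
parcellation <- function(labels, n_rois = max(labels), roi_ids = NULL) {
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 1L) || any(labels > n_rois)) {
    stop("parcellation labels must lie in 1..n_rois")
  }
  counts <- tabulate(labels, nbins = n_rois)
  if (any(counts == 0L)) {
    stop("empty ROI(s): ", paste(which(counts == 0L), collapse = ", "))
  }
  if (is.null(roi_ids)) roi_ids <- sprintf("roi%02d", seq_len(n_rois))
  structure(list(labels = labels, n_rois = as.integer(n_rois),
                 roi_ids = roi_ids),
            class = "parcellation")
}

#' ROI-level time series
#'
#' @param data numeric matrix (n_rois x n_timepoints).
#' @param dt sampling interval, seconds.
#' @param roi_ids ROI labels in row order.
#' @return object of class `parcel_series`.
#' @export
parcel_series <- function(data, dt, roi_ids = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L) stop("parcel series needs at least 2 ROIs")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  if (is.null(roi_ids)) roi_ids <- sprintf("roi%02d", seq_len(nrow(data)))
  structure(list(data = data, dt = dt, roi_ids = roi_ids,
                 n_rois = nrow(data), n_timepoints = ncol(data)),
            class = "parcel_series")
}

# --- zero-phase Butterworth filtering --------------------------------------

# Column-wise linear detrend (least squares line removed per column).
detrend_columns <- function(m) {
  n <- nrow(m)
  t0 <- seq_len(n) - (n + 1) / 2
  slope <- crossprod(t0, m) / sum(t0^2)
  sweep(m, 2L, colMeans(m)) - outer(t0, as.vector(slope))
}

# Zero-phase (forward-backward) Butterworth response applied spectrally:
# the combined transfer function of filtfilt is |H(omega)|^2 (zero phase),
# evaluated exactly from the digital filter coefficients and applied by FFT
# on the odd-reflection-padded series. This equals the time-domain
# forward-backward pass without its startup transients, and filtering all
# columns rides on one mvfft.
filtfilt_columns <- function(m, b, a, pad) {
  n <- nrow(m)
  pad <- min(pad, n - 1L)
  if (pad > 0L) {
    pre <- 2 * matrix(m[1L, ], pad, ncol(m), byrow = TRUE) -
      m[seq(pad + 1L, 2L), , drop = FALSE]
    post <- 2 * matrix(m[n, ], pad, ncol(m), byrow = TRUE) -
      m[seq(n - 1L, n - pad), , drop = FALSE]
    m <- rbind(pre, m, post)
  }
  len <- nrow(m)
  w <- 2 * pi * (0:(len - 1L)) / len
  ew <- exp(-1i * outer(w, seq_along(b) - 1L))
  h <- (ew %*% b) / (ew[, seq_along(a), drop = FALSE] %*% a)
  gain <- as.vector(Mod(h)^2)
  y <- Re(stats::mvfft(stats::mvfft(m) * gain, inverse = TRUE)) / len
  if (pad > 0L) y <- y[(pad + 1L):(pad + n), , drop = FALSE] else y <- y[seq_len(n), , drop = FALSE]
  y
}

butter_sos <- function(order, w, type) {
  flt <- signal::butter(order, w, type = type)
  list(b = as.numeric(flt$b), a = as.numeric(flt$a))
}

filter_series_matrix <- function(data, dt, band, type, order, detrend) {
  nyq <- 1 / (2 * dt)
  m <- t(data) # time down the columns
  if (detrend) m <- detrend_columns(m)
  if (type == "pass") {
    if (band$high_hz > nyq + 1e-12) {
      stop(sprintf("band edge %g Hz exceeds Nyquist %g Hz", band$high_hz, nyq))
    }
    if (band$low_hz <= 0) stop("bandpass requires low_hz > 0")
    flt <- butter_sos(order, c(band$low_hz, band$high_hz) / nyq, "pass")
    # pad with ~one period of the low edge so its transient dies in the pad
    pad <- ceiling(1 / (band$low_hz * dt))
  } else {
    if (band$high_hz > nyq + 1e-12) {
      stop(sprintf("cutoff %g Hz exceeds Nyquist %g Hz", band$high_hz, nyq))
    }
    flt <- butter_sos(order, band$high_hz / nyq, "low")
    pad <- ceiling(12 / (band$high_hz * dt))
  }
  if (ncol(m) == 0L) return(data)
  t(filtfilt_columns(m, flt$b, flt$a, pad))
}

filter_any_series <- function(x, band, type, order, detrend, dt = NULL) {
  if (inherits(x, "vertex_series")) {
    vertex_series(filter_series_matrix(x$data, x$dt, band, type, order, detrend), x$dt)
  } else if (inherits(x, "parcel_series")) {
    parcel_series(filter_series_matrix(x$data, x$dt, band, type, order, detrend),
                  x$dt, x$roi_ids)
  } else if (is.matrix(x)) {
    if (is.null(dt)) stop("dt is required when filtering a plain matrix")
    filter_series_matrix(x, dt, band, type, order, detrend)
  } else if (is.numeric(x)) {
    if (is.null(dt)) stop("dt is required when filtering a plain vector")
    as.vector(filter_series_matrix(matrix(x, nrow = 1L), dt, band, type,
                                   order, detrend))
  } else {
    stop("unsupported series type")
  }
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass of the given order, applied forward and backward
#' (zero phase) with odd-reflection end padding. The series is linearly
#' detrended first, so the DC component is removed. Rows of a
#' `vertex_series`/`parcel_series` (time courses) are filtered independently.
#'
#' @param x [vertex_series()], [parcel_series()], numeric matrix (rows =
#'   time courses) or numeric vector.
#' @param band [band_spec()]; `low_hz > 0` and `high_hz` at most Nyquist.
#' @param dt sampling interval (seconds); only needed for plain
#'   matrices/vectors.
#' @param order Butterworth order (default 4).
#' @return filtered object of the same type as `x`.
#' @export
bandpass <- function(x, band, dt = NULL, order = 4L) {
  stopifnot(inherits(band, "band_spec"))
  filter_any_series(x, band, "pass", order, detrend = TRUE, dt = dt)
}

#' Zero-phase low-pass filter
#'
#' As [bandpass()] with the low edge at 0: Butterworth low-pass applied
#' forward-backward. The DC component is retained (no detrending).
#'
#' @param x series object, matrix or vector (see [bandpass()]).
#' @param cutoff_hz cutoff frequency in Hz (at most Nyquist).
#' @param dt sampling interval for plain matrices/vectors.
#' @param order Butterworth order (default 4).
#' @return filtered object of the same type as `x`.
#' @export
lowpass <- function(x, cutoff_hz, dt = NULL, order = 4L) {
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L || cutoff_hz <= 0) {
    stop("cutoff_hz must be a positive number")
  }
  band <- structure(list(low_hz = 0, high_hz = cutoff_hz), class = "band_spec")
  filter_any_series(x, band, "low", order, detrend = FALSE, dt = dt)
}

#' One-sided amplitude spectrum
#'
#' Plain (untapered) discrete-Fourier amplitude spectrum of a single time
#' course. Amplitudes are RMS-scaled so that `sum(amplitude^2)` equals the
#' time-domain mean square (Parseval). Frequency resolution is `1/(N dt)`;
#' the DC bin is reported and flagged.
#'
#' @param ts numeric vector, length >= 4.
#' @param dt sampling interval in seconds.
#' @return list with `frequency`, `amplitude` and logical `is_dc`.
#' @export
amplitude_spectrum <- function(ts, dt) {
  ts <- as.numeric(ts)
  n <- length(ts)
  if (n < 4L) stop("need at least 4 timepoints for a spectrum")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  xf <- stats::fft(ts)
  half <- floor(n / 2)
  idx <- seq_len(half + 1L)
  amp <- Mod(xf[idx]) / n
  scale <- rep(sqrt(2), half + 1L)
  scale[1L] <- 1
  if (n %% 2L == 0L) scale[half + 1L] <- 1
  amp <- amp * scale
  list(frequency = (idx - 1L) / (n * dt), amplitude = amp,
       is_dc = idx == 1L)
}
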