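#' Surface regional homogeneity (ReHo) map
#'
#' For every vertex, ReHo is the average Pearson correlation over all
#' unordered pairs of distinct time courses in its k-hop neighbourhood
#' (centre vertex included). By default the series is band-pass filtered to
#' 0.01-0.1 Hz first, following the functional-connectivity convention for
#' this metric; pass `band = NULL` to compute on the series as given.
#'
#' Constant (zero-variance) vertices get ReHo 0 with a warning and are
#' excluded from the pair sets of their neighbours.
#'
#' @param series [vertex_series()].
#' @param mesh `surface_mesh` with matching vertex count.
#' @param hops neighbourhood radius in edge hops (1..6).
#' @param band [band_spec()] applied before computing correlations, or
#'   `NULL` for no filtering.
#' @return [vertex_map()] of kind `"reho"`.
#' @export
reho_map <- function(series, mesh, hops = 2L, band = band_spec(0.01, 0.1)) {
  stopifnot(inherits(series, "vertex_series"), inherits(mesh, "surface_mesh"))
  if (length(hops) != 1L || is.na(hops) || hops < 1) stop("hops must be >= 1")
  if (hops > 6) stop("hops larger than 6 are not supported")
  if (series$n_vertices != mesh$n_vertices) {
    stop("series vertex count does not match mesh")
  }
  if (!is.null(band)) series <- bandpass(series, band)
  x <- series$data
  n_t <- ncol(x)
  sds <- sqrt(rowSums((x - rowMeans(x))^2) / (n_t - 1))
  degenerate <- sds == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " constant vertex time course(s); ReHo set to 0")
  }
  xs <- (x - rowMeans(x)) / ifelse(degenerate, 1, sds)
  xs[degenerate, ] <- 0
  cmat <- tcrossprod(xs) / (n_t - 1)
  hoods <- khop_neighborhoods(mesh, hops)
  vals <- vapply(seq_len(series$n_vertices), function(v) {
    if (degenerate[v]) return(0)
    nb <- hoods[[v]]
    nb <- nb[!degenerate[nb]]
    m <- length(nb)
    if (m < 2L) return(0)
    (sum(cmat[nb, nb]) - m) / (m * (m - 1))
  }, numeric(1))
  vertex_map(pmin(1, pmax(-1, vals)), "reho")
}

#' Fractional amplitude of low-frequency fluctuations (fALFF) map
#'
#' Per vertex, the sum of spectral amplitudes (square root of periodogram
#' power) over the low band divided by the sum over the full band, DC
#' excluded from both. By default only the mean is removed before the
#' transform: subtracting a fitted line from trend-free data injects
#' broadband leakage (a pure in-band sinusoid would lose several percent of
#' its amplitude fraction), so linear detrending is opt-in for data with
#' real scanner drift. Constant vertices get fALFF 0 with a warning.
#'
#' @param series [vertex_series()].
#' @param low_band [band_spec()], default 0.01-0.05 Hz.
#' @param full_band [band_spec()], default 0 Hz to Nyquist; must contain
#'   `low_band` and stay at or below Nyquist.
#' @param detrend `"mean"` (default) or `"linear"`.
#' @return [vertex_map()] of kind `"falff"`.
#' @export
falff_map <- function(series, low_band = band_spec(0.01, 0.05),
                      full_band = NULL, detrend = c("mean", "linear")) {
  detrend <- match.arg(detrend)
  stopifnot(inherits(series, "vertex_series"), inherits(low_band, "band_spec"))
  nyq <- 1 / (2 * series$dt)
  if (is.null(full_band)) {
    full_band <- structure(list(low_hz = 0, high_hz = nyq), class = "band_spec")
  }
  tol <- 1e-12
  if (low_band$low_hz < full_band$low_hz - tol ||
      low_band$high_hz > full_band$high_hz + tol) {
    stop("low_band must be contained in full_band")
  }
  if (full_band$high_hz > nyq + tol) stop("full_band exceeds Nyquist")
  n <- series$n_timepoints
  m <- t(series$data)
  m <- if (detrend == "linear") detrend_columns(m) else
    sweep(m, 2L, colMeans(m))
  xf <- stats::mvfft(m)
  half <- floor(n / 2)
  amp <- Mod(xf[seq_len(half + 1L), , drop = FALSE]) / n
  freq <- (0:half) / (n * series$dt)
  in_band <- function(b) freq >= b$low_hz - tol & freq <= b$high_hz + tol & freq > tol
  low_sum <- colSums(amp[in_band(low_band), , drop = FALSE])
  full_sum <- colSums(amp[in_band(full_band), , drop = FALSE])
  zero <- full_sum == 0
  if (any(zero)) {
    warning(sum(zero), " constant vertex time course(s); fALFF set to 0")
  }
  vals <- ifelse(zero, 0, low_sum / pmax(full_sum, .Machine$double.xmin))
  vertex_map(pmin(1, pmax(0, vals)), "falff")
}

#' Write a vertex map as TSV
#'
#' Columns `vertex` (1-based) and `value`.
#'
#' @param map [vertex_map()].
#' @param path output file.
#' @export
write_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "vertex_map"))
  utils::write.table(
    data.frame(vertex = seq_len(map$n_vertices), value = map$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
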