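#' Vertex-wise BOLD time series
#'
#' @param data numeric matrix (n_vertices x n_timepoints), arbitrary BOLD
#'   units; each row is one vertex's time course.
#' @param dt sampling interval in seconds (the TR).
#' @return object of class `vertex_series` with fields `data`, `dt`,
#'   `n_vertices`, `n_timepoints`.
#' @export
vertex_series <- function(data, dt) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 2L) stop("a vertex series needs at least 2 timepoints")
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0) {
    stop("dt must be a positive number (seconds)")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("vertex series contains missing or non-finite values")
  }
  structure(list(data = data, dt = dt, n_vertices = nrow(data),
                 n_timepoints = ncol(data)),
            class = "vertex_series")
}

#' @export
print.vertex_series <- function(x, ...) {
  cat(sprintf("vertex_series: %d vertices x %d timepoints, dt = %g s\n",
              x$n_vertices, x$n_timepoints, x$dt))
  invisible(x)
}

#' Scalar map over mesh vertices
#'
#' One value per vertex: a ReHo map, a fALFF map, a component z-map or a
#' statistical t-map. Range invariants of the metric kinds are enforced
#' (ReHo is a mean correlation, fALFF a spectral fraction).
#'
#' @param values numeric vector, one value per vertex; must be finite.
#' @param kind one of `"reho"`, `"falff"`, `"zmap"`, `"tmap"`.
#' @return object of class `vertex_map`.
#' @export
vertex_map <- function(values, kind = c("zmap", "reho", "falff", "tmap")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("vertex map must be finite everywhere")
  }
  tol <- 1e-8
  if (kind == "reho" && (any(values < -1 - tol) || any(values > 1 + tol))) {
    stop("ReHo values must lie in [-1, 1]")
  }
  if (kind == "falff" && (any(values < -tol) || any(values > 1 + tol))) {
    stop("fALFF values must lie in [0, 1]")
  }
  structure(list(values = values, kind = kind, n_vertices = length(values)),
            class = "vertex_map")
}

#' @export
print.vertex_map <- function(x, ...) {
  cat(sprintf("vertex_map (%s): %d vertices, range [%.4g, %.4g]\n",
              x$kind, x$n_vertices, min(x$values), max(x$values)))
  invisible(x)
}

#' Save / load surface data
#'
#' Two dialects, selected by file extension:
#' * `.rds` — the lossless native archive (named fields `data`/`values` and
#'   `dt`/`kind`); round trips bit-exactly.
#' * `.gii` — GIFTI functional file (`.func.gii`); values are stored as
#'   float32, so round trips are exact only to single precision.
#'
#' @param x a [vertex_series()] or [vertex_map()].
#' @param path output file path (`.rds` or `.gii`).
#' @export
save_surface_data <- function(x, path) {
  if (!inherits(x, "vertex_series") && !inherits(x, "vertex_map")) {
    stop("x must be a vertex_series or vertex_map")
  }
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    if (inherits(x, "vertex_series")) {
      saveRDS(list(type = "vertex_series", data = x$data, dt = x$dt), path)
    } else {
      saveRDS(list(type = "vertex_map", values = x$values, kind = x$kind), path)
    }
  } else if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    write_gifti_data(x, path)
  } else {
    stop("unknown surface-data extension (expected .rds or .gii): ", path)
  }
  invisible(path)
}

#' @param mesh optional `surface_mesh`; when given, the loaded vertex count
#'   must match `mesh$n_vertices`.
#' @return `load_surface_data()` returns a [vertex_series()] or
#'   [vertex_map()].
#' @rdname save_surface_data
#' @export
load_surface_data <- function(path, mesh = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- readRDS(path)
    out <- if (identical(obj$type, "vertex_series")) {
      vertex_series(obj$data, obj$dt)
    } else if (identical(obj$type, "vertex_map")) {
      vertex_map(obj$values, obj$kind)
    } else {
      stop("not a surface-data archive: ", path)
    }
  } else if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    out <- read_gifti_data(path)
  } else {
    stop("unknown surface-data extension (expected .rds or .gii): ", path)
  }
  n <- if (inherits(out, "vertex_series")) out$n_vertices else out$n_vertices
  if (!is.null(mesh) && n != mesh$n_vertices) {
    stop(sprintf("vertex count mismatch: file has %d vertices, mesh has %d",
                 n, mesh$n_vertices))
  }
  out
}
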