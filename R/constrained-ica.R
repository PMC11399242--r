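#' Reference spatial component set
#'
#' Spatial reference maps (one per network) that guide constrained ICA.
#' Each map is internally centred and scaled to zero mean, unit variance
#' across vertices.
#'
#' @param maps numeric matrix (n_components x n_vertices), one reference per
#'   row, or a single numeric vector.
#' @param names optional component labels.
#' @return object of class `reference_set`.
#' @export
reference_set <- function(maps, names = NULL) {
  if (is.vector(maps)) maps <- matrix(maps, nrow = 1L)
  maps <- unname(as.matrix(maps))
  storage.mode(maps) <- "double"
  sds <- apply(maps, 1L, stats::sd)
  if (any(sds == 0)) stop("constant reference map(s)")
  maps <- (maps - rowMeans(maps)) / sds
  if (is.null(names)) names <- sprintf("net%02d", seq_len(nrow(maps)))
  structure(list(maps = maps, names = names, n_components = nrow(maps),
                 n_vertices = ncol(maps)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d components x %d vertices\n",
              x$n_components, x$n_vertices))
  invisible(x)
}

#' Constrained ICA configuration
#'
#' @param n_pcs number of principal components retained before extraction.
#' @param rho_min minimum correlation each extracted spatial component must
#'   keep with its reference.
#' @param max_iter maximum fixed-point iterations per component.
#' @param tol convergence tolerance on the weight-vector change.
#' @param lowpassed declarative flag: the caller asserts the series was
#'   already low-pass filtered (0.2 Hz in the standard pipeline).
#' @return list of class `cica_config`.
#' @export
cica_config <- function(n_pcs = 30L, rho_min = 0.2, max_iter = 500L,
                        tol = 1e-6, lowpassed = TRUE) {
  stopifnot(n_pcs >= 1L, rho_min > 0, rho_min < 1, max_iter >= 1L, tol > 0)
  structure(list(n_pcs = as.integer(n_pcs), rho_min = rho_min,
                 max_iter = as.integer(max_iter), tol = tol,
                 lowpassed = isTRUE(lowpassed)),
            class = "cica_config")
}

# Top-q eigenpairs of a symmetric PSD matrix. Small problems use the exact
# LAPACK decomposition; large ones a seeded randomized subspace iteration
# (Gaussian sketch, two power iterations), accurate to working precision for
# the well-separated leading spectrum that PCA dimension reduction needs.
top_eigen <- function(cv, q) {
  n <- nrow(cv)
  if (n <= max(4L * q, 120L)) {
    eg <- eigen(cv, symmetric = TRUE)
    return(list(values = eg$values[seq_len(q)],
                vectors = eg$vectors[, seq_len(q), drop = FALSE]))
  }
  p <- min(n, q + 12L)
  omega <- matrix(stats::rnorm(n * p), n, p)
  y <- cv %*% omega
  y <- cv %*% (cv %*% y)
  qq <- qr.Q(qr(y))
  small <- crossprod(qq, cv %*% qq)
  eg <- eigen((small + t(small)) / 2, symmetric = TRUE)
  list(values = eg$values[seq_len(q)],
       vectors = (qq %*% eg$vectors)[, seq_len(q), drop = FALSE])
}

#' Reference-constrained spatial ICA
#'
#' Extracts one spatially independent component per reference map from a
#' vertex time series, in the spatial-ICA orientation (components are vertex
#' maps; mixing happens over time). Each component maximizes an approximate
#' negentropy (log-cosh contrast, FastICA-style one-unit fixed point) under
#' the constraint that its correlation with the assigned reference stays at
#' or above `rho_min`; the constraint enters as a penalty term whose weight
#' doubles whenever it is violated. Components are extracted sequentially
#' with Gram-Schmidt decorrelation, initialized from the reference projected
#' into whitened space, and sign-aligned to positive reference correlation.
#'
#' The caller is expected to low-pass filter the series first (0.2 Hz in the
#' standard pipeline), recorded by `config$lowpassed`.
#'
#' @param series [vertex_series()] with more timepoints than components.
#' @param refs [reference_set()] with matching vertex count.
#' @param config [cica_config()].
#' @param seed integer seed for the random fallback initialization.
#' @return object of class `cica_result`: `spatial_zmaps` (n_components x
#'   n_vertices, each row mean 0 sd 1), `timecourses` (n_components x
#'   n_timepoints), `similarity` (correlation with reference after sign
#'   alignment), `converged`, `iterations`, `config`.
#' @export
fit_cica <- function(series, refs, config = cica_config(), seed = 1L) {
  stopifnot(inherits(series, "vertex_series"), inherits(refs, "reference_set"),
            inherits(config, "cica_config"))
  if (refs$n_vertices != series$n_vertices) {
    stop("reference maps do not match the series vertex count")
  }
  n_comp <- refs$n_components
  n_t <- series$n_timepoints
  n_v <- series$n_vertices
  if (n_t <= n_comp) stop("need more timepoints than components")

  # variables = timepoints, samples = vertices: centre each timepoint map
  m <- t(series$data)                       # n_t x n_v
  m <- m - rowMeans(m)
  cv <- tcrossprod(m) / n_v                 # n_t x n_t covariance
  q <- min(config$n_pcs, n_t - 1L, n_v - 1L)
  set.seed(as.integer(seed))
  eg <- top_eigen(cv, q)
  pos <- eg$values
  if (any(pos < max(pos) * 1e-10)) {
    stop("rank-deficient data: fewer than n_pcs informative components")
  }
  k <- t(eg$vectors) / sqrt(pos)            # q x n_t
  y <- k %*% m                              # q x n_v, whitened: yy'/n_v = I

  refs_m <- refs$maps
  w_all <- matrix(0, q, n_comp)
  zmaps <- matrix(0, n_comp, n_v)
  sims <- numeric(n_comp)
  conv <- logical(n_comp)
  iters <- integer(n_comp)
  set.seed(as.integer(seed))

  decorrelate <- function(w, j) {
    if (j > 1L) {
      prev <- w_all[, seq_len(j - 1L), drop = FALSE]
      w <- w - prev %*% crossprod(prev, w)
    }
    nrm <- sqrt(sum(w^2))
    if (nrm < 1e-12) return(NULL)
    w / nrm
  }

  for (j in seq_len(n_comp)) {
    r_vec <- as.vector(y %*% refs_m[j, ]) / n_v  # corr(w'y, ref) = w'r_vec
    align <- function(w) if (sum(w * r_vec) < 0) -w else w
    w <- decorrelate(matrix(r_vec, ncol = 1L), j)
    if (is.null(w)) w <- decorrelate(matrix(stats::rnorm(q), ncol = 1L), j)
    w <- align(w)
    lambda <- 1
    converged <- FALSE
    it <- 0L
    while (it < config$max_iter) {
      it <- it + 1L
      s <- as.vector(crossprod(w, y))
      gs <- tanh(s)
      w_new <- (y %*% gs) / n_v - mean(1 - gs^2) * w
      # penalty on the inequality constraint corr(s, ref) >= rho_min;
      # the weight doubles whenever the constraint is violated
      if (sum(w * r_vec) < config$rho_min) {
        w_new <- align(w_new) + lambda * r_vec
        lambda <- lambda * 2
      }
      w_new <- decorrelate(w_new, j)
      if (is.null(w_new)) {
        w_new <- decorrelate(matrix(stats::rnorm(q), ncol = 1L), j)
        next
      }
      w_new <- align(w_new)
      delta <- 1 - abs(sum(w_new * w))
      w <- w_new
      if (delta < config$tol) {
        converged <- TRUE
        break
      }
    }
    s <- as.vector(crossprod(w, y))
    rho <- stats::cor(s, refs_m[j, ])
    if (rho < 0) {
      w <- -w
      s <- -s
      rho <- -rho
    }
    w_all[, j] <- w
    zmaps[j, ] <- (s - mean(s)) / stats::sd(s)
    sims[j] <- rho
    conv[j] <- converged
    iters[j] <- it
  }

  tcs <- m %*% t(zmaps) / n_v               # n_t x n_comp covariances
  structure(list(
    spatial_zmaps = zmaps,
    timecourses = t(tcs),
    similarity = sims,
    converged = conv,
    iterations = iters,
    names = refs$names,
    config = config
  ), class = "cica_result")
}

#' @export
print.cica_result <- function(x, ...) {
  cat(sprintf("cica_result: %d components, similarity %s, %d/%d converged\n",
              nrow(x$spatial_zmaps),
              paste(sprintf("%.2f", x$similarity), collapse = "/"),
              sum(x$converged), length(x$converged)))
  invisible(x)
}

#' Threshold a component z-map
#'
#' @param zmap [vertex_map()] or numeric vector of z values.
#' @param z_abs non-negative absolute threshold.
#' @return logical vertex mask, `TRUE` where `|z| >= z_abs`.
#' @export
threshold_zmap <- function(zmap, z_abs = 2) {
  if (inherits(zmap, "vertex_map")) zmap <- zmap$values
  if (!is.numeric(z_abs) || length(z_abs) != 1L || z_abs < 0) {
    stop("z_abs must be a non-negative number")
  }
  abs(zmap) >= z_abs
}

#' Save / load a constrained-ICA result bundle
#'
#' The bundle is a directory with the arrays in the lossless archive dialect
#' and a JSON metadata file (configuration, similarities, convergence).
#'
#' @param x `cica_result`.
#' @param dir output directory (created if missing).
#' @export
save_cica_result <- function(x, dir) {
  stopifnot(inherits(x, "cica_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(spatial_zmaps = x$spatial_zmaps, timecourses = x$timecourses),
          file.path(dir, "arrays.rds"))
  meta <- list(names = x$names, similarity = x$similarity,
               converged = x$converged, iterations = x$iterations,
               config = unclass(x$config))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_cica_result
#' @export
load_cica_result <- function(dir) {
  arrays <- readRDS(file.path(dir, "arrays.rds"))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  structure(list(
    spatial_zmaps = arrays$spatial_zmaps, timecourses = arrays$timecourses,
    similarity = meta$similarity, converged = meta$converged,
    iterations = meta$iterations, names = meta$names,
    config = do.call(cica_config, meta$config)
  ), class = "cica_result")
}
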