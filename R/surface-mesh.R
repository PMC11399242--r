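#' Triangulated surface mesh
#'
#' Container for a cortical-style triangle mesh: vertex coordinates in mm,
#' triangle faces (1-based vertex indices), and the undirected vertex
#' adjacency graph induced by the faces. The adjacency graph is the substrate
#' for k-hop neighbourhoods (ReHo) and for approximate-geodesic Gaussian
#' smoothing.
#'
#' @param vertices numeric matrix (n_vertices x 3) of coordinates in mm.
#' @param faces integer matrix (n_faces x 3) of 1-based vertex indices.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `n_vertices`, `edges` (unique undirected edge list),
#'   `edge_lengths` (Euclidean, mm) and `graph` (igraph).
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- unname(as.matrix(vertices))
  storage.mode(vertices) <- "double"
  faces <- unname(as.matrix(faces))
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n)) {
    stop("face vertex index out of range [1, n_vertices]")
  }
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(1L, 3L)])
  key <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  edges <- key[!duplicated(key), , drop = FALSE]
  if (any(edges[, 1L] == edges[, 2L])) stop("degenerate face with repeated vertex")
  lens <- sqrt(rowSums((vertices[edges[, 1L], , drop = FALSE] -
                          vertices[edges[, 2L], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  structure(
    list(vertices = vertices, faces = faces, n_vertices = n,
         edges = edges, edge_lengths = lens, graph = g),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, %d edges\n",
              x$n_vertices, nrow(x$faces), nrow(x$edges)))
  invisible(x)
}

#' Triangulated rectangular grid mesh
#'
#' Deterministic planar mesh: `nx` x `ny` vertices on a regular grid with the
#' given spacing (mm), each cell split into two right triangles. Vertex index
#' of grid position (ix, iy) is `(iy - 1) * nx + ix`.
#'
#' @param nx,ny grid dimensions (vertices per row / column), both >= 2.
#' @param spacing_mm grid spacing in mm.
#' @return `surface_mesh`.
#' @export
grid_mesh <- function(nx, ny, spacing_mm = 2) {
  stopifnot(nx >= 2L, ny >= 2L, spacing_mm > 0)
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  vertices <- cbind((ix - 1) * spacing_mm, (iy - 1) * spacing_mm, 0)
  id <- function(ix, iy) (iy - 1L) * nx + ix
  cx <- rep(seq_len(nx - 1L), times = ny - 1L)
  cy <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- id(cx, cy); b <- id(cx + 1L, cy)
  cc <- id(cx, cy + 1L); d <- id(cx + 1L, cy + 1L)
  faces <- rbind(cbind(a, b, d), cbind(a, d, cc))
  surface_mesh(vertices, faces)
}

#' Icosphere mesh
#'
#' Deterministic closed mesh: regular icosahedron subdivided `subdivisions`
#' times (each triangle into four, midpoints projected onto the sphere).
#' Subdivision levels 0..4 give 12, 42, 162, 642, 2562 vertices.
#'
#' @param subdivisions non-negative integer.
#' @param radius_mm sphere radius in mm.
#' @return `surface_mesh`.
#' @export
icosphere_mesh <- function(subdivisions = 2, radius_mm = 50) {
  stopifnot(subdivisions >= 0L, radius_mm > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(parent = emptyenv())
    get_mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      idx <- nrow(v)
      assign(key, idx, envir = midpoint_cache)
      idx
    }
    newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; cc <- f[k, 3L]
      ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
      newf[(4L * (k - 1L) + 1L):(4L * k), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  surface_mesh(v * radius_mm, f)
}

#' k-hop neighbourhood of a vertex
#'
#' All vertices reachable from `vertex` in at most `hops` edge steps on the
#' mesh adjacency graph, including the centre vertex itself. This is the
#' neighbourhood definition used by the surface ReHo map.
#'
#' @param mesh `surface_mesh`.
#' @param vertex 1-based vertex index.
#' @param hops positive integer neighbourhood radius in edge hops.
#' @return sorted integer vector of vertex indices (centre included).
#' @export
khop_neighborhood <- function(mesh, vertex, hops) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (length(vertex) != 1L || is.na(vertex) || vertex < 1 || vertex > mesh$n_vertices) {
    stop("vertex index out of range")
  }
  if (length(hops) != 1L || is.na(hops) || hops < 1) stop("hops must be >= 1")
  nb <- igraph::ego(mesh$graph, order = hops, nodes = vertex)[[1L]]
  sort(as.integer(nb))
}

#' k-hop neighbourhoods of all vertices
#'
#' @param mesh `surface_mesh`.
#' @param hops positive integer.
#' @return list of sorted integer vectors, one per vertex (centre included).
#' @export
khop_neighborhoods <- function(mesh, hops) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (length(hops) != 1L || is.na(hops) || hops < 1) stop("hops must be >= 1")
  lapply(igraph::ego(mesh$graph, order = hops),
         function(v) sort(as.integer(v)))
}

#' Geodesic Gaussian smoothing operator
#'
#' Sparse smoothing matrix built from a Gaussian kernel on approximate
#' geodesic distances (shortest edge paths, Dijkstra with Euclidean edge
#' weights), truncated at 3 standard deviations. `sigma_mm =
#' fwhm_mm / (2 sqrt(2 ln 2))`.
#'
#' Two normalizations are available. `"balanced"` (default) applies symmetric
#' Sinkhorn balancing so the operator is doubly stochastic: every vertex's
#' weights sum to 1 *and* the global mean of any map is preserved exactly,
#' including on closed meshes. `"row"` divides each row by its sum only; it
#' reproduces the truncated Gaussian kernel shape exactly around any vertex
#' but does not conserve the mean near irregular vertices or boundaries.
#'
#' @param mesh `surface_mesh`.
#' @param fwhm_mm kernel full width at half maximum, mm (> 0).
#' @param normalize `"balanced"` or `"row"`.
#' @return sparse `dgCMatrix` (n_vertices x n_vertices).
#' @export
smoothing_operator <- function(mesh, fwhm_mm, normalize = c("balanced", "row")) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0) {
    stop("fwhm_mm must be a positive number")
  }
  normalize <- match.arg(normalize)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- igraph::distances(mesh$graph, weights = mesh$edge_lengths)
  keep <- d <= 3 * sigma
  k <- matrix(0, nrow(d), ncol(d))
  k[keep] <- exp(-d[keep]^2 / (2 * sigma^2))
  if (normalize == "row") {
    w <- k / rowSums(k)
  } else {
    # symmetric Sinkhorn: K stays symmetric, converges to doubly stochastic
    s <- rep(1, nrow(k))
    for (i in seq_len(500L)) {
      rs <- as.vector((k * outer(s, s)) %*% rep(1, length(s)))
      if (max(abs(rs - 1)) < 1e-13) break
      s <- s / sqrt(rs)
    }
    w <- k * outer(s, s)
    w <- w / rowSums(w) # residual correction, rowSums already ~1
  }
  methods::as(Matrix::Matrix(w, sparse = TRUE), "CsparseMatrix")
}

#' Smooth a vertex map or vertex series on the surface
#'
#' Gaussian-weighted averaging over approximate-geodesic neighbourhoods; see
#' [smoothing_operator()] for the kernel. Accepts a numeric vector (one value
#' per vertex), a matrix (vertices x anything), a [vertex_map()] or a
#' [vertex_series()], and returns the same shape.
#'
#' @param x data to smooth.
#' @param mesh `surface_mesh`.
#' @param fwhm_mm kernel FWHM in mm (> 0).
#' @param operator optional precomputed [smoothing_operator()] (overrides
#'   `fwhm_mm`); pass this when smoothing many sessions on one mesh.
#' @param normalize see [smoothing_operator()].
#' @return object of the same class/shape as `x`.
#' @export
smooth_surface <- function(x, mesh, fwhm_mm = 3, operator = NULL,
                           normalize = c("balanced", "row")) {
  if (is.null(operator)) {
    operator <- smoothing_operator(mesh, fwhm_mm, match.arg(normalize))
  }
  apply_op <- function(values) {
    if (is.matrix(values)) as.matrix(operator %*% values)
    else as.vector(operator %*% values)
  }
  if (inherits(x, "vertex_series")) {
    vertex_series(apply_op(x$data), x$dt)
  } else if (inherits(x, "vertex_map")) {
    vertex_map(apply_op(x$values), x$kind)
  } else {
    apply_op(x)
  }
}
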