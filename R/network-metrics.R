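#' Functional connectivity matrix
#'
#' Pearson correlation between all pairs of ROI time courses. The diagonal is
#' 1 by convention and ignored by every graph metric.
#'
#' @param parcels [parcel_series()].
#' @return object of class `fc_matrix` (field `r`: symmetric n_rois x n_rois
#'   correlation matrix with ROI ids as dimnames).
#' @export
compute_fc <- function(parcels) {
  stopifnot(inherits(parcels, "parcel_series"))
  sds <- apply(parcels$data, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI time course(s): ",
         paste(parcels$roi_ids[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(parcels$data))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(parcels$roi_ids, parcels$roi_ids)
  structure(list(r = r, n_rois = nrow(r)), class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("fc_matrix: %d ROIs, off-diagonal r in [%.3f, %.3f]\n",
              x$n_rois, min(off), max(off)))
  invisible(x)
}

#' Binarize an FC matrix at threshold sigma
#'
#' An edge (i, j) is present iff `r[i, j] > sigma` for `i != j`. The
#' threshold is applied to the signed correlation, not its absolute value.
#'
#' @param fc [compute_fc()] result.
#' @param sigma correlation threshold in (-1, 1).
#' @return object of class `binary_graph` (logical symmetric `adjacency`
#'   with zero diagonal, plus the `sigma` used).
#' @export
binarize <- function(fc, sigma) {
  stopifnot(inherits(fc, "fc_matrix"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= -1 || sigma >= 1) {
    stop("sigma must lie in (-1, 1)")
  }
  adj <- fc$r > sigma
  diag(adj) <- FALSE
  binary_graph(adj, sigma = sigma)
}

#' Binary graph container
#'
#' @param adjacency symmetric logical (or 0/1) matrix; the diagonal is
#'   forced to zero.
#' @param sigma threshold recorded with the graph (optional).
#' @return object of class `binary_graph`.
#' @export
binary_graph <- function(adjacency, sigma = NA_real_) {
  adj <- as.matrix(adjacency) != 0
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square")
  if (!isTRUE(all(adj == t(adj)))) stop("adjacency must be symmetric")
  diag(adj) <- FALSE
  structure(list(adjacency = adj, sigma = sigma, n_nodes = nrow(adj)),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("binary_graph: %d nodes, %d edges (sigma = %s)\n",
              x$n_nodes, sum(x$adjacency) / 2, format(x$sigma)))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

#' Edge density of a binary graph
#'
#' Fraction of realized edges among all `N(N-1)/2` possible node pairs
#' (isolated nodes included in the denominator).
#'
#' @param g [binary_graph()].
#' @return fraction in \code{[0, 1]}.
#' @export
edge_density <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  n <- g$n_nodes
  if (n < 2L) return(0)
  (sum(g$adjacency) / 2) / (n * (n - 1) / 2)
}

#' Global efficiency
#'
#' Mean over ordered distinct node pairs of the inverse shortest-path length,
#' with disconnected pairs contributing 0.
#'
#' @param g [binary_graph()].
#' @return value in \code{[0, 1]}.
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  n <- g$n_nodes
  if (n < 2L || sum(g$adjacency) == 0) return(0)
  d <- igraph::distances(as_igraph(g))
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over all nodes of the global efficiency of the subgraph induced by
#' each node's neighbours; nodes with fewer than 2 neighbours contribute 0.
#'
#' @param g [binary_graph()].
#' @return value in \code{[0, 1]}.
#' @export
local_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  n <- g$n_nodes
  if (n == 0L) return(0)
  adj <- g$adjacency
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2L) return(0)
    sub <- binary_graph(adj[nb, nb, drop = FALSE])
    global_efficiency(sub)
  }, numeric(1))
  mean(vals)
}

#' Rich-club coefficient
#'
#' With `S` the set of nodes of degree strictly greater than `k`,
#' `phi(k) = 2 E(S) / (|S| (|S| - 1))` where `E(S)` counts edges inside `S`.
#' Returns `NA` (flagged, not an error) when fewer than 2 nodes survive.
#' No random-graph normalization is applied.
#'
#' @param g [binary_graph()].
#' @param k non-negative degree cutoff.
#' @return `phi(k)` in \code{[0, 1]}, or `NA` when undefined.
#' @export
rich_club <- function(g, k) {
  stopifnot(inherits(g, "binary_graph"))
  if (!is.numeric(k) || length(k) != 1L || k < 0) stop("k must be >= 0")
  deg <- colSums(g$adjacency)
  s <- deg > k
  ns <- sum(s)
  if (ns < 2L) return(NA_real_)
  sum(g$adjacency[s, s]) / (ns * (ns - 1))
}

#' Rich-club curve
#'
#' `phi(k)` for `k = 0..max(degree)`; entries are `NA` where undefined.
#'
#' @param g [binary_graph()].
#' @return named numeric vector, names `k0`, `k1`, ...
#' @export
rich_club_curve <- function(g) {
  kmax <- max(c(0L, colSums(g$adjacency)))
  phi <- vapply(0:kmax, function(k) rich_club(g, k), numeric(1))
  names(phi) <- paste0("k", 0:kmax)
  phi
}

#' Largest degree cutoff with a defined rich-club coefficient in every graph
#'
#' The largest `k` such that `phi(k')` is defined for every graph in the
#' collection at every `k' <= k`. Because the surviving set shrinks
#' monotonically with `k`, this is the minimum over graphs of each graph's
#' largest defined cutoff. Returns `-1` if some graph has no defined cutoff
#' at all (fewer than 2 non-isolated nodes).
#'
#' @param graphs non-empty list of [binary_graph()] objects.
#' @return integer.
#' @export
max_common_k <- function(graphs) {
  if (!is.list(graphs) || length(graphs) == 0L) {
    stop("graphs must be a non-empty list of binary graphs")
  }
  per_graph <- vapply(graphs, function(g) {
    stopifnot(inherits(g, "binary_graph"))
    deg <- colSums(g$adjacency)
    ks <- -1L
    for (k in 0:max(c(0L, deg))) {
      if (sum(deg > k) >= 2L) ks <- k else break
    }
    ks
  }, integer(1))
  min(per_graph)
}

#' Nodal graph metrics
#'
#' Per-node degree, nodal efficiency (mean inverse distance to every other
#' node, disconnected pairs contributing 0) and betweenness centrality
#' (Brandes fractional counting, endpoints excluded, normalized by
#' `(N-1)(N-2)/2`).
#'
#' @param g [binary_graph()].
#' @return data.frame with columns `node`, `degree`, `efficiency`,
#'   `betweenness`.
#' @export
nodal_metrics <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  n <- g$n_nodes
  ig <- as_igraph(g)
  deg <- as.integer(colSums(g$adjacency))
  if (n < 2L) {
    return(data.frame(node = seq_len(n), degree = deg,
                      efficiency = numeric(n), betweenness = numeric(n)))
  }
  d <- igraph::distances(ig)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  eff <- rowSums(inv) / (n - 1)
  btw <- igraph::betweenness(ig, directed = FALSE, normalized = n > 2L)
  data.frame(node = seq_len(n), degree = deg, efficiency = eff,
             betweenness = as.numeric(btw))
}

#' Whole-graph summary
#'
#' @param g [binary_graph()].
#' @return object of class `graph_summary`: edge density, global and local
#'   efficiency, rich-club curve and nodal metrics.
#' @export
graph_summary <- function(g) {
  structure(list(
    sigma = g$sigma,
    edge_density = edge_density(g),
    global_efficiency = global_efficiency(g),
    local_efficiency = local_efficiency(g),
    rich_club = rich_club_curve(g),
    nodal = nodal_metrics(g)
  ), class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf(
    "graph_summary (sigma = %s): density %.3f, E_glob %.3f, E_loc %.3f\n",
    format(x$sigma), x$edge_density, x$global_efficiency,
    x$local_efficiency))
  invisible(x)
}

#' Serialize an FC matrix to long-format TSV
#'
#' Columns `roi_i`, `roi_j`, `r` over unordered pairs `i < j`.
#'
#' @param fc [compute_fc()] result.
#' @param path output file.
#' @export
write_fc_tsv <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  idx <- which(upper.tri(fc$r), arr.ind = TRUE)
  df <- data.frame(roi_i = rownames(fc$r)[idx[, 1L]],
                   roi_j = colnames(fc$r)[idx[, 2L]],
                   r = fc$r[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an FC matrix from long-format TSV
#'
#' @param path TSV written by [write_fc_tsv()].
#' @return `fc_matrix`.
#' @export
read_fc_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ids <- sort(unique(c(df$roi_i, df$roi_j)))
  r <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  r[cbind(df$roi_i, df$roi_j)] <- df$r
  r[cbind(df$roi_j, df$roi_i)] <- df$r
  structure(list(r = r, n_rois = length(ids)), class = "fc_matrix")
}

#' Serialize a graph summary to JSON
#'
#' @param x [graph_summary()].
#' @param path output file.
#' @export
write_graph_summary_json <- function(x, path) {
  stopifnot(inherits(x, "graph_summary"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}
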