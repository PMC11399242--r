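# Independent brute-force oracles: pure loops over pairs and paths, no
# igraph, no package graph code. Used to cross-check every network metric.

bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in seq_len(n)) {
          if (adj[v, u] && is.infinite(d[s, u])) {
            d[s, u] <- dist + 1
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      dist <- dist + 1
    }
  }
  d
}

bf_edge_density <- function(adj) {
  n <- nrow(adj)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (adj[i, j]) e <- e + 1
  e / (n * (n - 1) / 2)
}

bf_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- bf_distances(adj)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  }
  tot / (n * (n - 1))
}

bf_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    if (length(nb) >= 2) {
      vals[i] <- bf_global_efficiency(adj[nb, nb, drop = FALSE])
    }
  }
  mean(vals)
}

bf_rich_club <- function(adj, k) {
  deg <- rowSums(adj)
  s <- which(deg > k)
  if (length(s) < 2) return(NA_real_)
  e <- 0
  for (a in seq_along(s)) for (b in seq_along(s)) {
    if (a < b && adj[s[a], s[b]]) e <- e + 1
  }
  2 * e / (length(s) * (length(s) - 1))
}

# number of shortest paths between all pairs (dynamic programming over
# vertices in order of distance from the source)
bf_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(d[s, ])
    for (v in ord) {
      if (v == s || is.infinite(d[s, v])) next
      for (u in seq_len(n)) {
        if (adj[u, v] && d[s, u] == d[s, v] - 1) {
          sigma[s, v] <- sigma[s, v] + sigma[s, u]
        }
      }
    }
  }
  sigma
}

bf_betweenness <- function(adj, normalized = TRUE) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  sigma <- bf_path_counts(adj, d)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || is.infinite(d[s, t])) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  if (normalized && n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  btw
}

bf_nodal_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  vapply(seq_len(n), function(i) {
    tot <- 0
    for (j in seq_len(n)) if (j != i && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
    tot / (n - 1)
  }, numeric(1))
}

random_adjacency <- function(n, p = 0.5) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- adj[j, i] <- stats::runif(1) < p
  }
  adj
}

# amplitude of a sinusoid at a known frequency via least-squares fit
fitted_amplitude <- function(y, freq_hz, dt) {
  t <- (seq_along(y) - 1) * dt
  x1 <- sin(2 * pi * freq_hz * t)
  x2 <- cos(2 * pi * freq_hz * t)
  cf <- stats::coef(stats::lm(y ~ x1 + x2 - 1))
  sqrt(sum(cf^2))
}
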