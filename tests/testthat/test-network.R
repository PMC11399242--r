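make_graph <- function(adj) binary_graph(adj)

path_graph <- function(n) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  make_graph(adj)
}

complete_graph <- function(n) {
  adj <- matrix(TRUE, n, n)
  diag(adj) <- FALSE
  make_graph(adj)
}

star_graph <- function(n) {
  adj <- matrix(FALSE, n, n)
  adj[1, 2:n] <- adj[2:n, 1] <- TRUE
  make_graph(adj)
}

test_that("compute_fc reproduces Pearson correlations and flags zero variance", {
  ps <- parcel_series(rbind(c(1, 2, 3, 4), c(2, 4, 6, 8)), dt = 1)
  expect_equal(compute_fc(ps)$r[1, 2], 1)
  ps2 <- parcel_series(rbind(c(1, 2, 3, 4), c(4, 3, 2, 1)), dt = 1)
  expect_equal(compute_fc(ps2)$r[1, 2], -1)
  ps3 <- parcel_series(rbind(c(1, 2, 3), c(1, 3, 2)), dt = 1)
  expect_equal(compute_fc(ps3)$r[1, 2], 0.5)
  ps4 <- parcel_series(rbind(c(1, 2, 3), c(5, 5, 5)), dt = 1,
                       roi_ids = c("a", "bad_roi"))
  expect_error(compute_fc(ps4), "bad_roi")
})

test_that("binarize applies a signed threshold off the diagonal", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.6
  r[1, 3] <- r[3, 1] <- 0.4
  r[2, 3] <- r[3, 2] <- 0.7
  fc <- structure(list(r = r, n_rois = 3), class = "fc_matrix")
  g <- binarize(fc, 0.5)
  expect_equal(sum(g$adjacency) / 2, 2)
  expect_false(any(diag(g$adjacency)))
  g99 <- binarize(fc, 0.99)
  expect_equal(sum(g99$adjacency), 0)
  expect_error(binarize(fc, 1), "sigma")

  set.seed(31)
  rr <- stats::cor(matrix(rnorm(80), 10, 8))
  fc2 <- structure(list(r = rr, n_rois = 8), class = "fc_matrix")
  g2 <- binarize(fc2, 0.6)
  manual <- rr > 0.6
  diag(manual) <- FALSE
  expect_identical(g2$adjacency, manual)
})

test_that("whole-graph metrics match hand-derived values", {
  expect_equal(edge_density(complete_graph(4)), 1)
  expect_equal(edge_density(path_graph(4)), 0.5)
  expect_equal(edge_density(make_graph(matrix(FALSE, 3, 3))), 0)

  expect_equal(global_efficiency(complete_graph(5)), 1)
  expect_equal(global_efficiency(path_graph(3)), 5 / 6)
  expect_equal(global_efficiency(make_graph(matrix(FALSE, 2, 2))), 0)

  expect_equal(local_efficiency(complete_graph(3)), 1)
  expect_equal(local_efficiency(star_graph(5)), 0)
  expect_equal(local_efficiency(make_graph(matrix(FALSE, 4, 4))), 0)
})

test_that("rich club handles thresholds, degeneracy and max_common_k", {
  expect_equal(rich_club(complete_graph(4), 2), 1)
  # triangle plus pendant: S(k=1) is the triangle
  adj <- matrix(FALSE, 4, 4)
  adj[1, 2] <- adj[2, 3] <- adj[1, 3] <- adj[3, 4] <- TRUE
  adj <- adj | t(adj)
  expect_equal(rich_club(make_graph(adj), 1), 1)
  expect_true(is.na(rich_club(star_graph(5), 1)))
  expect_error(rich_club(complete_graph(3), -1), "k")

  expect_equal(max_common_k(list(complete_graph(4), complete_graph(4))), 2)
  expect_equal(max_common_k(list(complete_graph(4), star_graph(5))), 0)
  expect_error(max_common_k(list()), "non-empty")
})

test_that("nodal metrics match hand-derived cases", {
  nd <- nodal_metrics(path_graph(3))
  expect_equal(nd$betweenness, c(0, 1, 0))
  expect_equal(nd$degree, c(1, 2, 1))
  expect_equal(nd$efficiency, c((1 + 1 / 2) / 2, 1, (1 + 1 / 2) / 2))
  expect_equal(nodal_metrics(complete_graph(5))$betweenness, rep(0, 5))
})

test_that("all metrics agree with the exhaustive brute-force oracle", {
  set.seed(32)
  for (rep in 1:60) {
    n <- sample(3:7, 1)
    g <- make_graph(random_adjacency(n, runif(1, 0.2, 0.9)))
    adj <- g$adjacency
    expect_equal(edge_density(g), bf_edge_density(adj))
    expect_equal(global_efficiency(g), bf_global_efficiency(adj),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(g), bf_local_efficiency(adj),
                 tolerance = 1e-12)
    for (k in 0:max(1, max(rowSums(adj)))) {
      expect_equal(rich_club(g, k), bf_rich_club(adj, k))
    }
    nd <- nodal_metrics(g)
    expect_equal(nd$degree, as.integer(rowSums(adj)))
    expect_equal(nd$efficiency, bf_nodal_efficiency(adj), tolerance = 1e-12)
    expect_equal(nd$betweenness, bf_betweenness(adj), tolerance = 1e-12)
  }
})

test_that("raising sigma or removing edges never helps density or efficiency", {
  set.seed(33)
  for (rep in 1:20) {
    rr <- stats::cor(matrix(rnorm(10 * 40), 40, 10))
    fc <- structure(list(r = rr, n_rois = 10), class = "fc_matrix")
    gs <- lapply(c(0.1, 0.3, 0.5), function(s) binarize(fc, s))
    dens <- vapply(gs, edge_density, numeric(1))
    geff <- vapply(gs, global_efficiency, numeric(1))
    expect_true(all(diff(dens) <= 0))
    expect_true(all(diff(geff) <= 0))
    # adding one edge never decreases global efficiency
    g <- gs[[2]]
    off <- which(!g$adjacency & upper.tri(g$adjacency), arr.ind = TRUE)
    if (nrow(off) > 0) {
      pick <- off[sample(nrow(off), 1), ]
      adj2 <- g$adjacency
      adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- TRUE
      expect_gte(global_efficiency(make_graph(adj2)), global_efficiency(g))
    }
    # phi stays within [0, 1] where defined
    phi <- rich_club_curve(gs[[1]])
    expect_true(all(phi[!is.na(phi)] >= 0 & phi[!is.na(phi)] <= 1))
  }
})

test_that("FC matrices survive the TSV round trip", {
  set.seed(34)
  ps <- parcel_series(matrix(rnorm(5 * 60), 5, 60), dt = 1,
                      roi_ids = sprintf("r%02d", 1:5))
  fc <- compute_fc(ps)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fc_tsv(fc, f)
  back <- read_fc_tsv(f)
  expect_equal(back$r[fc$n_rois:1, fc$n_rois:1][fc$n_rois:1, fc$n_rois:1],
               fc$r, tolerance = 1e-12)
})

test_that("graph summaries assemble all metrics and serialize to JSON", {
  g <- binarize(structure(list(r = {
    r <- diag(4)
    r[upper.tri(r)] <- c(0.8, 0.7, 0.2, 0.9, 0.1, 0.75)
    r + t(r) - diag(4)
  }, n_rois = 4), class = "fc_matrix"), 0.5)
  gs <- graph_summary(g)
  expect_equal(gs$edge_density, edge_density(g))
  expect_equal(gs$global_efficiency, global_efficiency(g))
  expect_equal(unname(gs$rich_club["k0"]), rich_club(g, 0))
  expect_equal(nrow(gs$nodal), 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_graph_summary_json(gs, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$edge_density, gs$edge_density, tolerance = 1e-12)
  expect_equal(back$nodal$degree, gs$nodal$degree)
})
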