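# Simulation with sparse non-Gaussian spatial sources, smooth random
# mixing time courses, Gaussian noise, and noisy references.
make_cica_sim <- function(seed, n_v = 400, n_t = 300, n_src = 3,
                          snr = 5, ref_noise = 0.5) {
  set.seed(seed)
  sources <- matrix(0, n_src, n_v)
  for (j in seq_len(n_src)) {
    idx <- sample(n_v, round(0.1 * n_v))
    sources[j, idx] <- rexp(length(idx)) * sample(c(-1, 1), length(idx), TRUE)
  }
  sources <- (sources - rowMeans(sources)) / apply(sources, 1, sd)
  mixing <- matrix(rnorm(n_t * n_src), n_t, n_src)
  mixing <- apply(mixing, 2, function(x) stats::filter(x, rep(1 / 8, 8),
                                                       circular = TRUE))
  clean <- mixing %*% sources
  noise <- matrix(rnorm(n_t * n_v), n_t, n_v) * sd(clean) / sqrt(snr)
  refs_raw <- sources + ref_noise * matrix(rnorm(n_src * n_v), n_src, n_v)
  list(series = vertex_series(t(clean + noise), dt = 1),
       sources = sources, refs = reference_set(refs_raw))
}

truth_cor <- function(fit, sources) {
  vapply(seq_len(nrow(sources)), function(j) {
    abs(cor(fit$spatial_zmaps[j, ], sources[j, ]))
  }, numeric(1))
}

test_that("a single noise-free source is recovered almost exactly", {
  set.seed(51)
  n_v <- 300
  src <- rexp(n_v) * rbinom(n_v, 1, 0.15)
  src <- (src - mean(src)) / sd(src)
  tc <- rnorm(120)
  series <- vertex_series(t(outer(tc, src)) + 1e-4 * matrix(rnorm(n_v * 120), n_v),
                          dt = 1)
  fit <- fit_cica(series, reference_set(src), cica_config(n_pcs = 5))
  expect_gte(abs(cor(fit$spatial_zmaps[1, ], src)), 0.999)
  expect_gte(fit$similarity[1], 0.99)
})

test_that("planted sparse sources are recovered through noisy references", {
  sim <- make_cica_sim(52)
  fit <- fit_cica(sim$series, sim$refs, cica_config())
  tc <- truth_cor(fit, sim$sources)
  expect_true(all(tc >= 0.95))
  expect_true(all(fit$similarity >= 0.2))
  expect_true(all(fit$converged))
})

test_that("components follow the references when the pairing is permuted", {
  sim <- make_cica_sim(53)
  perm <- c(2, 3, 1)
  refs_perm <- reference_set(sim$refs$maps[perm, ])
  fit <- fit_cica(sim$series, refs_perm, cica_config())
  # component j should match the permuted source, not the original slot
  for (j in 1:3) {
    expect_gt(abs(cor(fit$spatial_zmaps[j, ], sim$sources[perm[j], ])), 0.9)
  }
})

test_that("whitening, z-scoring, determinism and thresholding invariants hold", {
  sim <- make_cica_sim(54)
  fit1 <- fit_cica(sim$series, sim$refs, cica_config(), seed = 9)
  fit2 <- fit_cica(sim$series, sim$refs, cica_config(), seed = 9)
  expect_identical(fit1$spatial_zmaps, fit2$spatial_zmaps)
  expect_identical(fit1$timecourses, fit2$timecourses)

  for (j in 1:3) {
    expect_lt(abs(mean(fit1$spatial_zmaps[j, ])), 1e-6)
    expect_equal(sd(fit1$spatial_zmaps[j, ]), 1, tolerance = 1e-6)
  }
  expect_true(all(fit1$similarity >= 0 & fit1$similarity <= 1))

  # whitened covariance is the identity
  m <- t(sim$series$data)
  m <- m - rowMeans(m)
  eg <- eigen(tcrossprod(m) / ncol(m), symmetric = TRUE)
  k <- t(eg$vectors[, 1:30]) / sqrt(eg$values[1:30])
  y <- k %*% m
  expect_lt(max(abs(tcrossprod(y) / ncol(y) - diag(30))), 1e-8)

  expect_identical(threshold_zmap(c(3, -2, 0, 1.9), 2),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(threshold_zmap(rnorm(10), 0)))
  set.seed(55)
  frac <- mean(threshold_zmap(rnorm(10000), 2))
  expect_lt(abs(frac - 2 * pnorm(-2)), 0.01)
})

test_that("configuration and input contracts are enforced", {
  sim <- make_cica_sim(56, n_v = 100, n_t = 60)
  expect_error(fit_cica(sim$series, reference_set(rnorm(99))), "vertex count")
  expect_error(cica_config(rho_min = 0), "rho_min")
  # rank-deficient: duplicated timepoints only span a low-dimensional space
  flat <- vertex_series(matrix(rep(rnorm(100), 50), 100, 50), dt = 1)
  expect_error(fit_cica(flat, sim$refs, cica_config(n_pcs = 30)),
               "rank-deficient")
  expect_error(threshold_zmap(rnorm(5), -1), "non-negative")
})

test_that("result bundles round-trip through the archive + JSON format", {
  sim <- make_cica_sim(57, n_v = 120, n_t = 80)
  fit <- fit_cica(sim$series, sim$refs, cica_config(n_pcs = 10))
  dir <- withr::local_tempdir()
  save_cica_result(fit, dir)
  back <- load_cica_result(dir)
  expect_identical(back$spatial_zmaps, fit$spatial_zmaps)
  expect_equal(back$similarity, fit$similarity, tolerance = 1e-12)
  expect_equal(back$config$rho_min, fit$config$rho_min)
})
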